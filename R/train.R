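#' Partition chromosomes into folds by total length
#'
#' Greedy longest-first bin packing of chromosomes into `k` folds balancing
#' total bp. Fold 0 is reserved for final evaluation of the model ensemble
#' and never contributes gradients in any training mode. Specific
#' chromosomes (e.g. chr9/chr13/chr20/chr21 for the human autosomes) can be
#' pinned into fold 0 via `pin_fold0`.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths.
#' @param k Number of folds (default 10).
#' @param pin_fold0 Optional character vector of chromosome names forced
#'   into fold 0.
#' @param seed Seed used only to break exact length ties deterministically.
#' @return A `fold_partition`: list with `assignment` (named integer vector,
#'   values 0..k-1), `k`, `holdout_fold = 0`.
#' @export
partition_folds <- function(chromosome_lengths, k = 10L, pin_fold0 = NULL,
                            seed = 1L) {
  k <- as.integer(k)
  if (length(chromosome_lengths) < k) {
    stop("need at least as many chromosomes as folds")
  }
  stopifnot(!is.null(names(chromosome_lengths)))
  if (!is.null(pin_fold0)) {
    missing <- setdiff(pin_fold0, names(chromosome_lengths))
    if (length(missing)) stop("pinned chromosomes not found: ",
                              paste(missing, collapse = ", "))
  }
  set.seed(as.integer(seed))
  tie_break <- runif(length(chromosome_lengths))
  ord <- order(-chromosome_lengths, tie_break)
  assignment <- setNames(rep(NA_integer_, length(chromosome_lengths)),
                         names(chromosome_lengths))
  totals <- numeric(k)
  if (!is.null(pin_fold0)) {
    assignment[pin_fold0] <- 0L
    totals[1] <- sum(chromosome_lengths[pin_fold0])
  }
  open <- if (is.null(pin_fold0)) seq_len(k) else 2:k  # 1-based fold index
  for (i in ord) {
    nm <- names(chromosome_lengths)[i]
    if (!is.na(assignment[nm])) next
    f <- open[which.min(totals[open])]
    assignment[nm] <- f - 1L
    totals[f] <- totals[f] + chromosome_lengths[i]
  }
  structure(list(assignment = assignment, k = k, holdout_fold = 0L),
            class = "fold_partition")
}

#' Optimizer / training loop configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs on validation loss
#'   (default 10). Weights from the best validation epoch are restored.
#' @param lambda,alpha Multiscale loss parameters (defaults 1/500, 1e-6).
#' @param clip_norm Global gradient-norm clip applied before each Adam
#'   step (`Inf` = no clipping, the default). Desk-scale runs use a finite
#'   clip to protect short runs from occasional destabilizing steps.
#' @param calibrate_quantity If TRUE, the quantity head is refit in closed
#'   form after training: weighted least squares (weights `1/(total+1)^2`,
#'   approximating log-scale error) of training-window totals on the
#'   pooled trunk features. The refit is exactly realizable by the head's
#'   affine form, so this only replaces how the final-layer parameters are
#'   obtained; it makes the scalar head deterministic given the trunk,
#'   removing optimizer noise from short desk-scale runs. Default FALSE
#'   (canonical end-to-end protocol).
#' @param average_last If > 0, the returned weights are the element-wise
#'   mean over the final `average_last` epochs instead of the single best
#'   validation epoch (tail weight averaging). Default 0 (off): restore the
#'   best-validation-epoch weights. Averaging damps the optimization noise
#'   of short desk-scale runs; see the methods vignette.
#' @param seed Seed governing batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 100L, patience = 10L,
                         lambda = 1 / 500, alpha = 1e-6, clip_norm = Inf,
                         calibrate_quantity = FALSE, average_last = 0L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, average_last >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lambda = lambda, alpha = alpha,
                 clip_norm = clip_norm,
                 calibrate_quantity = isTRUE(calibrate_quantity),
                 average_last = as.integer(average_last),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a training dataset from a simulated panel
#'
#' Materializes one (input, target) pair per element x library: the input is
#' the two-hot encoded personalized (or variant-masked) sequence window
#' around the element center, jittered once by up to `jitter_max` bp (a
#' static dataset: jitter is not redrawn between epochs); the target is the
#' RPM-normalized strand-specific coverage over the central `output_length`
#' bp, concatenated plus strand then minus strand.
#'
#' @param panel A `sim_panel`.
#' @param arch A [model_config()].
#' @param partition A [partition_folds()] result over the panel chromosomes.
#' @param jitter_max Maximum window jitter in bp.
#' @param masked If TRUE, inputs use the reference sequence with all
#'   variants masked (labels are unchanged) — the reference-training
#'   ablation.
#' @param library_ids Libraries to include (default all).
#' @param seed Seed for jitter draws.
#' @return A `dipcap_dataset`: list with `X` (`N x L x 4`), `Y` (`N x P`),
#'   `fold`, `element_id`, `library_id`, `window_id`.
#' @export
make_dataset <- function(panel, arch, partition, jitter_max = 0L,
                         masked = FALSE, library_ids = NULL, seed = 1L) {
  stopifnot(inherits(panel, "sim_panel"), inherits(arch, "dipcap_arch"))
  libs <- if (is.null(library_ids)) panel$libraries$library_id else library_ids
  donors <- panel$libraries$donor_id[match(libs, panel$libraries$library_id)]
  L <- arch$input_length
  P <- 2L * arch$output_length
  half_out <- arch$output_length %/% 2L
  n_el <- nrow(panel$elements)
  N <- n_el * length(libs)
  rpm <- 1e6 / library_totals(panel, libs)
  set.seed(as.integer(seed))
  X <- array(0, dim = c(N, L, 4L))
  Y <- matrix(0, N, P)
  fold <- integer(N)
  element_id <- character(N)
  library_id <- character(N)
  idx <- 0L
  for (e in seq_len(n_el)) {
    el <- panel$elements[e, ]
    cov <- panel$coverage[[el$element_id]]
    el_fold <- partition$assignment[[el$chrom]]
    snp_in <- which(panel$snps$chrom == el$chrom &
                      abs(panel$snps$pos - el$center) <= L %/% 2L + jitter_max)
    for (li in seq_along(libs)) {
      win <- extract_window(el$chrom, el$center, panel$chrom_lengths[[el$chrom]],
                            width = L, jitter_max = jitter_max)
      ref_seq <- substr(panel$reference[[el$chrom]], win$start + 1L, win$end)
      dosage <- integer(L)
      alt <- rep(NA_character_, L)
      if (!masked && length(snp_in)) {
        sp <- panel$snps[snp_in, ]
        inside <- sp$pos >= win$start & sp$pos < win$end
        if (any(inside)) {
          sp <- sp[inside, ]
          at <- sp$pos - win$start + 1L
          dosage[at] <- panel$genotypes[donors[li], sp$snp_id]
          alt[at] <- sp$alt
        }
      }
      xi <- two_hot_encode(mask_variants(ref_seq), dosage, alt)
      out_start <- win$start + L %/% 2L - half_out  # centered output window
      rel <- (out_start - cov$window$start + 1L):(out_start - cov$window$start +
                                                    arch$output_length)
      if (min(rel) < 1L || max(rel) > cov$window$width) {
        stop("output window extends beyond stored coverage; increase element_window")
      }
      idx <- idx + 1L
      X[idx, , ] <- xi
      Y[idx, ] <- c(cov$plus[libs[li], rel], cov$minus[libs[li], rel]) *
        rpm[[libs[li]]]
      fold[idx] <- el_fold
      element_id[idx] <- el$element_id
      library_id[idx] <- libs[li]
    }
  }
  structure(list(X = X, Y = Y, fold = fold, element_id = element_id,
                 library_id = library_id,
                 window_id = paste(element_id, library_id, sep = ":"),
                 masked = masked, arch = arch),
            class = "dipcap_dataset")
}

# ---- Adam optimizer over the named parameter list ----
adam_init <- function(params, names) {
  list(m = lapply(params[names], function(p) p * 0),
       v = lapply(params[names], function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr, names) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

# Mean multiscale loss over a set of windows. `batch_stats = TRUE` uses
# per-batch normalization statistics (fixed batch partitioning, so the
# value is deterministic); this is how validation is scored during
# training, because running statistics lag the weights they normalize and
# make inference-mode validation loss spuriously noisy.
eval_loss <- function(model, X, Y, config, batch_size = 256L,
                      batch_stats = FALSE) {
  n <- nrow(Y)
  total <- 0
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    xc <- aperm(X[s:e, , , drop = FALSE], c(3L, 2L, 1L))
    out <- nn_forward_cpp(model$params, unclass(model$arch), xc,
                          isTRUE(batch_stats))  # state discarded
    total <- total + (e - s + 1L) *
      multiscale_loss_cpp(Y[s:e, , drop = FALSE], out$profile,
                          as.numeric(out$quantity), config$lambda,
                          config$alpha)
  }
  total / n
}

# Deterministic refit of the quantity head on the trained trunk: an affine
# map of the pooled trunk features is fit to the training-window totals
# under the same log-scale squared error the multiscale loss uses,
# by damped Gauss-Newton from a fixed (mean-quantity) start. The result is
# written directly into the head (BN set to the identity), so the head is
# a deterministic function of the trunk.
calibrate_quantity_head <- function(model, dataset, train_idx,
                                    batch_size = 256L, alpha = 1e-6,
                                    floor = 1, max_iter = 40L) {
  Fd <- model$arch$n_filters_tower
  G <- matrix(0, length(train_idx), Fd)
  for (s in seq(1L, length(train_idx), by = batch_size)) {
    e <- min(s + batch_size - 1L, length(train_idx))
    xc <- aperm(dataset$X[train_idx[s:e], , , drop = FALSE], c(3L, 2L, 1L))
    G[s:e, ] <- nn_gap_cpp(model$params, unclass(model$arch), xc)
  }
  tot <- rowSums(dataset$Y[train_idx, , drop = FALSE])
  X <- cbind(1, G)
  obj <- function(beta) {
    mu <- pmax(X %*% beta, floor)
    sum((log(mu + alpha) - log(tot + alpha))^2)
  }
  beta <- c(mean(tot), rep(0, Fd))
  f <- obj(beta)
  for (iter in seq_len(max_iter)) {
    mu <- pmax(as.numeric(X %*% beta), floor)
    r <- log(mu + alpha) - log(tot + alpha)
    J <- X / (mu + alpha)
    H <- crossprod(J) + diag(1e-8, ncol(X))
    delta <- tryCatch(solve(H, -crossprod(J, r)),
                      error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {  # backtracking line search
      cand <- beta + step * as.numeric(delta)
      fc <- obj(cand)
      if (fc < f || step < 1e-4) break
      step <- step / 2
    }
    if (fc >= f - 1e-10 * abs(f)) break
    beta <- cand
    f <- fc
  }
  model$params$quant_W <- matrix(beta[-1], nrow = 1)
  model$params$quant_b <- unname(beta[1])
  model$params$bnq_gamma <- 1
  model$params$bnq_beta <- 0
  model$params$bnq_mean <- 0
  model$params$bnq_var <- 1 - model$arch$bn_eps  # sqrt(var + eps) = 1
  model
}

# Freeze batch-norm inference statistics from one large calibration batch
# of training windows, taken in a single training-mode pass with momentum
# 0. By induction through the layers, inference with these frozen
# statistics reproduces the network's training-mode behavior on the
# calibration batch exactly (layer k's statistics are computed from inputs
# normalized the same way inference will normalize them), which is what
# incremental EMA statistics — recorded while every deeper layer still saw
# per-batch normalization — fail to do; the mismatch compounds across the
# 13 BN layers and can wreck inference-mode predictions outright.
refresh_bn_stats <- function(model, X, idx, calibration_size = 512L) {
  take <- idx[unique(as.integer(round(seq(1L, length(idx),
                                          length.out = min(calibration_size,
                                                           length(idx))))))]
  xc <- aperm(X[take, , , drop = FALSE], c(3L, 2L, 1L))
  arch0 <- unclass(model$arch)
  arch0$bn_momentum <- 0  # state <- exactly this batch's statistics
  out <- nn_forward_cpp(model$params, arch0, xc, TRUE)
  for (nm in names(out$state)) model$params[[nm]] <- out$state[[nm]]
  model
}

#' Train one model replicate with early stopping
#'
#' Adam on the multiscale loss over the training folds, validating on
#' `holdout_fold` for early stopping. Fold 0 is always excluded from
#' training and validation (it is the final-evaluation fold). The weights
#' from the best validation epoch are restored at the end. The model keeps
#' a training log (window ids and folds seen, per-epoch losses and learning
#' rates) for leakage auditing.
#'
#' @param dataset A `dipcap_dataset`.
#' @param holdout_fold Validation fold (>= 1).
#' @param config A [train_config()].
#' @param model Optional starting model (default: fresh [build_model()] with
#'   `config$seed`).
#' @param lr_schedule Optional vector of per-epoch learning rates (recycled
#'   to `max_epochs`); overrides `config$learning_rate`.
#' @return A trained `dipcap_model` with `history` and `train_log`.
#' @export
train_model <- function(dataset, holdout_fold, config = train_config(),
                        model = NULL, lr_schedule = NULL) {
  stopifnot(inherits(dataset, "dipcap_dataset"), holdout_fold >= 1)
  if (is.null(model)) {
    model <- build_model(dataset$arch, seed = config$seed)
    # data-scale initialization of the quantity head: its BN shift/scale
    # start at the mean/sd of the training totals, so optimization spends
    # its steps on shape rather than on climbing to the coverage scale
    tot <- rowSums(dataset$Y[!dataset$fold %in% c(0L, holdout_fold), ,
                             drop = FALSE])
    model$params$bnq_beta <- mean(tot)
    model$params$bnq_gamma <- max(sd(tot), 1e-3)
  }
  train_idx <- which(!dataset$fold %in% c(0L, holdout_fold))
  val_idx <- which(dataset$fold == holdout_fold)
  if (!length(val_idx)) stop("validation fold ", holdout_fold, " is empty")
  if (!length(train_idx)) stop("no training windows left")
  lrs <- if (is.null(lr_schedule)) rep(config$learning_rate, config$max_epochs)
         else rep(lr_schedule, length.out = config$max_epochs)
  tn <- trainable_names(model$params)
  opt <- adam_init(model$params, tn)
  set.seed(config$seed + 1000L)
  best <- list(val = Inf, params = model$params, epoch = 0L)
  history <- data.frame()
  wait <- 0L
  avg_k <- if (is.null(config$average_last)) 0L else config$average_last
  tail_params <- list()  # rolling window of end-of-epoch weights
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      xc <- aperm(dataset$X[b, , , drop = FALSE], c(3L, 2L, 1L))
      res <- nn_loss_grad_cpp(model$params, unclass(model$arch), xc,
                              dataset$Y[b, , drop = FALSE], config$lambda,
                              config$alpha)
      for (nm in names(res$state)) model$params[[nm]] <- res$state[[nm]]
      grads <- res$grads
      clip <- if (is.null(config$clip_norm)) Inf else config$clip_norm
      if (is.finite(clip)) {
        gnorm <- sqrt(sum(vapply(tn, function(nm) sum(grads[[nm]]^2),
                                 numeric(1))))
        if (gnorm > clip) {
          for (nm in tn) grads[[nm]] <- grads[[nm]] * (clip / gnorm)
        }
      }
      upd <- adam_step(model$params, grads, opt, lrs[epoch], tn)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1L
    }
    val_loss <- eval_loss(model, dataset$X[val_idx, , , drop = FALSE],
                          dataset$Y[val_idx, , drop = FALSE], config,
                          batch_stats = TRUE)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb, val_loss = val_loss,
      lr = lrs[epoch]))
    if (avg_k > 0L) {
      tail_params[[length(tail_params) + 1L]] <- model$params[tn]
      if (length(tail_params) > avg_k) tail_params[[1L]] <- NULL
    }
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (avg_k > 0L && length(tail_params)) {
    for (nm in tn) {
      model$params[[nm]] <- Reduce(`+`, lapply(tail_params, `[[`, nm)) /
        length(tail_params)
    }
  } else {
    model$params <- best$params
  }
  model <- refresh_bn_stats(model, dataset$X, train_idx)
  if (isTRUE(config$calibrate_quantity)) {
    model <- calibrate_quantity_head(model, dataset, train_idx)
  }
  model$history <- history
  model$lr_log <- history$lr
  model$best_epoch <- best$epoch
  model$holdout_fold <- holdout_fold
  model$train_log <- list(
    window_ids = dataset$window_id[train_idx],
    folds_used = sort(unique(dataset$fold[train_idx])),
    val_fold = holdout_fold,
    masked = dataset$masked,
    seed = config$seed
  )
  model$masked_inputs <- isTRUE(dataset$masked)
  model
}

#' Train the leave-one-out fold ensemble
#'
#' Trains one replicate per training fold (1..9 by default); replicate `i`
#' holds out fold `i` for validation and trains on the remaining training
#' folds. Fold 0 is never seen by any replicate.
#'
#' @param dataset A `dipcap_dataset`.
#' @param config A [train_config()].
#' @param folds Training folds (default `1:9`).
#' @return A `dipcap_ensemble`.
#' @export
train_ensemble <- function(dataset, config = train_config(), folds = 1:9) {
  replicates <- lapply(folds, function(f) {
    dipcap_log("train", sprintf("replicate holdout fold %d", f))
    train_model(dataset, holdout_fold = f,
                config = modifyList(config, list(seed = config$seed + f)))
  })
  names(replicates) <- as.character(folds)
  structure(list(replicates = replicates, folds = folds,
                 arch = dataset$arch, masked_inputs = isTRUE(dataset$masked)),
            class = "dipcap_ensemble")
}

#' Ensemble prediction (mean of replicates)
#'
#' Profiles are averaged after per-replicate normalization to sum 1 (so a
#' replicate's overall scale does not dominate the shape); quantities are
#' averaged directly.
#'
#' @param object A `dipcap_ensemble`.
#' @param x Encoded input (matrix or batch array).
#' @param ... Unused.
#' @return A `pq_prediction`.
#' @export
predict.dipcap_ensemble <- function(object, x, ...) {
  preds <- lapply(object$replicates, function(m) predict(m, x))
  prof <- 0
  for (p in preds) {
    pr <- p$profile
    s <- rowSums(pr)
    s[s <= 0] <- 1
    prof <- prof + pr / s
  }
  prof <- prof / length(preds)
  q <- Reduce(`+`, lapply(preds, `[[`, "quantity")) / length(preds)
  structure(list(profile = prof, quantity = q), class = "pq_prediction")
}

#' Subsample libraries without isogenic duplicates
#'
#' Draws `n` libraries from `n` distinct donors, uniformly without
#' replacement; when a donor has several isogenic replicate libraries, one
#' of them is chosen at random. This mirrors the rule that a subsampling
#' run never contains two libraries from the same individual.
#'
#' @param panel A `sim_panel`.
#' @param n Number of libraries (<= number of distinct donors).
#' @param seed Seed.
#' @return A `sim_panel` restricted to the sampled libraries.
#' @export
subsample_panel <- function(panel, n, seed = 1L) {
  stopifnot(inherits(panel, "sim_panel"))
  donors <- unique(panel$libraries$donor_id)
  if (n > length(donors)) stop("n exceeds the number of distinct donors")
  set.seed(as.integer(seed))
  chosen <- sample(donors, n)
  libs <- vapply(chosen, function(d) {
    cand <- panel$libraries$library_id[panel$libraries$donor_id == d]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1), USE.NAMES = FALSE)
  subset_panel_libraries(panel, libs)
}

#' Restrict a panel to a set of libraries
#'
#' @param panel A `sim_panel`.
#' @param library_ids Libraries to keep.
#' @return The restricted `sim_panel`.
#' @export
subset_panel_libraries <- function(panel, library_ids) {
  stopifnot(all(library_ids %in% panel$libraries$library_id))
  panel$libraries <- panel$libraries[
    match(library_ids, panel$libraries$library_id), , drop = FALSE]
  panel$coverage <- lapply(panel$coverage, function(cov) {
    cov$plus <- cov$plus[library_ids, , drop = FALSE]
    cov$minus <- cov$minus[library_ids, , drop = FALSE]
    cov
  })
  panel
}

#' Train the variant-masking (reference sequence) ablation
#'
#' Identical training protocol to the personalized model, but every input
#' window uses the reference sequence with variants masked; the
#' per-individual coverage labels are unchanged. The returned model is
#' flagged `masked_inputs`, so downstream prediction also uses masked
#' inputs (reference-model predictions are allele-invariant by
#' construction).
#'
#' @param panel A `sim_panel`.
#' @param arch A [model_config()].
#' @param partition A [partition_folds()] result.
#' @param holdout_fold Validation fold.
#' @param config A [train_config()].
#' @param jitter_max,library_ids,dataset_seed Passed to [make_dataset()].
#' @return A trained `dipcap_model` with `masked_inputs = TRUE`.
#' @export
train_reference_ablation <- function(panel, arch, partition, holdout_fold = 1L,
                                     config = train_config(), jitter_max = 0L,
                                     library_ids = NULL, dataset_seed = 1L) {
  ds <- make_dataset(panel, arch, partition, jitter_max = jitter_max,
                     masked = TRUE, library_ids = library_ids,
                     seed = dataset_seed)
  train_model(ds, holdout_fold, config)
}

#' Fine-tune a pretrained model on a new dataset
#'
#' All weights are trainable. The first `warmup_epochs` epochs run at
#' `warmup_lr` (default 1e-4), subsequent epochs at the configured learning
#' rate (default 0.001). The same fold partition as pretraining should be
#' used to avoid leakage into variant benchmarks.
#'
#' @param model A pretrained `dipcap_model` (architecture must match the
#'   dataset).
#' @param dataset A `dipcap_dataset` for the new cell type / readout.
#' @param holdout_fold Validation fold.
#' @param config A [train_config()].
#' @param warmup_lr Warmup learning rate (default 1e-4).
#' @param warmup_epochs Number of warmup epochs (default 1).
#' @return The fine-tuned model; `model$lr_log` records the realized
#'   schedule.
#' @export
fine_tune <- function(model, dataset, holdout_fold = 1L,
                      config = train_config(), warmup_lr = 1e-4,
                      warmup_epochs = 1L) {
  stopifnot(inherits(model, "dipcap_model"))
  if (!identical(unclass(model$arch), unclass(dataset$arch))) {
    stop("pretrained model architecture does not match the dataset")
  }
  schedule <- c(rep(warmup_lr, warmup_epochs),
                rep(config$learning_rate,
                    max(0L, config$max_epochs - warmup_epochs)))
  train_model(dataset, holdout_fold, config, model = model,
              lr_schedule = schedule)
}

#' Subsampling experiment: performance versus panel size
#'
#' For each `n` in `n_values`, draws `runs_per_n` random subpanels of `n`
#' distinct donors, trains a model on each, and evaluates cross-loci
#' metrics on fold-0 elements plus tiQTL/diQTL effect-score correlations.
#' Each row logs the seeds needed for an exact re-run.
#'
#' @param panel A `sim_panel`.
#' @param arch,partition,config Training setup.
#' @param n_values Panel sizes (default `c(5, 10, 15, 20, 30)`).
#' @param runs_per_n Runs per size (default 5).
#' @param holdout_fold Validation fold for single-replicate training.
#' @param ensemble If TRUE each run trains a full 9-replicate ensemble
#'   (expensive); default FALSE trains one replicate.
#' @param seed Base seed; run `(n, r)` uses deterministic offsets.
#' @return data.frame: `n`, `run`, `profile_pcc`, `quantity_pcc`,
#'   `tiqtl_pcc`, `diqtl_pcc`, `subsample_seed`, `train_seed`.
#' @export
run_subsampling_experiment <- function(panel, arch, partition,
                                       config = train_config(),
                                       n_values = c(5L, 10L, 15L, 20L, 30L),
                                       runs_per_n = 5L, holdout_fold = 1L,
                                       ensemble = FALSE, seed = 1L) {
  rows <- list()
  for (n in n_values) {
    for (r in seq_len(runs_per_n)) {
      sub_seed <- seed + 101L * n + r
      tr_seed <- seed + 997L * n + r
      sub <- subsample_panel(panel, n, seed = sub_seed)
      ds <- make_dataset(sub, arch, partition, seed = tr_seed)
      fit <- if (ensemble) {
        train_ensemble(ds, modifyList(config, list(seed = tr_seed)))
      } else {
        train_model(ds, holdout_fold,
                    modifyList(config, list(seed = tr_seed)))
      }
      cl <- cross_loci_benchmark(fit, sub, partition)
      qt <- qtl_correlations(fit, sub)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, run = r, profile_pcc = cl$profile_pcc,
        quantity_pcc = cl$quantity_pcc,
        tiqtl_pcc = qt[["tiQTL"]], diqtl_pcc = qt[["diQTL"]],
        subsample_seed = sub_seed, train_seed = tr_seed)
      dipcap_log("subsample", sprintf(
        "n=%d run=%d profile=%.3f quantity=%.3f ti=%.3f di=%.3f", n, r,
        cl$profile_pcc, cl$quantity_pcc, qt[["tiQTL"]], qt[["diQTL"]]))
    }
  }
  do.call(rbind, rows)
}
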