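#' L2 variant effect score from genotype-binned tracks
#'
#' Individuals are binned by genotype dosage at the QTL; the score is the
#' Euclidean (L2) norm of the difference between the averaged
#' homozygous-reference (dosage 0) and averaged homozygous-alternate
#' (dosage 2) tracks. Heterozygotes are excluded. The score is symmetric
#' under swapping the bins and invariant to adding a common track to all
#' individuals.
#'
#' @param tracks Numeric matrix, one row per individual (coverage units).
#' @param genotypes Dosage vector (0/1/2) aligned with rows.
#' @return Nonnegative scalar; 0 iff the bin-averaged tracks are identical.
#' @export
l2_effect <- function(tracks, genotypes) {
  stopifnot(is.matrix(tracks), nrow(tracks) == length(genotypes))
  hom_ref <- which(genotypes == 0)
  hom_alt <- which(genotypes == 2)
  if (!length(hom_ref)) stop("empty homozygous-reference bin")
  if (!length(hom_alt)) stop("empty homozygous-alternate bin")
  d <- colMeans(tracks[hom_ref, , drop = FALSE]) -
    colMeans(tracks[hom_alt, , drop = FALSE])
  sqrt(sum(d^2))
}

#' Build QTL records from a panel's planted effects
#'
#' One record per planted SNP with at least one homozygous-reference and
#' one homozygous-alternate library in the panel (others are dropped, with
#' a logged count). The record's kind is `tiQTL` when the planted quantity
#' effect dominates (|log2FC| >= |directionality logit|), else `diQTL`.
#'
#' @param panel A `sim_panel`.
#' @return List of `qtl_record`s: `snp_id`, `element_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `kind`, `genotypes` (per library), `center`.
#' @export
qtl_records <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(panel$effects))) {
    eff <- panel$effects[i, ]
    snp <- panel$snps[panel$snps$snp_id == eff$snp_id, ]
    el <- panel$elements[panel$elements$element_id == eff$element_id, ]
    g <- setNames(panel$genotypes[panel$libraries$donor_id, snp$snp_id],
                  panel$libraries$library_id)
    if (!any(g == 0) || !any(g == 2)) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      snp_id = snp$snp_id, element_id = el$element_id, chrom = snp$chrom,
      pos = snp$pos, ref = snp$ref, alt = snp$alt,
      kind = if (abs(eff$quantity_log2fc_per_allele) >=
                 abs(eff$directionality_logit_per_allele)) "tiQTL" else "diQTL",
      genotypes = g, center = el$center
    ), class = "qtl_record")
  }
  if (dropped > 0) {
    dipcap_log("qtl", sprintf("dropped %d QTL(s) lacking a homozygous bin",
                              dropped))
  }
  out
}

# two-hot inputs for every library at an element-centered window (jitter 0);
# identical inputs are collapsed and an index map returned
element_inputs <- function(panel, chrom, center, input_length,
                           masked = FALSE) {
  libs <- panel$libraries$library_id
  donors <- panel$libraries$donor_id
  half <- input_length %/% 2L
  start <- as.integer(center) - half
  ref_seq <- substr(panel$reference[[chrom]], start + 1L,
                    start + input_length)
  sp <- panel$snps[panel$snps$chrom == chrom & panel$snps$pos >= start &
                     panel$snps$pos < start + input_length, , drop = FALSE]
  sig <- if (masked || nrow(sp) == 0) rep("ref", length(libs)) else
    apply(panel$genotypes[donors, sp$snp_id, drop = FALSE], 1L, paste,
          collapse = "")
  uniq <- !duplicated(sig)
  map <- match(sig, sig[uniq])
  X <- array(0, dim = c(sum(uniq), input_length, 4L))
  ui <- which(uniq)
  for (k in seq_along(ui)) {
    dosage <- integer(input_length)
    alt <- rep(NA_character_, input_length)
    if (!masked && nrow(sp)) {
      at <- sp$pos - start + 1L
      dosage[at] <- panel$genotypes[donors[ui[k]], sp$snp_id]
      alt[at] <- sp$alt
    }
    X[k, , ] <- two_hot_encode(ref_seq, dosage, alt)
  }
  list(X = X, map = setNames(map, libs))
}

#' Observed QTL effect from panel coverage
#'
#' RPM-normalized coverage over the central `output_length` bp around the
#' QTL's element (jitter 0), both strands concatenated, scored with
#' [l2_effect()].
#'
#' @param panel A `sim_panel`.
#' @param qtl A `qtl_record`.
#' @param output_length Track half-width per strand in bp.
#' @return Nonnegative scalar effect score.
#' @export
observed_qtl_effect <- function(panel, qtl, output_length) {
  cov <- panel$coverage[[qtl$element_id]]
  libs <- panel$libraries$library_id
  rpm <- 1e6 / library_totals(panel, libs)
  half <- output_length %/% 2L
  rel <- (qtl$center - half - cov$window$start + 1L):
    (qtl$center - half - cov$window$start + output_length)
  stopifnot(min(rel) >= 1, max(rel) <= cov$window$width)
  tracks <- cbind(cov$plus[libs, rel, drop = FALSE],
                  cov$minus[libs, rel, drop = FALSE]) * rpm[libs]
  l2_effect(tracks, qtl$genotypes[libs])
}

#' Predicted QTL effect
#'
#' Predicts per-library tracks ([predicted_track()]: normalized profile
#' times quantity) on two-hot inputs at the element-centered window (jitter
#' 0) and applies [l2_effect()] with the same genotype bins. A model
#' trained on masked inputs predicts on masked inputs, making its effect
#' exactly 0 whenever all the window's variants are masked. For an
#' ensemble with a fold partition, the holdout-aware compositing rule of
#' [composite_prediction()] selects the prediction source.
#'
#' @param object A `dipcap_model` or `dipcap_ensemble`.
#' @param qtl A `qtl_record`.
#' @param panel A `sim_panel`.
#' @param partition Optional [partition_folds()] result (required for
#'   ensemble compositing).
#' @return Nonnegative scalar effect score.
#' @export
predicted_qtl_effect <- function(object, qtl, panel, partition = NULL) {
  predictor <- object
  if (inherits(object, "dipcap_ensemble")) {
    if (is.null(partition)) stop("ensemble scoring requires a fold partition")
    predictor <- composite_prediction(object, qtl, partition)$predictor
  }
  arch <- if (inherits(predictor, "dipcap_ensemble")) predictor$arch else
    predictor$arch
  masked <- isTRUE(if (inherits(predictor, "dipcap_ensemble"))
    predictor$masked_inputs else predictor$masked_inputs)
  inp <- element_inputs(panel, qtl$chrom, qtl$center, arch$input_length,
                        masked = masked)
  pred <- predict(predictor, inp$X)
  tracks <- predicted_track(pred)[inp$map, , drop = FALSE]
  l2_effect(tracks, qtl$genotypes[names(inp$map)])
}

#' Holdout-aware prediction compositing
#'
#' QTLs on the fully withheld fold 0 are scored with the full ensemble;
#' QTLs on any other fold `i` are scored with replicate `i` alone — the one
#' model that held that fold out of training. No QTL is ever scored by a
#' replicate trained on its chromosome.
#'
#' @param ensemble A `dipcap_ensemble`.
#' @param qtl A `qtl_record` (or any list with `chrom`).
#' @param partition A [partition_folds()] result.
#' @return List with `source` (`"ensemble"` or `"replicate:i"`) and
#'   `predictor`.
#' @export
composite_prediction <- function(ensemble, qtl, partition) {
  chrom <- qtl$chrom
  if (!chrom %in% names(partition$assignment)) {
    stop("chromosome ", chrom, " not in the fold partition")
  }
  fold <- partition$assignment[[chrom]]
  if (fold == 0L) {
    list(source = "ensemble", predictor = ensemble)
  } else {
    list(source = paste0("replicate:", fold),
         predictor = ensemble$replicates[[as.character(fold)]])
  }
}

#' Cross-loci profile and quantity metrics
#'
#' Profile performance: median over loci of the Pearson correlation between
#' predicted and observed tracks (both strands concatenated). Quantity
#' performance: Pearson correlation between `log10(total + pseudocount)` of
#' predicted and observed coverage across loci. Loci where either track is
#' constant (undefined correlation) are excluded with a logged count.
#'
#' @param predictions Matrix of predicted tracks (loci x track length).
#' @param observations Matrix of observed tracks, same shape.
#' @param pseudocount Added inside the log10 (default 1e-6).
#' @return List: `profile_pcc`, `quantity_pcc`, `n_loci`, `n_excluded`.
#' @export
cross_loci_metrics <- function(predictions, observations,
                               pseudocount = 1e-6) {
  stopifnot(all(dim(predictions) == dim(observations)),
            nrow(predictions) >= 2)
  per_locus <- vapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions[i, ]
    o <- observations[i, ]
    if (sd(p) == 0 || sd(o) == 0) return(NA_real_)
    cor(p, o)
  }, numeric(1))
  n_excluded <- sum(is.na(per_locus))
  if (n_excluded > 0) {
    dipcap_log("metrics", sprintf(
      "%d locus/loci with constant tracks excluded from profile metric",
      n_excluded))
  }
  list(
    profile_pcc = median(per_locus, na.rm = TRUE),
    quantity_pcc = cor(log10(rowSums(predictions) + pseudocount),
                       log10(rowSums(observations) + pseudocount)),
    n_loci = nrow(predictions), n_excluded = n_excluded
  )
}

#' Cross-loci benchmark on fold-0 elements
#'
#' Predicts fold-0 element tracks from reference sequence (as in the
#' cross-loci benchmark, which uses reference sequence and panel-averaged
#' RPM coverage) and compares against the panel-mean observed coverage.
#'
#' @param object A `dipcap_model` or `dipcap_ensemble`.
#' @param panel A `sim_panel`.
#' @param partition A [partition_folds()] result.
#' @param fold Which fold's elements to evaluate (default 0, the final
#'   evaluation fold); `NULL` evaluates every element.
#' @return [cross_loci_metrics()] output plus `element_ids`.
#' @export
cross_loci_benchmark <- function(object, panel, partition, fold = 0L) {
  arch <- object$arch
  els <- if (is.null(fold)) panel$elements else panel$elements[
    partition$assignment[panel$elements$chrom] == fold, , drop = FALSE]
  if (nrow(els) < 2) stop("need at least 2 elements on the evaluation fold")
  libs <- panel$libraries$library_id
  rpm <- 1e6 / library_totals(panel, libs)
  half <- arch$output_length %/% 2L
  P <- 2L * arch$output_length
  pred <- matrix(0, nrow(els), P)
  obs <- matrix(0, nrow(els), P)
  X <- array(0, dim = c(nrow(els), arch$input_length, 4L))
  for (i in seq_len(nrow(els))) {
    el <- els[i, ]
    inp <- element_inputs(panel, el$chrom, el$center, arch$input_length,
                          masked = TRUE)  # reference sequence inputs
    X[i, , ] <- inp$X[1, , ]
    cov <- panel$coverage[[el$element_id]]
    rel <- (el$center - half - cov$window$start + 1L):
      (el$center - half - cov$window$start + arch$output_length)
    obs[i, ] <- c(colMeans(cov$plus[libs, rel, drop = FALSE] * rpm[libs]),
                  colMeans(cov$minus[libs, rel, drop = FALSE] * rpm[libs]))
  }
  pr <- predict(object, X)
  pred <- predicted_track(pr)
  out <- cross_loci_metrics(pred, obs)
  out$element_ids <- els$element_id
  out
}

#' QTL benchmark across model variants
#'
#' For each model, computes the Pearson correlation between predicted and
#' observed L2 effect scores over the QTL set, and the fraction of QTLs
#' predicted as having no effect (predicted score 0 after rounding at
#' `zero_tol`). A degenerate predictor whose scores have zero variance
#' (e.g. a masked-input model, whose predicted effects are all exactly 0)
#' is reported with `pcc = 0` and `degenerate = TRUE`: a constant score
#' carries no discriminative association.
#'
#' @param models Named list of `dipcap_model` / `dipcap_ensemble`.
#' @param panel A `sim_panel`.
#' @param qtls List of `qtl_record`s (default: [qtl_records()] of the
#'   panel).
#' @param partition Optional partition for ensemble compositing.
#' @param zero_tol Rounding tolerance defining "no effect" (default 1e-8).
#' @return data.frame: `model`, `kind`, `pcc`, `no_effect_frac`, `n`,
#'   `degenerate`.
#' @export
qtl_benchmark <- function(models, panel, qtls = NULL, partition = NULL,
                          zero_tol = 1e-8) {
  if (is.null(qtls)) qtls <- qtl_records(panel)
  if (length(qtls) < 2) stop("need at least 2 QTLs")
  arch1 <- models[[1]]$arch
  observed <- vapply(qtls, function(q)
    observed_qtl_effect(panel, q, arch1$output_length), numeric(1))
  kinds <- vapply(qtls, `[[`, character(1), "kind")
  rows <- list()
  for (nm in names(models)) {
    predicted <- vapply(qtls, function(q)
      predicted_qtl_effect(models[[nm]], q, panel, partition), numeric(1))
    for (kd in c("tiQTL", "diQTL", "all")) {
      sel <- if (kd == "all") rep(TRUE, length(qtls)) else kinds == kd
      if (sum(sel) < 2) next
      p <- predicted[sel]
      degenerate <- sd(p) == 0
      if (degenerate) {
        dipcap_log("qtl", sprintf(
          "model '%s': constant predicted effects (%s); reporting pcc = 0",
          nm, kd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, kind = kd,
        pcc = if (degenerate) 0 else cor(observed[sel], p),
        no_effect_frac = mean(round(p / zero_tol) == 0),
        n = sum(sel), degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# tiQTL/diQTL effect correlations for one model (helper used by the
# subsampling experiment)
qtl_correlations <- function(object, panel, partition = NULL) {
  qtls <- qtl_records(panel)
  arch <- object$arch
  res <- c(tiQTL = NA_real_, diQTL = NA_real_)
  if (length(qtls) < 2) return(res)
  observed <- vapply(qtls, function(q)
    observed_qtl_effect(panel, q, arch$output_length), numeric(1))
  predicted <- vapply(qtls, function(q)
    predicted_qtl_effect(object, q, panel, partition), numeric(1))
  kinds <- vapply(qtls, `[[`, character(1), "kind")
  for (kd in names(res)) {
    sel <- kinds == kd
    if (sum(sel) >= 2 && sd(predicted[sel]) > 0) {
      res[[kd]] <- cor(observed[sel], predicted[sel])
    } else if (sum(sel) >= 2) {
      res[[kd]] <- 0
    }
  }
  res
}
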