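# approximate hg38 autosome lengths (bp), used for the fold-pinning check
HG38_AUTOSOMES <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468
)

test_that("fold partitioning balances lengths and supports fold-0 pinning", {
  equal <- setNames(rep(1000, 10), paste0("chr", 1:10))
  pt <- partition_folds(equal, k = 10L)
  expect_setequal(unname(pt$assignment), 0:9)  # one chromosome per fold
  expect_error(partition_folds(equal[1:5], k = 10L), "at least as many")
  # balance property over random instances
  set.seed(17)
  for (i in 1:100) {
    n <- sample(12:30, 1)
    lens <- setNames(runif(n, 0.5, 1.5) * 1e6, paste0("c", seq_len(n)))
    p <- partition_folds(lens, k = 5L, seed = i)
    totals <- tapply(lens, p$assignment[names(lens)], sum)
    expect_lte(max(totals) / min(totals), 2)
  }
  # hg38 autosomes with the canonical fold-0 chromosomes pinned
  pinned <- partition_folds(HG38_AUTOSOMES, k = 10L,
                            pin_fold0 = c("chr9", "chr13", "chr20", "chr21"))
  expect_true(all(pinned$assignment[c("chr9", "chr13", "chr20", "chr21")] == 0))
  expect_equal(sum(pinned$assignment == 0), 4L)
  expect_identical(pinned$holdout_fold, 0L)
})

test_that("datasets tag folds and masking removes heterozygous entries", {
  fx <- tiny_fixture()
  ds <- fx$dataset
  expect_equal(dim(ds$X)[1], nrow(fx$panel$elements) *
                 nrow(fx$panel$libraries))
  expect_setequal(unique(ds$fold),
                  unique(unname(fx$partition$assignment[fx$panel$elements$chrom])))
  # every input row sums to 2 over channels
  expect_true(all(apply(ds$X, c(1, 2), sum) == 2))
  masked <- make_dataset(fx$panel, fx$arch, fx$partition, masked = TRUE,
                         seed = 1L)
  expect_false(any(masked$X == 1))              # no heterozygous rows
  expect_identical(masked$Y, ds$Y)              # labels unchanged
  # in a zero-variant window set, masked and personalized inputs agree
  nosnp <- simulate_panel(tiny_sim_config(n_snps = 1L, causal_fraction = 0))
  # place the one SNP wherever it fell; windows without it are identical
  d1 <- make_dataset(nosnp, fx$arch, fx$partition, masked = FALSE, seed = 2L)
  d2 <- make_dataset(nosnp, fx$arch, fx$partition, masked = TRUE, seed = 2L)
  same <- vapply(seq_len(dim(d1$X)[1]), function(i)
    identical(d1$X[i, , ], d2$X[i, , ]), logical(1))
  expect_gt(mean(same), 0.9)
})

test_that("training excludes fold 0, validates on the holdout, restores best weights", {
  fx <- tiny_fixture()
  cfg <- tiny_train_config(max_epochs = 4L)
  m <- train_model(fx$dataset, holdout_fold = 2L, cfg)
  # leakage audit from the training log
  fold0_ids <- fx$dataset$window_id[fx$dataset$fold == 0L]
  holdout_ids <- fx$dataset$window_id[fx$dataset$fold == 2L]
  expect_length(intersect(m$train_log$window_ids, fold0_ids), 0L)
  expect_length(intersect(m$train_log$window_ids, holdout_ids), 0L)
  expect_false(0L %in% m$train_log$folds_used)
  expect_false(2L %in% m$train_log$folds_used)
  # restored weights reproduce the best recorded validation loss
  val_idx <- which(fx$dataset$fold == 2L)
  val_now <- dipcap:::eval_loss(m, fx$dataset$X[val_idx, , , drop = FALSE],
                                fx$dataset$Y[val_idx, , drop = FALSE], cfg,
                                batch_stats = TRUE)
  expect_equal(val_now, min(m$history$val_loss), tolerance = 1e-10)
  # and that best is never worse than epoch 1 (early-stopping progress)
  expect_lte(min(m$history$val_loss), m$history$val_loss[1])
  expect_error(train_model(fx$dataset, holdout_fold = 99L, cfg), "empty")
})

test_that("the fold ensemble is leakage-free and averages replicates", {
  fx <- tiny_fixture()
  ens <- train_ensemble(fx$dataset, tiny_train_config(max_epochs = 1L),
                        folds = 1:9)
  expect_s3_class(ens, "dipcap_ensemble")
  fold0_ids <- fx$dataset$window_id[fx$dataset$fold == 0L]
  for (f in 1:9) {
    rep_f <- ens$replicates[[as.character(f)]]
    expect_length(intersect(rep_f$train_log$window_ids, fold0_ids), 0L)
    expect_false(f %in% rep_f$train_log$folds_used)
    expect_equal(rep_f$holdout_fold, f)
  }
  # ensemble prediction = mean of per-replicate normalized profiles and
  # mean of quantities
  x <- fx$dataset$X[1:3, , , drop = FALSE]
  pe <- predict(ens, x)
  manual_prof <- 0
  manual_q <- 0
  for (f in as.character(1:9)) {
    p <- predict(ens$replicates[[f]], x)
    s <- rowSums(p$profile)
    s[s <= 0] <- 1
    manual_prof <- manual_prof + p$profile / s
    manual_q <- manual_q + p$quantity
  }
  expect_equal(pe$profile, manual_prof / 9, tolerance = 1e-12)
  expect_equal(pe$quantity, manual_q / 9, tolerance = 1e-12)
})

test_that("subsampling never draws two isogenic libraries and is uniform", {
  cfg <- tiny_sim_config(genome_length = 3000L, n_elements = 2L,
                         n_individuals = 3L, n_snps = 20L, n_isogenic = 1L)
  panel <- simulate_panel(cfg)  # donors D001..D003, one duplicated
  dup_donor <- panel$libraries$donor_id[duplicated(panel$libraries$donor_id)]
  for (s in 1:200) {
    sub <- subsample_panel(panel, 2L, seed = s)
    expect_equal(anyDuplicated(sub$libraries$donor_id), 0L)
  }
  # n = number of distinct donors -> every donor represented once
  all_d <- subsample_panel(panel, 3L, seed = 1L)
  expect_setequal(all_d$libraries$donor_id, unique(panel$libraries$donor_id))
  expect_error(subsample_panel(panel, 4L), "exceeds")
  # uniform donor inclusion: P(donor in draw) = n/D
  counts <- setNames(numeric(3), unique(panel$libraries$donor_id))
  n_draws <- 10000L
  for (s in seq_len(n_draws)) {
    sub <- subsample_panel(panel, 2L, seed = 100000L + s)
    counts[sub$libraries$donor_id] <- counts[sub$libraries$donor_id] + 1
  }
  expect_true(all(abs(counts / n_draws - 2 / 3) < 0.02))
})

test_that("fine-tuning runs one warmup epoch and stays stable on its own data", {
  fx <- tiny_fixture()
  pre_cfg <- tiny_train_config(max_epochs = 3L)
  pre <- train_model(fx$dataset, holdout_fold = 1L, pre_cfg)
  tuned <- fine_tune(pre, fx$dataset, holdout_fold = 1L,
                     config = tiny_train_config(max_epochs = 3L, seed = 2L),
                     warmup_lr = 1e-4, warmup_epochs = 1L)
  # exactly one epoch at the warmup rate, later epochs at the base rate
  expect_equal(sum(tuned$lr_log == 1e-4), 1L)
  expect_equal(tuned$lr_log[1], 1e-4)
  if (length(tuned$lr_log) > 1) {
    expect_true(all(tuned$lr_log[-1] == 0.001))
  }
  # fine-tuning on the pretraining data does not degrade validation loss
  # by more than 5% (best-epoch restoration bounds the damage)
  val_idx <- which(fx$dataset$fold == 1L)
  val_pre <- dipcap:::eval_loss(pre, fx$dataset$X[val_idx, , , drop = FALSE],
                                fx$dataset$Y[val_idx, , drop = FALSE],
                                pre_cfg, batch_stats = TRUE)
  val_tuned <- dipcap:::eval_loss(tuned,
                                  fx$dataset$X[val_idx, , , drop = FALSE],
                                  fx$dataset$Y[val_idx, , drop = FALSE],
                                  pre_cfg, batch_stats = TRUE)
  # losses are negative near convergence; compare on a shifted scale
  expect_lte(val_tuned, val_pre + 0.05 * abs(val_pre))
  # architecture mismatch is an error
  other <- build_model(tiny_arch(input_length = 128L, output_length = 64L),
                       seed = 1)
  expect_error(fine_tune(other, fx$dataset), "architecture")
})

test_that("fine-tuning to a shifted cell state beats the frozen model", {
  # "new cell type": same genome and elements, re-drawn element base rates
  # and noise (coverage re-simulated under a different seed)
  fx <- tiny_fixture()
  cfg_b <- tiny_sim_config(seed = 77L, base_rate_sdlog = 1.0)
  panel_b <- fx$panel
  panel_b$coverage <- simulate_coverage(
    cfg_b, fx$panel$elements, fx$panel$effects, fx$panel$snps,
    fx$panel$genotypes, fx$panel$libraries, reference = fx$panel$reference)
  ds_b <- make_dataset(panel_b, fx$arch, fx$partition, seed = 3L)
  pre <- train_model(fx$dataset, 1L, tiny_train_config(max_epochs = 4L))
  tuned <- fine_tune(pre, ds_b, holdout_fold = 1L,
                     config = tiny_train_config(max_epochs = 4L, seed = 9L))
  cfg <- tiny_train_config()
  val_idx <- which(ds_b$fold == 1L)
  frozen_loss <- dipcap:::eval_loss(pre, ds_b$X[val_idx, , , drop = FALSE],
                                    ds_b$Y[val_idx, , drop = FALSE], cfg)
  tuned_loss <- dipcap:::eval_loss(tuned, ds_b$X[val_idx, , , drop = FALSE],
                                   ds_b$Y[val_idx, , drop = FALSE], cfg)
  expect_lt(tuned_loss, frozen_loss)
})

test_that("the subsampling experiment returns a complete, re-runnable table", {
  # common SNPs so even a 3-library subsample yields scoreable QTLs
  panel <- simulate_panel(tiny_sim_config(maf_range = c(0.4, 0.5),
                                          causal_fraction = 1))
  arch <- tiny_arch()
  partition <- partition_folds(panel$chrom_lengths, k = 10L, seed = 1L)
  run <- function() run_subsampling_experiment(
    panel, arch, partition, config = tiny_train_config(max_epochs = 2L),
    n_values = 5L, runs_per_n = 1L, seed = 5L)
  tab <- run()
  expect_equal(nrow(tab), 1L)
  expect_true(all(is.finite(unlist(
    tab[, c("profile_pcc", "quantity_pcc", "tiqtl_pcc", "diqtl_pcc")]))))
  # the logged seeds make the run exactly repeatable
  expect_identical(tab, run())
  expect_true(all(c("subsample_seed", "train_seed") %in% names(tab)))
})
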