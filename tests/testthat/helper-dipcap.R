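# quiet stage logging during tests
options(dipcap.verbose = FALSE)

# pin BLAS threading for bit-reproducible float accumulation
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# a micro panel/arch pair small enough to train in a few seconds
tiny_sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    genome_length = 6000L, n_chromosomes = 10L, n_individuals = 6L,
    n_elements = 20L, element_window = 200L, n_snps = 300L,
    causal_fraction = 0.5, quantity_effect_sd = 0.5,
    directionality_effect_sd = 0.5, dispersion = 0.1, seed = seed
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

tiny_arch <- function(...) {
  defaults <- list(input_length = 64L, output_length = 32L,
                   scale_factor = 0.05, n_tower = 4L)
  do.call(model_config, modifyList(defaults, list(...)))
}

tiny_train_config <- function(...) {
  defaults <- list(max_epochs = 2L, patience = 10L, batch_size = 32L,
                   seed = 1L)
  do.call(train_config, modifyList(defaults, list(...)))
}

# cached tiny panel + dataset so several tests can share one build
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_panel(tiny_sim_config())
      arch <- tiny_arch()
      partition <- partition_folds(panel$chrom_lengths, k = 10L, seed = 1L)
      dataset <- make_dataset(panel, arch, partition, seed = 1L)
      cache <<- list(panel = panel, arch = arch, partition = partition,
                     dataset = dataset)
    }
    cache
  }
})

# independent scalar recomputation of the multiscale loss (test oracle)
oracle_loss <- function(p_obs, y_profile, y_quantity, lambda = 1 / 500,
                        alpha = 1e-6) {
  np <- sqrt(sum(p_obs^2))
  ny <- sqrt(sum(y_profile^2))
  cosv <- if (np > 0 && ny > 0) sum(p_obs * y_profile) / (np * ny) else 0
  -cosv + lambda * (log(sum(p_obs) + alpha) - log(y_quantity + alpha))^2
}

# independent Pearson correlation (explicit formula, no stats::cor)
oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# brute-force average-precision by explicit threshold enumeration
oracle_auprc <- function(scores, labels) {
  s2 <- scores^2
  labels <- as.logical(labels)
  thresholds <- sort(unique(s2), decreasing = TRUE)
  npos <- sum(labels)
  prev_recall <- 0
  auprc <- 0
  for (th in thresholds) {
    sel <- s2 >= th
    precision <- sum(labels[sel]) / sum(sel)
    recall <- sum(labels[sel]) / npos
    auprc <- auprc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auprc
}
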