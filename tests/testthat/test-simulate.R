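test_that("reference simulation: contract, determinism, base frequencies", {
  cfg <- tiny_sim_config(genome_length = 1000L, n_chromosomes = 2L)
  ref <- simulate_reference(cfg)
  expect_length(ref, 2L)
  expect_true(all(nchar(ref) == 1000L))
  expect_true(all(strsplit(paste0(ref, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_identical(simulate_reference(cfg), ref)
  # binomial concentration of base frequencies at 100 kb
  big <- simulate_reference(tiny_sim_config(genome_length = 100000L,
                                            n_chromosomes = 1L))
  freq <- table(strsplit(big[[1]], "")[[1]]) / 100000
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("genotype simulation: dosage law, edge cases, determinism", {
  cfg <- tiny_sim_config(genome_length = 2000L, n_chromosomes = 2L,
                         n_individuals = 10000L, n_snps = 5L,
                         maf_range = c(0.5, 0.5))
  ref <- simulate_reference(cfg)
  g <- simulate_genotypes(cfg, ref)
  expect_true(all(abs(colMeans(g$genotypes) - 1.0) < 0.03))  # E[dosage] = 2p
  expect_false(any(duplicated(paste(g$snps$chrom, g$snps$pos))))
  expect_true(all(g$snps$ref != g$snps$alt))
  one <- tiny_sim_config(n_individuals = 1L, n_snps = 50L)
  g1 <- simulate_genotypes(one, simulate_reference(one))
  expect_equal(nrow(g1$genotypes), 1L)
  expect_true(all(g1$genotypes %in% 0:2))
  expect_identical(simulate_genotypes(cfg, ref)$genotypes, g$genotypes)
  too_many <- tiny_sim_config(genome_length = 10L, n_chromosomes = 1L,
                              n_snps = 50L)
  expect_error(simulate_genotypes(too_many, simulate_reference(too_many)),
               "exceeds")
})

test_that("plant_effects: count law, eligibility, effect size distribution", {
  cfg <- tiny_sim_config(genome_length = 30000L, n_chromosomes = 2L,
                         n_elements = 10L, element_window = 2000L,
                         n_snps = 4000L, causal_fraction = 0.8,
                         quantity_effect_sd = 0.5)
  ref <- simulate_reference(cfg)
  g <- simulate_genotypes(cfg, ref)
  elements <- dipcap:::place_elements(cfg)
  eff <- plant_effects(cfg, g$snps, elements)
  # eligibility oracle: SNP within element_window/2 of some same-chrom center
  eligible <- vapply(seq_len(nrow(g$snps)), function(i) {
    any(elements$chrom == g$snps$chrom[i] &
          abs(elements$center - g$snps$pos[i]) <= cfg$element_window %/% 2L)
  }, logical(1))
  expect_equal(nrow(eff), round(0.8 * sum(eligible)))
  expect_true(all(eff$snp_id %in% g$snps$snp_id[eligible]))
  expect_gt(nrow(eff), 500)  # enough draws for the sd check
  expect_lt(abs(sd(eff$quantity_log2fc_per_allele) - 0.5), 0.05)
  # causal_fraction limits
  none <- plant_effects(tiny_sim_config(causal_fraction = 0), g$snps, elements)
  expect_equal(nrow(none), 0L)
  all_eff <- plant_effects(
    tiny_sim_config(genome_length = 30000L, n_chromosomes = 2L,
                    n_elements = 10L, element_window = 2000L,
                    n_snps = 4000L, causal_fraction = 1),
    g$snps, elements)
  expect_equal(nrow(all_eff), sum(eligible))
})

make_coverage_inputs <- function(cfg, n_ind, dosages, q_fc = 0, d_logit = 0) {
  elements <- data.frame(element_id = "el0001", chrom = "chr1",
                         center = 1000L, plus_mode = 1055L,
                         minus_mode = 945L, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "snp00001", chrom = "chr1", pos = 1000L,
                     ref = "A", alt = "G", af = 0.5,
                     stringsAsFactors = FALSE)
  genotypes <- matrix(dosages, ncol = 1,
                      dimnames = list(sprintf("D%03d", seq_len(n_ind)),
                                      "snp00001"))
  libraries <- data.frame(library_id = sprintf("L%03d", seq_len(n_ind)),
                          donor_id = rownames(genotypes),
                          stringsAsFactors = FALSE)
  effects <- if (q_fc != 0 || d_logit != 0) {
    data.frame(snp_id = "snp00001", element_id = "el0001",
               quantity_log2fc_per_allele = q_fc,
               directionality_logit_per_allele = d_logit,
               stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(0), element_id = character(0),
               quantity_log2fc_per_allele = numeric(0),
               directionality_logit_per_allele = numeric(0))
  }
  list(elements = elements, snps = snps, genotypes = genotypes,
       libraries = libraries, effects = effects)
}

test_that("coverage: noiseless limit, quantity ratio, strand allocation", {
  # noiseless limit: no effects, Poisson at huge rate -> totals within 1%
  cfg <- tiny_sim_config(genome_length = 2000L, n_chromosomes = 1L,
                         dispersion = 0, base_rate_meanlog = log(1e6),
                         base_rate_sdlog = 0, base_logit_sd = 0)
  inp <- make_coverage_inputs(cfg, 5L, rep(1L, 5))
  cov <- simulate_coverage(cfg, inp$elements, inp$effects, inp$snps,
                           inp$genotypes, inp$libraries)
  totals <- rowSums(cov[[1]]$plus) + rowSums(cov[[1]]$minus)
  expect_true(all(abs(totals - 1e6) / 1e6 < 0.01))

  # quantity effect: log2FC = 1 per allele -> dosage-2 / dosage-0 ratio ~ 4
  cfg2 <- tiny_sim_config(genome_length = 2000L, n_chromosomes = 1L,
                          dispersion = 0.1, base_rate_meanlog = log(2000),
                          base_rate_sdlog = 0, base_logit_sd = 0)
  dos <- rep(c(0L, 2L), each = 100L)
  inp2 <- make_coverage_inputs(cfg2, 200L, dos, q_fc = 1.0)
  cov2 <- simulate_coverage(cfg2, inp2$elements, inp2$effects, inp2$snps,
                            inp2$genotypes, inp2$libraries)
  totals2 <- rowSums(cov2[[1]]$plus) + rowSums(cov2[[1]]$minus)
  ratio <- mean(totals2[dos == 2]) / mean(totals2[dos == 0])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)

  # directionality effect: logit +2 per allele, base 0 -> plus share ~ 0.982
  inp3 <- make_coverage_inputs(cfg2, 200L, dos, d_logit = 2.0)
  cov3 <- simulate_coverage(cfg2, inp3$elements, inp3$effects, inp3$snps,
                            inp3$genotypes, inp3$libraries)
  plus_frac <- rowSums(cov3[[1]]$plus) /
    (rowSums(cov3[[1]]$plus) + rowSums(cov3[[1]]$minus))
  expect_gt(mean(plus_frac[dos == 2]), 0.8)
  expect_lt(abs(mean(plus_frac[dos == 0]) - 0.5), 0.05)
  # counts are nonnegative integers
  expect_true(all(cov3[[1]]$plus >= 0) && all(cov3[[1]]$plus == round(cov3[[1]]$plus)))
})

test_that("generator-level effect recovery: dosage regression finds the planted slope", {
  # the 2-standard-error interval covers the truth ~95% of the time by
  # construction, so require coverage in at least 2 of 3 independent panels
  covered <- 0L
  for (s in 1:3) {
    cfg <- tiny_sim_config(genome_length = 2000L, n_chromosomes = 1L,
                           dispersion = 0.1, base_rate_meanlog = log(2000),
                           base_rate_sdlog = 0, base_logit_sd = 0,
                           seed = 40L + s)
    set.seed(420 + s)
    dos <- sample(0:2, 150L, replace = TRUE)
    inp <- make_coverage_inputs(cfg, 150L, dos, q_fc = 0.6)
    cov <- simulate_coverage(cfg, inp$elements, inp$effects, inp$snps,
                             inp$genotypes, inp$libraries)
    totals <- rowSums(cov[[1]]$plus) + rowSums(cov[[1]]$minus)
    fit <- summary(lm(log2(totals) ~ dos))
    slope <- fit$coefficients["dos", "Estimate"]
    se <- fit$coefficients["dos", "Std. Error"]
    if (abs(slope - 0.6) < 2 * se) covered <- covered + 1L
  }
  expect_gte(covered, 2L)
})

test_that("the full panel is seed-deterministic and respects invariants", {
  cfg <- tiny_sim_config()
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$reference, p2$reference)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$coverage[[3]]$plus, p2$coverage[[3]]$plus)
  expect_identical(p1$effects, p2$effects)
  expect_true(all(p1$genotypes %in% 0:2))
  # every element has one peak per strand at the configured spacing
  expect_equal(nrow(p1$peaks), 2L * nrow(p1$elements))
  spacing <- p1$elements$plus_mode - p1$elements$minus_mode
  expect_true(all(spacing == cfg$element_spacing))
  # planted effects reference SNPs within their element window
  for (i in seq_len(nrow(p1$effects))) {
    snp <- p1$snps[p1$snps$snp_id == p1$effects$snp_id[i], ]
    el <- p1$elements[p1$elements$element_id == p1$effects$element_id[i], ]
    expect_lte(abs(snp$pos - el$center), cfg$element_window %/% 2L)
    expect_identical(snp$chrom, el$chrom)
  }
})

test_that("isogenic replicate libraries share donor genotypes", {
  cfg <- tiny_sim_config(n_isogenic = 2L)
  p <- simulate_panel(cfg)
  expect_equal(nrow(p$libraries), cfg$n_individuals + 2L)
  expect_lt(length(unique(p$libraries$donor_id)), nrow(p$libraries))
})
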