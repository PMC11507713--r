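#' Configuration for the synthetic diploid panel generator
#'
#' The generator emulates the statistical structure of a panel of diploid
#' individuals with strand-specific, base-resolution transcription
#' initiation coverage: a panel of donors carrying biallelic SNPs at given
#' allele frequencies; divergently transcribed initiation elements whose
#' opposing-strand modes sit `element_spacing` bp apart (~110 bp in real
#' elements); planted quantity-modulating (tiQTL-like) and
#' directionality-modulating (diQTL-like) per-allele effects; and
#' negative-binomial count noise with a logistic strand allocation.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param n_individuals Number of genetically distinct donors.
#' @param n_elements Number of divergent initiation elements (distributed
#'   round-robin across chromosomes).
#' @param element_spacing bp between the opposing-strand initiation modes
#'   (default 110).
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Allele-frequency range, within (0, 0.5].
#' @param causal_fraction Fraction of eligible SNPs (those inside an element
#'   window) given planted effects.
#' @param quantity_effect_sd SD of per-allele log2 fold changes on element
#'   totals.
#' @param directionality_effect_sd SD of per-allele logit shifts on the
#'   plus-strand allocation.
#' @param dispersion Negative-binomial overdispersion of element totals
#'   (variance `mu + dispersion * mu^2`); 0 gives Poisson noise.
#' @param element_window bp window around each element center defining SNP
#'   eligibility for planted effects and the span of stored coverage
#'   (default 1000).
#' @param base_rate_meanlog,base_rate_sdlog Log-normal parameters of
#'   per-element expected totals (gives quantity prediction dynamic range).
#' @param base_rate_gc_coef Weight of the sequence-determined component of
#'   the log expected total: the standardized GC content of the central
#'   `gc_window` bp around the element center, scaled by this coefficient,
#'   is added to the log rate. This gives element quantity a learnable,
#'   sequence-driven component that generalizes across loci (as real core
#'   promoter strength does); set to 0 for pure log-normal noise.
#' @param gc_window Width (bp) of the GC window for the sequence component.
#' @param gc_shape_coef Coupling of initiation bump sharpness to the same
#'   GC latent: the per-element bump SD is
#'   `bump_sd * exp(-gc_shape_coef * z_gc)`, so GC-rich elements have
#'   sharper initiation modes (as real CpG-rich promoters do). This makes
#'   the sequence factor behind element quantity visible to the profile
#'   loss as well; set to 0 to decouple shape from sequence.
#' @param base_logit_sd SD of per-element baseline strand-allocation logits.
#' @param bump_sd SD (bp) of the discretized Gaussian initiation bump on
#'   each strand.
#' @param peak_halfwidth Half-width (bp) of emitted unidirectional peak
#'   calls around each mode.
#' @param n_isogenic Number of extra libraries that are isogenic replicates
#'   of randomly chosen donors (same genotypes, independent noise).
#' @param seed Integer seed; all generator output is a deterministic
#'   function of the configuration including this seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 20000L, n_chromosomes = 10L,
                       n_individuals = 40L, n_elements = 200L,
                       element_spacing = 110L, n_snps = 2000L,
                       maf_range = c(0.05, 0.5), causal_fraction = 0.25,
                       quantity_effect_sd = 0.4,
                       directionality_effect_sd = 0.5, dispersion = 0.2,
                       element_window = 1000L,
                       base_rate_meanlog = log(1000), base_rate_sdlog = 0.5,
                       base_rate_gc_coef = 1.2, gc_window = 200L,
                       gc_shape_coef = 0.25,
                       base_logit_sd = 0.5, bump_sd = 15, peak_halfwidth = 25L,
                       n_isogenic = 0L, seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_individuals = as.integer(n_individuals),
    n_elements = as.integer(n_elements),
    element_spacing = as.integer(element_spacing),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    causal_fraction = as.numeric(causal_fraction),
    quantity_effect_sd = as.numeric(quantity_effect_sd),
    directionality_effect_sd = as.numeric(directionality_effect_sd),
    dispersion = as.numeric(dispersion),
    element_window = as.integer(element_window),
    base_rate_meanlog = as.numeric(base_rate_meanlog),
    base_rate_sdlog = as.numeric(base_rate_sdlog),
    base_rate_gc_coef = as.numeric(base_rate_gc_coef),
    gc_window = as.integer(gc_window),
    gc_shape_coef = as.numeric(gc_shape_coef),
    base_logit_sd = as.numeric(base_logit_sd),
    bump_sd = as.numeric(bump_sd),
    peak_halfwidth = as.integer(peak_halfwidth),
    n_isogenic = as.integer(n_isogenic),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      genome_length > 0, n_chromosomes > 0, n_individuals > 0,
      n_elements > 0, element_spacing > 0, n_snps > 0,
      length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
      maf_range[1] <= maf_range[2],
      causal_fraction >= 0, causal_fraction <= 1,
      dispersion >= 0, element_window > element_spacing,
      bump_sd > 0, n_isogenic >= 0
    )
  })
  class(cfg) <- "sim_config"
  cfg
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

#' Simulate a random reference genome
#'
#' Uniform-random A/C/G/T strings, one per chromosome, reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sim_chrom_names(config)
  setNames(vapply(chroms, function(ch) {
    paste0(sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE),
           collapse = "")
  }, character(1)), chroms)
}

#' Simulate biallelic SNP genotypes for a donor panel
#'
#' SNP positions are drawn uniformly without replacement across the genome;
#' each SNP gets an allele frequency uniform in `maf_range` and per-donor
#' dosages are binomial(2, af), i.e. Hardy-Weinberg with no linkage
#' disequilibrium. Genotypes are unphased dosages (0/1/2 copies of the
#' alternate allele).
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List with `snps` (data.frame: `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `af`) and `genotypes` (donors x SNPs integer dosage
#'   matrix, rownames = donor ids).
#' @export
simulate_genotypes <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  space <- config$genome_length * config$n_chromosomes
  if (config$n_snps > space) {
    stop("n_snps exceeds the number of available genomic positions")
  }
  set.seed(config$seed + 1L)
  chroms <- sim_chrom_names(config)
  idx <- sort(sample.int(space, config$n_snps))
  chrom <- chroms[(idx - 1L) %/% config$genome_length + 1L]
  pos <- (idx - 1L) %% config$genome_length  # 0-based
  ref_base <- vapply(seq_along(idx), function(i) {
    substr(reference[[chrom[i]]], pos[i] + 1L, pos[i] + 1L)
  }, character(1))
  alt_base <- vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
  af <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  donors <- sprintf("D%03d", seq_len(config$n_individuals))
  geno <- matrix(
    rbinom(config$n_individuals * config$n_snps, 2L,
           rep(af, each = config$n_individuals)),
    nrow = config$n_individuals,
    dimnames = list(donors, sprintf("snp%05d", seq_len(config$n_snps)))
  )
  list(
    snps = data.frame(
      snp_id = colnames(geno), chrom = chrom, pos = pos,
      ref = ref_base, alt = alt_base, af = af, stringsAsFactors = FALSE
    ),
    genotypes = geno
  )
}

# deterministic element placement: round-robin across chromosomes, evenly
# spaced with a margin wide enough for the element window
place_elements <- function(config) {
  chroms <- sim_chrom_names(config)
  per_chrom <- table(factor(
    chroms[(seq_len(config$n_elements) - 1L) %% config$n_chromosomes + 1L],
    levels = chroms
  ))
  # margin leaves room for the model window plus jitter around edge elements
  margin <- config$element_window %/% 2L + 40L
  span <- config$genome_length - 2L * margin
  out <- lapply(chroms, function(ch) {
    k <- per_chrom[[ch]]
    if (k == 0L) return(NULL)
    if (span < (k - 1L) * config$element_window) {
      stop("genome_length too short for the requested element count/window")
    }
    centers <- if (k == 1L) margin + span %/% 2L else
      as.integer(round(margin + (seq_len(k) - 1L) * span / (k - 1L)))
    data.frame(chrom = ch, center = centers, stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, out)
  el$element_id <- sprintf("el%04d", seq_len(nrow(el)))
  half <- config$element_spacing %/% 2L
  el$minus_mode <- el$center - half
  el$plus_mode <- el$center + (config$element_spacing - half)
  el[, c("element_id", "chrom", "center", "plus_mode", "minus_mode")]
}

#' Plant variant effects at eligible SNPs
#'
#' Eligible SNPs are those lying within the element window
#' (`element_window` bp centered on an element's center, same chromosome).
#' Exactly `round(causal_fraction * n_eligible)` SNPs receive effects; each
#' planted SNP gets a per-allele quantity effect (log2 fold change on the
#' element total, tiQTL-like) and a per-allele directionality effect (shift
#' of the plus-strand allocation logit, diQTL-like), both drawn
#' `Normal(0, sd)` with the configured SDs.
#'
#' @param config A [sim_config()].
#' @param snps SNP table from [simulate_genotypes()].
#' @param elements Element table (as produced internally by
#'   [simulate_panel()]).
#' @return data.frame: `snp_id`, `element_id`, `quantity_log2fc_per_allele`,
#'   `directionality_logit_per_allele`.
#' @export
plant_effects <- function(config, snps, elements) {
  stopifnot(inherits(config, "sim_config"))
  half <- config$element_window %/% 2L
  # nearest element on the same chromosome, if within the window
  assign_el <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    hit <- snps$chrom == el$chrom & abs(snps$pos - el$center) <= half
    d_new <- abs(snps$pos - el$center)
    cur <- assign_el
    take <- hit & (is.na(cur) |
      d_new < abs(snps$pos - elements$center[match(cur, elements$element_id)]))
    assign_el[take] <- el$element_id
  }
  eligible <- which(!is.na(assign_el))
  n_eff <- round(config$causal_fraction * length(eligible))
  set.seed(config$seed + 2L)
  chosen <- if (n_eff > 0) sort(sample(eligible, n_eff)) else integer(0)
  data.frame(
    snp_id = snps$snp_id[chosen],
    element_id = assign_el[chosen],
    quantity_log2fc_per_allele = rnorm(n_eff, 0, config$quantity_effect_sd),
    directionality_logit_per_allele =
      rnorm(n_eff, 0, config$directionality_effect_sd),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-library strand-specific initiation coverage
#'
#' For each element and library, the expected total is
#' `base_rate * 2^(sum dosage * quantity_log2fc)` over the element's planted
#' SNPs; the realized total is negative-binomial (Poisson when
#' `dispersion = 0`). The plus-strand share is
#' `plogis(base_logit + sum dosage * directionality_logit)`; read positions
#' are drawn from discretized Gaussians (sd `bump_sd`) centered on the two
#' opposing-strand modes.
#'
#' @param config A [sim_config()].
#' @param elements Element table.
#' @param effects Planted effects from [plant_effects()].
#' @param snps SNP table.
#' @param genotypes Donor x SNP dosage matrix.
#' @param libraries data.frame with `library_id`, `donor_id`.
#' @param reference Optional named chromosome sequences; when supplied and
#'   `base_rate_gc_coef != 0`, the sequence-determined (GC) component of
#'   the element rates is active.
#' @return List per element: `window` (a `genomic_window` of
#'   `element_window` bp around the center), `plus` and `minus` (libraries x
#'   width integer count matrices, rownames = library ids).
#' @export
simulate_coverage <- function(config, elements, effects, snps, genotypes,
                              libraries, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  W <- config$element_window
  half <- W %/% 2L
  nlib <- nrow(libraries)
  n_el <- nrow(elements)
  gc_z <- numeric(n_el)
  if (!is.null(reference)) {
    gw <- config$gc_window
    gc_z <- vapply(seq_len(n_el), function(i) {
      s <- substr(reference[[elements$chrom[i]]],
                  elements$center[i] - gw %/% 2L + 1L,
                  elements$center[i] + gw %/% 2L)
      gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
      # standardize against the uniform-sequence null: gc ~ N(0.5, 0.25/gw)
      (gc - 0.5) / sqrt(0.25 / gw)
    }, numeric(1))
  }
  base_rate <- exp(config$base_rate_meanlog +
                     config$base_rate_gc_coef * gc_z +
                     rnorm(n_el, 0, config$base_rate_sdlog))
  bump_sd_el <- config$bump_sd * exp(-config$gc_shape_coef * gc_z)
  base_logit <- rnorm(n_el, 0, config$base_logit_sd)
  out <- vector("list", n_el)
  names(out) <- elements$element_id
  for (i in seq_len(n_el)) {
    el <- elements[i, ]
    eff <- effects[effects$element_id == el$element_id, , drop = FALSE]
    log2fc <- numeric(nlib)
    dlogit <- numeric(nlib)
    if (nrow(eff)) {
      dos <- genotypes[libraries$donor_id, eff$snp_id, drop = FALSE]
      log2fc <- as.numeric(dos %*% eff$quantity_log2fc_per_allele)
      dlogit <- as.numeric(dos %*% eff$directionality_logit_per_allele)
    }
    mu <- base_rate[i] * 2^log2fc
    total <- if (config$dispersion <= 1e-12) rpois(nlib, mu) else
      rnbinom(nlib, mu = mu, size = 1 / config$dispersion)
    p_plus <- plogis(base_logit[i] + dlogit)
    n_plus <- rbinom(nlib, total, p_plus)
    n_minus <- total - n_plus
    start <- el$center - half
    plus <- matrix(0L, nlib, W, dimnames = list(libraries$library_id, NULL))
    minus <- plus
    for (l in seq_len(nlib)) {
      if (n_plus[l] > 0) {
        ppos <- pmin(pmax(round(rnorm(n_plus[l], el$plus_mode,
                                      bump_sd_el[i])), start), start + W - 1L)
        plus[l, ] <- tabulate(ppos - start + 1L, nbins = W)
      }
      if (n_minus[l] > 0) {
        mpos <- pmin(pmax(round(rnorm(n_minus[l], el$minus_mode,
                                      bump_sd_el[i])), start), start + W - 1L)
        minus[l, ] <- tabulate(mpos - start + 1L, nbins = W)
      }
    }
    out[[i]] <- list(
      window = structure(list(chromosome = el$chrom, start = as.integer(start),
                              end = as.integer(start + W), width = W),
                         class = "genomic_window"),
      plus = plus, minus = minus
    )
  }
  out
}

#' Simulate a complete diploid panel
#'
#' Orchestrates [simulate_reference()], [simulate_genotypes()], element
#' placement, [plant_effects()] and [simulate_coverage()] into a single
#' `sim_panel` object carrying everything downstream stages need: the
#' reference genome, donor genotypes, per-library coverage windows, the
#' planted-effect truth table, and unidirectional peak calls per strand.
#'
#' @param config A [sim_config()].
#' @return A `sim_panel` object.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  reference <- simulate_reference(config)
  geno <- simulate_genotypes(config, reference)
  elements <- place_elements(config)
  effects <- plant_effects(config, geno$snps, elements)
  donors <- rownames(geno$genotypes)
  libraries <- data.frame(
    library_id = sprintf("L%03d", seq_len(config$n_individuals)),
    donor_id = donors, stringsAsFactors = FALSE
  )
  if (config$n_isogenic > 0) {
    set.seed(config$seed + 4L)
    dup <- sample(donors, config$n_isogenic, replace = config$n_isogenic >
                    length(donors))
    libraries <- rbind(libraries, data.frame(
      library_id = sprintf("L%03d", config$n_individuals +
                             seq_len(config$n_isogenic)),
      donor_id = dup, stringsAsFactors = FALSE
    ))
  }
  coverage <- simulate_coverage(config, elements, effects, geno$snps,
                                geno$genotypes, libraries,
                                reference = reference)
  ph <- config$peak_halfwidth
  peaks <- rbind(
    data.frame(chrom = elements$chrom, start = elements$plus_mode - ph,
               end = elements$plus_mode + ph + 1L,
               name = paste0(elements$element_id, "_plus"), score = 0L,
               strand = "+", summit = elements$plus_mode,
               stringsAsFactors = FALSE),
    data.frame(chrom = elements$chrom, start = elements$minus_mode - ph,
               end = elements$minus_mode + ph + 1L,
               name = paste0(elements$element_id, "_minus"), score = 0L,
               strand = "-", summit = elements$minus_mode,
               stringsAsFactors = FALSE)
  )
  structure(
    list(config = config, reference = reference,
         chrom_lengths = setNames(rep(config$genome_length,
                                      config$n_chromosomes),
                                  sim_chrom_names(config)),
         snps = geno$snps, genotypes = geno$genotypes,
         libraries = libraries, elements = elements, effects = effects,
         coverage = coverage, peaks = peaks),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d chrom x %d bp; %d donors (%d libraries); %d elements; %d SNPs (%d with planted effects)\n",
    x$config$n_chromosomes, x$config$genome_length,
    x$config$n_individuals, nrow(x$libraries), nrow(x$elements),
    nrow(x$snps), nrow(x$effects)))
  invisible(x)
}

# raw per-library totals across all element windows, both strands
library_totals <- function(panel, library_ids = NULL) {
  libs <- if (is.null(library_ids)) panel$libraries$library_id else library_ids
  tot <- setNames(numeric(length(libs)), libs)
  for (cov in panel$coverage) {
    tot <- tot + rowSums(cov$plus[libs, , drop = FALSE]) +
      rowSums(cov$minus[libs, , drop = FALSE])
  }
  tot
}

#' Write a simulated panel to standard file formats
#'
#' Reference as FASTA; genotypes as a minimal unphased VCF (GT field,
#' `0/1` notation); coverage as two bedGraph files per library (plus/minus
#' strand); peaks as 6-column BED; the planted-effect truth table as TSV.
#'
#' @param panel A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sim_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             vcf = file.path(dir, "genotypes.vcf"),
             bed = file.path(dir, "peaks.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(panel$reference, paths[["fasta"]])
  write_vcf_snps(paths[["vcf"]], panel$snps, panel$genotypes)
  write_bed6(panel$peaks, paths[["bed"]])
  write.table(panel$effects, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  covdir <- file.path(dir, "coverage")
  dir.create(covdir, showWarnings = FALSE)
  for (lib in panel$libraries$library_id) {
    for (strand in c("plus", "minus")) {
      df <- do.call(rbind, lapply(panel$coverage, function(cov) {
        v <- cov[[strand]][lib, ]
        nz <- which(v != 0)
        if (!length(nz)) return(NULL)
        data.frame(chrom = cov$window$chromosome,
                   start = cov$window$start + nz - 1L,
                   end = cov$window$start + nz, value = v[nz])
      }))
      p <- file.path(covdir, sprintf("%s_%s.bedGraph", lib, strand))
      write_bedgraph(df, p)
      paths[[paste(lib, strand, sep = "_")]] <- p
    }
  }
  invisible(paths)
}
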