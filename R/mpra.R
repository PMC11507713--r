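# A synthetic stand-in for a reporter plasmid backbone. The real minimal
# promoter plasmid sequence is not shipped; this synthetic backbone carries
# a canonical TATA-box minimal promoter (TATA box + initiator) at a known
# offset and is sufficient for testing the construct-assembly and variant
# scoring machinery. A real backbone can be supplied as FASTA.
SYNTHETIC_MINP <- paste0(
  "GGGTATATAATGGAAGCTCGACTTCCAG",  # TATA box context
  "CTTGGCATCCGGTCACTC"             # initiator-like downstream
)

#' Synthetic reporter backbone (labelled synthetic)
#'
#' Generates a random-sequence plasmid-like backbone with the synthetic
#' minimal TATA promoter embedded at `promoter_offset`. This is a
#' stand-in for a real reporter backbone, which can be supplied instead as
#' a FASTA file; all coordinates are 1-based within the backbone.
#'
#' @param length Total backbone length in bp (default 4000).
#' @param promoter_offset 1-based position where the minimal promoter
#'   starts (default 2001); the tested oligo is inserted directly upstream
#'   of this position.
#' @param seed Seed for the random padding sequence.
#' @return List with `sequence`, `promoter_offset`, `promoter_width`.
#' @export
synthetic_backbone <- function(length = 4000L, promoter_offset = 2001L,
                               seed = 7L) {
  length <- as.integer(length)
  pw <- nchar(SYNTHETIC_MINP)
  stopifnot(promoter_offset + pw - 1L <= length, promoter_offset > 1L)
  set.seed(as.integer(seed))
  pad <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  seq <- paste0(pad, collapse = "")
  substr(seq, promoter_offset, promoter_offset + pw - 1L) <- SYNTHETIC_MINP
  list(sequence = seq, promoter_offset = as.integer(promoter_offset),
       promoter_width = pw)
}

#' Assemble a reporter construct around a tested oligo
#'
#' Inserts a 200 bp oligonucleotide directly upstream of the backbone's
#' minimal promoter, then extracts a window of `input_length` bp containing
#' the insert and the promoter, padded on both sides by backbone sequence.
#' By default the oligo is centered in the window; `oligo_center_offset`
#' shifts the window (positive values move the oligo left of center).
#' Reference and alternate constructs for the same SNP are identical
#' outside the oligo span. Re-assembly with a larger `input_length` (e.g. a
#' longer-context model) pads further from the backbone.
#'
#' @param oligo_seq The tested oligo sequence (must be `oligo_length` bp).
#' @param backbone A [synthetic_backbone()] (or list with `sequence` and
#'   `promoter_offset`).
#' @param input_length Model input window length (default 1000).
#' @param oligo_center_offset Shift of the window relative to centering the
#'   oligo (default 0).
#' @param oligo_length Required oligo length (default 200).
#' @return A `reporter_construct`: list with `sequence` (length
#'   `input_length`) and `oligo_span` (1-based start/end of the insert
#'   within the window).
#' @export
assemble_construct <- function(oligo_seq, backbone, input_length = 1000L,
                               oligo_center_offset = 0L,
                               oligo_length = 200L) {
  if (nchar(oligo_seq) != oligo_length) {
    stop(sprintf("oligo must be %d bp (got %d)", oligo_length,
                 nchar(oligo_seq)))
  }
  bs <- backbone$sequence
  po <- backbone$promoter_offset
  full <- paste0(substr(bs, 1L, po - 1L), oligo_seq,
                 substr(bs, po, nchar(bs)))
  oligo_start_full <- po  # insert occupies [po, po + oligo_length - 1]
  oligo_mid <- oligo_start_full + oligo_length %/% 2L
  win_start <- oligo_mid - input_length %/% 2L + as.integer(oligo_center_offset)
  win_end <- win_start + input_length - 1L
  if (win_start < 1L || win_end > nchar(full)) {
    stop("backbone too short to pad the construct to input_length")
  }
  structure(list(
    sequence = substr(full, win_start, win_end),
    oligo_span = c(start = oligo_start_full - win_start + 1L,
                   end = oligo_start_full - win_start + oligo_length)
  ), class = "reporter_construct")
}

#' Predicted SNP effect from a reporter construct pair
#'
#' Runs the model on the reference and alternate constructs (encoded as
#' homozygous two-hot sequence) and returns
#' `log2((quantity_alt + pseudocount) / (quantity_ref + pseudocount))`:
#' positive values mean the alternate allele increases predicted
#' initiation. Swapping the alleles negates the score.
#'
#' @param object A `dipcap_model` or `dipcap_ensemble`.
#' @param ref_construct,alt_construct `reporter_construct`s of equal
#'   length.
#' @param pseudocount Stabilizer inside the ratio (default 1e-6).
#' @return Signed log2 fold change.
#' @export
predict_snp_effect <- function(object, ref_construct, alt_construct,
                               pseudocount = 1e-6) {
  sref <- ref_construct$sequence
  salt <- alt_construct$sequence
  if (nchar(sref) != nchar(salt)) stop("constructs must have equal length")
  X <- array(0, dim = c(2L, nchar(sref), 4L))
  X[1L, , ] <- two_hot_encode(sref)
  X[2L, , ] <- two_hot_encode(salt)
  pred <- predict(object, X)
  log2((pred$quantity[2] + pseudocount) / (pred$quantity[1] + pseudocount))
}

#' Precision-recall curve for emVar classification
#'
#' Uses the squared SNP effect score as the classifier score (an effect in
#' either direction marks an expression-modulating variant). The area under
#' the curve is the average-precision summation: `sum((R_i - R_{i-1}) *
#' P_i)` over distinct score thresholds (tied scores collapse to one
#' threshold). Perfectly separated scores give auPRC 1; a constant score
#' gives the positive-class prevalence.
#'
#' @param scores Signed per-SNP predicted effects.
#' @param labels Logical (or 0/1) emVar indicator.
#' @return List with `auprc` and `curve` (data.frame `threshold`,
#'   `precision`, `recall`).
#' @export
emvar_prc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a precision-recall curve")
  }
  s2 <- scores^2
  ord <- order(-s2)
  s2 <- s2[ord]
  y <- labels[ord]
  npos <- sum(y)
  # collapse tied scores: cumulative counts at the last index of each group
  last <- which(!duplicated(s2, fromLast = TRUE))
  tp <- cumsum(y)[last]
  n_at <- seq_along(y)[last]
  precision <- tp / n_at
  recall <- tp / npos
  auprc <- sum(diff(c(0, recall)) * precision)
  list(auprc = auprc,
       curve = data.frame(threshold = s2[last], precision = precision,
                          recall = recall))
}

#' Bootstrap auPRC differences against a reference model
#'
#' Resamples SNPs with replacement `n_boot` times (the same resample is
#' applied to every model's scores), recomputes each model's auPRC, and
#' returns the per-bootstrap difference `auPRC(other) - auPRC(reference)`.
#' The one-sided empirical p-value per model is the fraction of bootstraps
#' with a difference >= 0 (testing whether the other model matches or beats
#' the reference). Resamples containing a single class are redrawn, with a
#' logged count.
#'
#' @param score_sets Named list of score vectors, all aligned to the same
#'   SNPs.
#' @param labels emVar indicator.
#' @param reference Name of the reference model in `score_sets`.
#' @param n_boot Number of bootstraps (default 1000).
#' @param seed Seed.
#' @return List: `delta` (n_boot x other-models matrix), `p` (named,
#'   one-sided), `auprc` (point estimates), `n_redrawn`.
#' @export
bootstrap_delta_auprc <- function(score_sets, labels, reference,
                                  n_boot = 1000L, seed = 1L) {
  stopifnot(reference %in% names(score_sets))
  labels <- as.logical(labels)
  n <- length(labels)
  stopifnot(all(vapply(score_sets, length, integer(1)) == n))
  others <- setdiff(names(score_sets), reference)
  set.seed(as.integer(seed))
  delta <- matrix(NA_real_, n_boot, length(others),
                  dimnames = list(NULL, others))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && !all(labels[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    ref_auprc <- emvar_prc(score_sets[[reference]][idx], labels[idx])$auprc
    for (m in others) {
      delta[b, m] <- emvar_prc(score_sets[[m]][idx], labels[idx])$auprc -
        ref_auprc
    }
  }
  if (n_redrawn > 0) {
    dipcap_log("bootstrap", sprintf("redrew %d single-class resample(s)",
                                    n_redrawn))
  }
  list(delta = delta,
       p = apply(delta, 2L, function(d) mean(d >= 0)),
       auprc = vapply(score_sets, function(s)
         emvar_prc(s, labels)$auprc, numeric(1)),
       n_redrawn = n_redrawn)
}

#' Agreement between predicted and observed variant effects
#'
#' Pearson correlation over paired log2 fold changes, plus the sign
#' mismatch fraction among pairs where both values are nonzero after
#' rounding at `zero_tol` (zero-valued pairs are excluded with a logged
#' count).
#'
#' @param predicted,observed Paired log2FC vectors.
#' @param zero_tol Rounding tolerance for "zero" (default 1e-8).
#' @return List: `pcc`, `sign_mismatch`, `n_used`, `n_excluded`.
#' @export
effect_agreement <- function(predicted, observed, zero_tol = 1e-8) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  nz <- round(predicted / zero_tol) != 0 & round(observed / zero_tol) != 0
  n_excluded <- sum(!nz)
  if (n_excluded > 0) {
    dipcap_log("mpra", sprintf(
      "%d pair(s) with a zero value excluded from sign comparison",
      n_excluded))
  }
  if (!any(nz)) stop("all pairs excluded: no nonzero predicted/observed pairs")
  list(pcc = cor(predicted, observed),
       sign_mismatch = mean(sign(predicted[nz]) != sign(observed[nz])),
       n_used = sum(nz), n_excluded = n_excluded)
}

#' Restrict MPRA variants to holdout (fold-0) chromosomes
#'
#' With a fold partition supplied, only SNPs on fold-0 chromosomes enter
#' the benchmark, avoiding leakage from variants seen in pretraining.
#'
#' @param snp_chroms Chromosome per SNP.
#' @param partition A [partition_folds()] result.
#' @return Logical vector: SNP is on a holdout chromosome.
#' @export
filter_holdout_snps <- function(snp_chroms, partition) {
  fold <- partition$assignment[snp_chroms]
  if (any(is.na(fold))) {
    stop("SNP chromosome(s) missing from the fold partition: ",
         paste(unique(snp_chroms[is.na(fold)]), collapse = ", "))
  }
  unname(fold == partition$holdout_fold)
}
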