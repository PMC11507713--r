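#' Two-hot encoding of an unphased diploid sequence
#'
#' Each position is represented as the sum of the one-hot encodings of its
#' two (unphased) alleles, so every row of the result sums to 2. Channel
#' order is A, C, G, T. A homozygous-reference position gives
#' `2 * onehot(ref)`; a heterozygous position with alternate-allele dosage 1
#' gives `onehot(ref) + onehot(alt)`; dosage 2 gives `2 * onehot(alt)`.
#' Unknown bases (`N`) encode as all-zero rows.
#'
#' @param ref Reference bases: a single string or a character vector, one
#'   base per position (A/C/G/T/N).
#' @param dosage Integer vector of alternate-allele copy counts per position
#'   (0, 1 or 2). Default: all zero (homozygous reference).
#' @param alt Character vector of alternate bases; required wherever
#'   `dosage > 0`.
#' @return An `L x 4` integer matrix with columns A, C, G, T.
#' @examples
#' two_hot_encode("ACGT")               # 2 * one-hot
#' two_hot_encode("AC", dosage = c(0, 1), alt = c(NA, "T"))
#' @export
two_hot_encode <- function(ref, dosage = NULL, alt = NULL) {
  if (length(ref) == 1L && nchar(ref[1]) > 1L) {
    ref <- strsplit(ref, "")[[1]]
  }
  ref <- toupper(ref)
  L <- length(ref)
  if (is.null(dosage)) dosage <- integer(L)
  if (length(dosage) != L) stop("dosage must have one entry per position")
  if (!all(dosage %in% 0:2)) stop("dosage must be 0, 1 or 2")
  if (is.null(alt)) alt <- rep(NA_character_, L)
  alt <- toupper(alt)
  if (any(dosage > 0 & (is.na(alt) | !alt %in% c("A", "C", "G", "T")))) {
    stop("an A/C/G/T alternate base is required wherever dosage > 0")
  }
  bad <- !ref %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("unknown base(s) in reference window: ",
         paste(unique(ref[bad]), collapse = ", "))
  }
  onehot_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, names(onehot_idx)))
  known <- ref != "N"
  ridx <- onehot_idx[ref[known]]
  m[cbind(which(known), ridx)] <- 2L - dosage[known]
  has_alt <- dosage > 0
  if (any(has_alt)) {
    aidx <- onehot_idx[alt[has_alt]]
    rows <- which(has_alt)
    m[cbind(rows, aidx)] <- m[cbind(rows, aidx)] + dosage[has_alt]
  }
  m
}

#' Two-hot encoding from IUPAC ambiguity codes
#'
#' Convenience encoder for diploid sequences written with IUPAC codes, where
#' an ambiguity code denotes a heterozygous position (e.g. `Y` = C/T, `R` =
#' A/G). The sequence `AYCR` therefore encodes as
#' `[[2,0,0,0],[0,1,0,1],[0,2,0,0],[1,0,1,0]]`.
#'
#' @param seq A string over A, C, G, T, N and the two-base IUPAC codes
#'   R, Y, S, W, K, M.
#' @return An `L x 4` integer matrix with columns A, C, G, T.
#' @examples
#' two_hot_encode_iupac("AYCR")
#' @export
two_hot_encode_iupac <- function(seq) {
  bases <- toupper(strsplit(seq, "")[[1]])
  alleles <- list(
    A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), N = character(0)
  )
  bad <- !bases %in% names(alleles)
  if (any(bad)) stop("unsupported IUPAC code(s): ",
                     paste(unique(bases[bad]), collapse = ", "))
  onehot_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(0L, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, names(onehot_idx)))
  for (i in seq_along(bases)) {
    for (a in alleles[[bases[i]]]) {
      m[i, onehot_idx[a]] <- m[i, onehot_idx[a]] + 1L
    }
  }
  m
}

#' Decode a two-hot matrix back to sequence
#'
#' Homozygous rows decode to the base itself, heterozygous rows to the
#' corresponding IUPAC ambiguity code, all-zero rows to `N`.
#'
#' @param m An `L x 4` two-hot matrix (columns A, C, G, T).
#' @return A character string of length-L.
#' @export
decode_two_hot <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  bases <- c("A", "C", "G", "T")
  code <- apply(m, 1L, function(row) {
    if (sum(row) == 0) return("N")
    if (any(row == 2)) return(bases[which(row == 2)])
    pair <- sort(bases[row == 1])
    iupac <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
    iupac[[paste0(pair, collapse = "")]]
  })
  paste0(code, collapse = "")
}

#' Mask variants (reference passthrough)
#'
#' Variant masking means ignoring an individual's genotypes: the model input
#' is the plain reference sequence, which two-hot encodes as homozygous
#' reference everywhere. The function exists to make the masking step of the
#' reference-training ablation explicit in pipelines; it validates the
#' variant positions and returns the reference window unchanged.
#'
#' @param reference_window Reference bases (string or character vector).
#' @param variant_positions Integer positions (1-based within the window) of
#'   variants being masked.
#' @return The reference window, unchanged.
#' @export
mask_variants <- function(reference_window, variant_positions = integer(0)) {
  L <- if (length(reference_window) == 1L) nchar(reference_window)
       else length(reference_window)
  if (length(variant_positions) &&
      (min(variant_positions) < 1L || max(variant_positions) > L)) {
    stop("variant positions outside the window")
  }
  reference_window
}

#' Extract a (jittered) genomic window
#'
#' Returns the half-open, 0-based window of `width` bp around `center`,
#' shifted by a jitter drawn uniformly from `-jitter_max..jitter_max`
#' (inclusive, integer). With `jitter_max = 0` the window is exactly
#' centered: `[center - width/2, center + width/2)`.
#'
#' @param chromosome Chromosome name.
#' @param center 0-based center position.
#' @param chrom_length Chromosome length in bp.
#' @param width Window width in bp (default 1000).
#' @param jitter_max Maximum absolute jitter in bp (default 250).
#' @return A `genomic_window`: list with `chromosome`, `start` (0-based
#'   inclusive), `end` (exclusive), `width`.
#' @export
extract_window <- function(chromosome, center, chrom_length, width = 1000L,
                           jitter_max = 250L) {
  width <- as.integer(width)
  jitter_max <- as.integer(jitter_max)
  stopifnot(width > 0, jitter_max >= 0)
  j <- if (jitter_max > 0) sample(seq.int(-jitter_max, jitter_max), 1L) else 0L
  start <- as.integer(center) - width %/% 2L + j
  end <- start + width
  if (start < 0L || end > chrom_length) {
    stop(sprintf("window [%d, %d) outside chromosome %s (length %d)",
                 start, end, chromosome, chrom_length))
  }
  structure(list(chromosome = chromosome, start = start, end = end,
                 width = width),
            class = "genomic_window")
}

peak_summit <- function(peaks) {
  if (!is.null(peaks$summit)) return(as.integer(peaks$summit))
  as.integer((peaks$start + peaks$end) %/% 2L)
}

# gap between nearest edges of two half-open intervals; 0 if they overlap
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Pair divergent unidirectional peaks into initiation elements
#'
#' Divergently transcribed regulatory elements consist of two opposing-strand
#' core promoters roughly 110 bp apart. A unidirectional peak is retained iff
#' a peak on the opposite strand of the same chromosome lies within
#' `max_distance` bp (gap between nearest interval edges, 0 for overlapping
#' peaks). One element is emitted per mutual-nearest retained pair, centered
#' at the midpoint of the two peak summits (summit = `summit` column when
#' present, otherwise the interval midpoint; nearest-peak ties resolve to
#' the leftmost).
#'
#' @param peaks A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), and optionally `summit`.
#' @param max_distance Maximum allowed gap in bp (default 200).
#' @return List with `elements` (data.frame `chrom`, `center`, `plus_idx`,
#'   `minus_idx`, `gap`; indices into `peaks`) and `keep` (logical, per
#'   input peak: has an opposite-strand partner within `max_distance`).
#' @export
pair_divergent_peaks <- function(peaks, max_distance = 200L) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(peaks)))
  n <- nrow(peaks)
  keep <- logical(n)
  summit <- peak_summit(peaks)
  elements <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch & peaks$strand == "+")
    mi <- which(peaks$chrom == ch & peaks$strand == "-")
    if (!length(pi) || !length(mi)) next
    gap <- outer(seq_along(pi), seq_along(mi), function(a, b) {
      interval_gap(peaks$start[pi[a]], peaks$end[pi[a]],
                   peaks$start[mi[b]], peaks$end[mi[b]])
    })
    within <- gap <= max_distance
    keep[pi] <- keep[pi] | apply(within, 1L, any)
    keep[mi] <- keep[mi] | apply(within, 2L, any)
    # mutual nearest neighbours (ties -> leftmost, i.e. smallest start)
    nearest_minus <- apply(gap, 1L, function(g) {
      cand <- which(g == min(g))
      cand[which.min(peaks$start[mi[cand]])]
    })
    nearest_plus <- apply(gap, 2L, function(g) {
      cand <- which(g == min(g))
      cand[which.min(peaks$start[pi[cand]])]
    })
    for (a in seq_along(pi)) {
      b <- nearest_minus[a]
      if (nearest_plus[b] == a && gap[a, b] <= max_distance) {
        elements[[length(elements) + 1L]] <- data.frame(
          chrom = ch,
          center = (summit[pi[a]] + summit[mi[b]]) %/% 2L,
          plus_idx = pi[a], minus_idx = mi[b], gap = gap[a, b]
        )
      }
    }
  }
  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(chrom = character(0), center = integer(0),
               plus_idx = integer(0), minus_idx = integer(0), gap = integer(0))
  list(elements = elements[order(elements$chrom, elements$center), ,
                           drop = FALSE],
       keep = keep)
}

#' Reads-per-million normalization
#'
#' Scales coverage so the library-wide total (across both strands) equals
#' one million. `x` may be a numeric vector/matrix or an arbitrarily nested
#' list of such (e.g. `list(plus = ..., minus = ...)` per window); the
#' normalization factor is computed from the grand total and applied to
#' every element, so windowing and normalization commute.
#'
#' @param x Coverage values (nonnegative).
#' @return `x` scaled by `1e6 / total`.
#' @export
rpm_normalize <- function(x) {
  total <- rpm_total(x)
  if (total <= 0) stop("cannot RPM-normalize a zero-total library")
  rpm_scale(x, 1e6 / total)
}

rpm_total <- function(x) {
  if (is.list(x)) sum(vapply(x, rpm_total, numeric(1))) else sum(x)
}

rpm_scale <- function(x, f) {
  if (is.list(x)) lapply(x, rpm_scale, f = f) else x * f
}
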