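#' Read / write FASTA
#'
#' Thin wrappers around Biostrings, returning plain named character vectors
#' so the rest of the package can use base string operations.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read biallelic SNPs from a VCF
#'
#' Restricted to biallelic SNVs: indels, multi-allelic and other records are
#' skipped, with the skip count logged. Genotypes are collapsed to unphased
#' alternate-allele dosages.
#'
#' @param path VCF file path.
#' @return List with `snps` (data.frame: `chrom`, `pos` 0-based, `ref`,
#'   `alt`), `genotypes` (samples x SNPs dosage matrix) and `n_skipped`.
#' @export
read_vcf_snps <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    dipcap_log("vcf", sprintf("skipped %d non-SNP/multi-allelic record(s)",
                              n_skipped))
  }
  vcf <- vcf[keep, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
  })
  list(
    snps = data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L,  # VCF is 1-based
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
      stringsAsFactors = FALSE
    ),
    genotypes = t(dosage),
    n_skipped = n_skipped
  )
}

#' Write a minimal unphased VCF of biallelic SNPs
#'
#' @param path Output path.
#' @param snps data.frame with `chrom`, `pos` (0-based), `ref`, `alt` and
#'   optionally `snp_id`.
#' @param genotypes Samples x SNPs dosage matrix (0/1/2), rownames = sample
#'   names, columns aligned with `snps` rows.
#' @export
write_vcf_snps <- function(path, snps, genotypes) {
  stopifnot(ncol(genotypes) == nrow(snps))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  ids <- if (!is.null(snps$snp_id)) snps$snp_id else
    sprintf("snp%05d", seq_len(nrow(snps)))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i] + 1L, ids[i], snps$ref[i], snps$alt[i],
            ".", "PASS", ".", "GT", gt_str[genotypes[, i] + 1L]),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write bedGraph coverage
#'
#' Four-column bedGraph (one file per strand), via rtracklayer.
#'
#' @param path File path.
#' @return `read_bedgraph`: data.frame `chrom`, `start` (0-based), `end`,
#'   `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param coverage data.frame with `chrom`, `start` (0-based), `end`,
#'   `value`.
#' @export
write_bedgraph <- function(coverage, path) {
  if (is.null(coverage) || nrow(coverage) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    coverage$chrom,
    IRanges::IRanges(start = coverage$start + 1L, end = coverage$end),
    score = coverage$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write BED6 peak intervals
#'
#' @param path File path.
#' @return `read_bed6`: data.frame `chrom`, `start` (0-based half-open),
#'   `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else ".",
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed6
#' @param peaks data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
write_bed6 <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = peaks$strand
  )
  gr$name <- if (!is.null(peaks$name)) peaks$name else "."
  gr$score <- if (!is.null(peaks$score)) peaks$score else 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a TSV table
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Build and write a run manifest
#'
#' Records the command, a hash of the configuration, all seeds, checksums of
#' input files, the fold assignment and the package version — enough to
#' re-run a result exactly.
#'
#' @param command Command name.
#' @param config Configuration list (hashed into the manifest).
#' @param seeds Named list/vector of seeds used.
#' @param inputs Character vector of input file paths (checksummed if they
#'   exist).
#' @param fold_assignment Optional named fold assignment.
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(command, config = list(), seeds = list(),
                         inputs = character(0), fold_assignment = NULL,
                         path = NULL) {
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  checksums <- if (length(inputs)) {
    ex <- file.exists(inputs)
    setNames(ifelse(ex, tools::md5sum(inputs), NA_character_), inputs)
  } else NULL
  manifest <- list(
    command = command,
    config_hash = cfg_hash,
    seeds = seeds,
    input_checksums = as.list(checksums),
    fold_assignment = as.list(fold_assignment),
    version = as.character(utils::packageVersion("dipcap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(manifest))
  }
  manifest
}

#' Validate a run manifest
#'
#' Schema-lite check that the fields needed to re-run a result are present.
#'
#' @param manifest Manifest list (or path to a manifest JSON).
#' @return TRUE invisibly, or an error naming the missing field.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  required <- c("command", "config_hash", "seeds", "version")
  for (f in required) {
    if (is.null(manifest[[f]])) stop("manifest missing field: ", f)
  }
  invisible(TRUE)
}
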