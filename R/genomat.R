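#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# Call states are stored as an integer matrix: 0 = hom-ref, 1 = het,
# 2 = hom-alt, NA = missing. The four canonical GT strings are the only
# on-disk representation.
CALL_HOM_REF <- 0L
CALL_HET <- 1L
CALL_HOM_ALT <- 2L

#' Convert VCF GT strings to call codes
#'
#' Maps genotype strings to the four-state call encoding used throughout the
#' package: `0/0` to hom-ref (0), `0/1` or `1/0` to het (1), `1/1` to
#' hom-alt (2), and anything containing `.` or an allele index above 1 to
#' missing (`NA`). Phased separators (`|`) are accepted and phase is
#' discarded; partially missing genotypes such as `./1` are coerced to
#' missing.
#'
#' @param gt character vector of GT fields.
#' @return integer vector of call codes (0, 1, 2 or `NA`).
#' @export
#' @examples
#' gt_to_call(c("0/0", "0/1", "1|0", "1/1", "./.", "./1"))
gt_to_call <- function(gt) {
  gt <- sub(":.*$", "", as.character(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- CALL_HOM_REF
  out[gt %in% c("0/1", "1/0")] <- CALL_HET
  out[gt == "1/1"] <- CALL_HOM_ALT
  out
}

#' Convert call codes to canonical GT strings
#'
#' Inverse of [gt_to_call()]: emits `0/0`, `0/1`, `1/1`, or `./.` for
#' missing. Always unphased.
#'
#' @param call integer vector of call codes.
#' @return character vector of GT strings.
#' @export
call_to_gt <- function(call) {
  out <- rep("./.", length(call))
  out[!is.na(call) & call == CALL_HOM_REF] <- "0/0"
  out[!is.na(call) & call == CALL_HET] <- "0/1"
  out[!is.na(call) & call == CALL_HOM_ALT] <- "1/1"
  out
}

#' Construct a genotype matrix
#'
#' The central container: an ordered set of samples, an ordered set of
#' marker records, and a dense samples-by-markers matrix of call codes.
#' Marker records carry `id`, `chrom`, 1-based `pos`, `ref` and `alt`
#' allele strings, plus `is_snp` and `is_biallelic` flags so that
#' multi-allelic or non-SNP records read from a VCF survive to the filter
#' stage, where they are rejected explicitly rather than silently dropped.
#'
#' @param calls integer matrix (samples x markers) of call codes.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`; optional `is_snp`, `is_biallelic` (default derived from the
#'   alleles).
#' @param samples character vector of unique sample identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.character(samples)
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(markers),
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers))
  )
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("duplicate marker identifiers: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (any(markers$pos < 1)) stop("marker positions must be >= 1 (1-based)")
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad)) stop("call codes must be 0, 1, 2 or NA")
  nuc <- c("A", "C", "G", "T")
  if (is.null(markers$is_snp))
    markers$is_snp <- markers$ref %in% nuc &
      vapply(strsplit(markers$alt, ",", fixed = TRUE),
             function(a) all(a %in% nuc), logical(1))
  if (is.null(markers$is_biallelic))
    markers$is_biallelic <- !grepl(",", markers$alt, fixed = TRUE)
  dimnames(calls) <- list(samples, markers$id)
  rownames(markers) <- NULL
  structure(list(samples = samples, markers = markers, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers\n",
              length(x$samples), nrow(x$markers)))
  cat(sprintf("  biallelic SNPs: %d; flagged (multi-allelic or non-SNP): %d\n",
              sum(x$markers$is_snp & x$markers$is_biallelic),
              sum(!(x$markers$is_snp & x$markers$is_biallelic))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / markers in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_markers <- function(x) nrow(x$markers)

#' Subset a genotype matrix by marker
#'
#' @param x a `genotype_matrix`.
#' @param idx integer or logical index, or character vector of marker ids.
#' @return a `genotype_matrix` restricted to the selected markers.
#' @export
subset_markers <- function(x, idx) {
  if (is.character(idx)) {
    idx <- match(idx, x$markers$id)
    if (anyNA(idx)) stop("unknown marker id(s)")
  }
  genotype_matrix(x$calls[, idx, drop = FALSE],
                  x$markers[idx, , drop = FALSE], x$samples)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Uses `vcfR` for parsing. All records are retained: multi-allelic and
#' non-SNP records are flagged (`is_snp`, `is_biallelic` columns) so the
#' filter stage can reject and count them. Per-sample genotypes referencing
#' allele indices above 1, or containing `.`, are coerced to missing.
#' Coordinates remain 1-based as in the VCF.
#'
#' @param path VCF file (plain or gzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction
#'   applied after reading (1-based inclusive).
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(v@gt) == 0 && nrow(fix) > 0)
    stop("VCF has no genotype (GT) columns: ", path)
  if (nrow(fix) > 0) {
    fmt <- v@gt[, "FORMAT"]
    if (any(!grepl("(^|:)GT(:|$)", fmt)))
      stop("VCF record without GT in FORMAT (first at data line ",
           which(!grepl("(^|:)GT(:|$)", fmt))[1], "): ", path)
  }
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (anyDuplicated(samples))
    stop("duplicate sample names in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  markers <- data.frame(id = id, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  if (nrow(markers) > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    calls <- t(matrix(gt_to_call(gt), nrow = nrow(markers)))  # samples x markers
  } else {
    calls <- matrix(integer(0), nrow = length(samples), ncol = 0)
  }
  x <- genotype_matrix(calls, markers, samples)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0) stop("bad region string: ", region)
    keep <- x$markers$chrom == m[2]
    if (m[3] != "")
      keep <- keep & x$markers$pos >= as.integer(m[4]) &
        x$markers$pos <= as.integer(m[5])
    x <- subset_markers(x, which(keep))
  }
  x
}

# Format the body of a GT-only VCF; shared by write_vcf and the synthetic
# fixture generator.
vcf_header_lines <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##source=snpfinger",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record_lines <- function(markers, gt_by_marker) {
  # gt_by_marker: character matrix, markers x samples
  body <- cbind(markers$chrom, markers$pos, markers$id, markers$ref,
                markers$alt, ".", "PASS", ".", "GT", gt_by_marker)
  apply(body, 1, paste, collapse = "\t")
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a plain-text, GT-only VCF with records in deterministic
#' (chromosome, position) order. Missing calls are serialized as `./.`;
#' all genotypes are written unphased.
#'
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  ord <- order(x$markers$chrom, x$markers$pos)
  m <- x$markers[ord, , drop = FALSE]
  lines <- vcf_header_lines(x$samples)
  if (nrow(m) > 0) {
    gt <- apply(x$calls[, ord, drop = FALSE], 1, call_to_gt)
    gt <- matrix(gt, nrow = nrow(m))  # markers x samples
    lines <- c(lines, vcf_record_lines(m, gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file. Sequence names are truncated at the first
#'   whitespace; sequences are uppercased.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Fetch a 1-based inclusive slice of a chromosome
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates; clipped to the contig.
#' @return uppercase nucleotide string.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATGCCC"))
#' genome_fetch(g, "chr1", 1, 3)  # "ATG"
genome_fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  start <- max(1L, as.integer(start))
  end <- min(len, as.integer(end))
  if (start > end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Read CDS segments from a GFF3 annotation
#'
#' Imports via `rtracklayer` and keeps `CDS` features only. Each segment
#' carries chromosome, 1-based inclusive interval, strand, phase and a
#' transcript id (taken from the `Parent` attribute, falling back to
#' `transcript_id` or `ID`). Transcripts whose phase-adjusted concatenated
#' CDS length is not a multiple of 3 are reported with a warning, never
#' silently fixed.
#'
#' @param path GFF3 file.
#' @param genome optional `DNAStringSet`; when supplied, chromosome names
#'   present in the annotation but absent from the genome raise an error
#'   listing the offending names.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `phase`, `transcript_id`, ordered by transcript then genomic position.
#' @export
read_cds <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  tx <- as.character(S4Vectors::mcols(gr)$Parent)
  if (length(tx) == 0 || all(is.na(tx)) || all(tx == "character(0)")) {
    tx <- S4Vectors::mcols(gr)$transcript_id
    if (is.null(tx)) tx <- S4Vectors::mcols(gr)$ID
  }
  tx[tx == "character(0)"] <- NA
  if (anyNA(tx)) stop("CDS feature without Parent/transcript_id in ", path)
  cds <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = as.integer(S4Vectors::mcols(gr)$phase),
    transcript_id = as.character(tx),
    stringsAsFactors = FALSE)
  if (any(!cds$strand %in% c("+", "-")))
    stop("CDS feature without strand in ", path)
  if (anyNA(cds$phase)) stop("CDS feature without phase in ", path)
  if (!is.null(genome)) {
    bad <- setdiff(unique(cds$chrom), names(genome))
    if (length(bad))
      stop("annotation chromosomes absent from genome: ",
           paste(bad, collapse = ", "))
  }
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  bad_tx <- vapply(split(cds, cds$transcript_id), function(s) {
    ph <- reading_phase(s)
    (sum(s$end - s$start + 1) - ph) %% 3 != 0
  }, logical(1))
  if (any(bad_tx))
    warning("CDS length not a codon multiple after phase adjustment for ",
            "transcript(s): ", paste(names(bad_tx)[bad_tx], collapse = ", "))
  cds
}

# Phase of the first segment in *reading* order (largest start for minus
# strand).
reading_phase <- function(seg) {
  if (seg$strand[1] == "+") seg$phase[which.min(seg$start)]
  else seg$phase[which.max(seg$start)]
}

#' Read or write a delimited genotype-call table
#'
#' Tab-separated interchange format with call tokens `0/0`, `0/1`, `1/1`,
#' `./.`. With `orientation = "samples"` rows are samples and columns are
#' markers (first column `sample`); with `orientation = "markers"` rows are
#' markers and columns samples (first column `marker`), the layout used by
#' fingerprint-matrix exports.
#'
#' @param path file to read or write.
#' @param orientation `"samples"` or `"markers"`.
#' @return `read_genotype_table`: a data.frame of call tokens with sample
#'   rownames and marker column names (always sample-major, whatever the
#'   on-disk orientation).
#' @export
read_genotype_table <- function(path, orientation = c("samples", "markers")) {
  orientation <- match.arg(orientation)
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  rn <- d[[1]]
  d <- as.data.frame(d[, -1, drop = FALSE])
  rownames(d) <- rn
  if (orientation == "markers") {
    d <- as.data.frame(t(as.matrix(d)), stringsAsFactors = FALSE)
  }
  d
}

#' @rdname read_genotype_table
#' @param x a `genotype_matrix`.
#' @export
write_genotype_table <- function(x, path, orientation = c("samples", "markers")) {
  orientation <- match.arg(orientation)
  tok <- matrix(call_to_gt(x$calls), nrow = length(x$samples),
                dimnames = list(x$samples, x$markers$id))
  if (orientation == "samples") {
    d <- data.frame(sample = rownames(tok), tok, check.names = FALSE)
  } else {
    d <- data.frame(marker = colnames(tok), t(tok), check.names = FALSE)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
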