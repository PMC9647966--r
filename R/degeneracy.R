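FOLD_LEVELS <- c("NONCODING", "NONDEGENERATE", "TWOFOLD", "THREEFOLD",
                 "FOURFOLD", "CONFLICT")

# Degeneracy of one codon position under the standard genetic code
# (translation table 1): the number of nucleotides at that position, the
# observed one included, that leave the encoded amino acid unchanged.
# Codons containing anything outside ACGT are treated as non-degenerate so
# that ambiguity codes can never be selected as neutral sites.
codon_position_fold <- function(codon, pos_in_codon) {
  stopifnot(nchar(codon) == 3, pos_in_codon %in% 1:3)
  nuc <- c("A", "C", "G", "T")
  bases <- strsplit(codon, "")[[1]]
  if (!all(bases %in% nuc)) return("NONDEGENERATE")
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  variants <- vapply(nuc, function(b) {
    v <- bases; v[pos_in_codon] <- b
    code[[paste(v, collapse = "")]]
  }, character(1))
  n_syn <- sum(variants == aa)
  c("NONDEGENERATE", "TWOFOLD", "THREEFOLD", "FOURFOLD")[n_syn]
}

# Reconstruct the coding sequence of one transcript and locate a genomic
# site within it. Segments are concatenated in reading order (reverse
# complement for minus strand) and the reading-start phase is trimmed.
# Returns NULL when the site falls in the trimmed phase overhang (no
# complete codon is defined for it by this transcript).
locate_in_transcript <- function(chrom, pos, seg, genome) {
  seg <- seg[order(seg$start), , drop = FALSE]
  strand <- seg$strand[1]
  ph <- reading_phase(seg)
  seqs <- vapply(seq_len(nrow(seg)), function(i)
    genome_fetch(genome, seg$chrom[i], seg$start[i], seg$end[i]),
    character(1))
  widths <- seg$end - seg$start + 1
  if ((sum(widths) - ph) %% 3 != 0)
    stop("CDS of transcript '", seg$transcript_id[1],
         "' is not a codon multiple after phase adjustment")
  if (strand == "+") {
    coding <- paste(seqs, collapse = "")
    i <- which(seg$start <= pos & seg$end >= pos & seg$chrom == chrom)[1]
    offset <- if (i > 1) sum(widths[seq_len(i - 1)]) else 0L
    idx <- offset + (pos - seg$start[i] + 1L)
  } else {
    coding <- paste(rev(vapply(seqs, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1))), collapse = "")
    i <- which(seg$start <= pos & seg$end >= pos & seg$chrom == chrom)[1]
    after <- if (i < nrow(seg)) sum(widths[seq(i + 1, nrow(seg))]) else 0L
    idx <- after + (seg$end[i] - pos + 1L)
  }
  idx <- idx - ph
  if (idx < 1) return(NULL)
  coding <- substr(coding, ph + 1, nchar(coding))
  codon_i <- (idx - 1) %/% 3
  list(codon = substr(coding, codon_i * 3 + 1, codon_i * 3 + 3),
       pos_in_codon = (idx - 1) %% 3 + 1)
}

#' Classify a genomic site by codon degeneracy
#'
#' For every transcript whose CDS covers the site, the containing codon is
#' reconstructed respecting strand and phase (minus-strand codons are read
#' on the reverse complement; multi-segment CDS are concatenated with
#' phase-adjustment), and the site's codon position is classified by how
#' many of the four nucleotides there are synonymous under the standard
#' genetic code. A site covered by no CDS is `NONCODING`; transcripts that
#' disagree yield `CONFLICT`.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param cds CDS segment table from [read_cds()].
#' @param genome genome from [read_genome()].
#' @return list with `chrom`, `pos`, `fold` (one of `NONCODING`,
#'   `NONDEGENERATE`, `TWOFOLD`, `THREEFOLD`, `FOURFOLD`, `CONFLICT`) and
#'   `transcripts`, the covering transcript ids.
#' @export
classify_site <- function(chrom, pos, cds, genome) {
  cov <- cds[cds$chrom == chrom & cds$start <= pos & cds$end >= pos, ,
             drop = FALSE]
  txs <- unique(cov$transcript_id)
  if (length(txs) == 0)
    return(list(chrom = chrom, pos = pos, fold = "NONCODING",
                transcripts = character(0)))
  folds <- character(0)
  for (tx in txs) {
    seg <- cds[cds$transcript_id == tx, , drop = FALSE]
    loc <- locate_in_transcript(chrom, pos, seg, genome)
    if (is.null(loc)) next  # site in the phase overhang: no codon defined
    folds <- c(folds, codon_position_fold(loc$codon, loc$pos_in_codon))
  }
  fold <- if (length(folds) == 0) "NONCODING"
          else if (length(unique(folds)) == 1) folds[1]
          else "CONFLICT"
  list(chrom = chrom, pos = pos, fold = fold, transcripts = txs)
}

#' Classify many sites at once
#'
#' @param sites data.frame with `chrom` and `pos` columns.
#' @inheritParams classify_site
#' @return character vector of fold classes, one per row of `sites`.
#' @export
classify_sites <- function(sites, cds, genome) {
  vapply(seq_len(nrow(sites)), function(i)
    classify_site(sites$chrom[i], sites$pos[i], cds, genome)$fold,
    character(1))
}

#' Is a site fourfold degenerate?
#'
#' Convenience predicate: `TRUE` iff [classify_site()] returns `FOURFOLD`
#' (so `FALSE` for sites where covering transcripts conflict).
#'
#' @inheritParams classify_site
#' @return logical scalar.
#' @export
is_4d <- function(chrom, pos, cds, genome) {
  identical(classify_site(chrom, pos, cds, genome)$fold, "FOURFOLD")
}

#' Export fourfold-degenerate sites as BED
#'
#' Writes one BED line per site, converting the package's 1-based
#' inclusive coordinates to BED's 0-based half-open convention
#' (`pos` becomes the interval `[pos - 1, pos)`).
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  name <- if (!is.null(sites$id)) sites$id else
    paste0(sites$chrom, "_", sites$pos)
  d <- data.frame(chrom = sites$chrom, start = sites$pos - 1L,
                  end = sites$pos, name = name)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
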