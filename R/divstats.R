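#' Alternate-allele frequency of one marker
#'
#' Complete-case estimate: `p_alt = (2 * n_homalt + n_het) / (2 * n_called)`,
#' with missing calls excluded from both numerator and denominator. No
#' small-sample correction is applied.
#'
#' @param calls integer vector of call codes (0/1/2/`NA`).
#' @return `p_alt` in `[0, 1]`, or `NA` when every call is missing.
#' @export
#' @examples
#' allele_freq(c(0L, 1L, 2L))  # 0.5
allele_freq <- function(calls) {
  called <- calls[!is.na(calls)]
  if (length(called) == 0) return(NA_real_)
  (2 * sum(called == 2L) + sum(called == 1L)) / (2 * length(called))
}

#' Polymorphism information content of a biallelic locus
#'
#' Botstein's PIC in its biallelic closed form
#' `1 - (p^2 + q^2) - 2 p^2 q^2`, bounded above by 0.375 at `p = 0.5`.
#'
#' @param p allele frequency in `[0, 1]` (either allele; the function is
#'   symmetric under `p <-> 1 - p`).
#' @return PIC value.
#' @export
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Gene diversity (expected heterozygosity) of a biallelic locus
#'
#' `1 - p^2 - q^2`, the probability that two random alleles differ;
#' maximum 0.5 at `p = 0.5`.
#'
#' @inheritParams pic_biallelic
#' @return gene diversity value.
#' @export
gene_diversity_biallelic <- function(p) {
  1 - p^2 - (1 - p)^2
}

#' Per-marker diversity statistics
#'
#' Computes, from one marker's calls: minor allele frequency
#' `maf = min(p, 1 - p)`; gene diversity `1 - p^2 - q^2`; PIC
#' (biallelic Botstein form); observed heterozygosity
#' `n_het / n_called`; missing rate `n_missing / n_samples`. Frequencies
#' use called alleles only.
#'
#' @param calls integer vector of call codes.
#' @param n_total total number of samples the missing rate is relative to
#'   (defaults to `length(calls)`).
#' @return one-row data.frame with columns `maf`, `pic`, `het_obs`,
#'   `gene_diversity`, `missing_rate`, `n_called`. All statistics are `NA`
#'   (except `missing_rate`) when every call is missing.
#' @export
marker_stats <- function(calls, n_total = length(calls)) {
  n_called <- sum(!is.na(calls))
  p <- allele_freq(calls)
  if (is.na(p)) {
    return(data.frame(maf = NA_real_, pic = NA_real_, het_obs = NA_real_,
                      gene_diversity = NA_real_,
                      missing_rate = 1, n_called = 0L))
  }
  data.frame(
    maf = min(p, 1 - p),
    pic = pic_biallelic(p),
    het_obs = sum(calls == 1L, na.rm = TRUE) / n_called,
    gene_diversity = gene_diversity_biallelic(p),
    missing_rate = sum(is.na(calls)) / n_total,
    n_called = n_called)
}

#' Diversity statistics for every marker of a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @return data.frame with one row per marker: `id`, `chrom`, `pos`,
#'   `ref`, `alt`, then the [marker_stats()] columns.
#' @export
marker_stats_all <- function(x) {
  st <- do.call(rbind, lapply(seq_len(n_markers(x)), function(j)
    marker_stats(x$calls[, j], n_total = n_samples(x))))
  cbind(x$markers[, c("id", "chrom", "pos", "ref", "alt")], st)
}

SPECTRUM_PAIRS <- c("A/G", "C/T", "A/T", "A/C", "G/T", "C/G")

canonical_pair <- function(ref, alt) {
  a <- pmin(ref, alt); b <- pmax(ref, alt)
  p <- paste0(a, "/", b)
  # map alphabetical form onto the conventional labels
  map <- c("A/G" = "A/G", "C/T" = "C/T", "A/T" = "A/T",
           "A/C" = "A/C", "G/T" = "G/T", "C/G" = "C/G")
  map[p]
}

#' Variant-type spectrum and Ts/Tv ratio
#'
#' Tallies the six unordered single-base substitution types (`A/G`, `C/T`
#' transitions; `A/T`, `A/C`, `G/T`, `C/G` transversions) and their
#' transition/transversion ratio. Accepts a `genotype_matrix`, a marker
#' data.frame with `ref`/`alt` columns, or a named numeric vector of
#' per-type weights (counts or percentages) — the latter lets the ratio be
#' recovered from a published spectrum.
#'
#' @param x markers in one of the forms above.
#' @return object of class `variant_spectrum`: list with `counts` (named
#'   over the six types), `ts`, `tv`, `ts_tv` (`NA` when no
#'   transversions).
#' @export
#' @examples
#' variant_spectrum(data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "T")))
variant_spectrum <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- x$markers
  if (is.data.frame(x)) {
    ok <- x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")
    if (!all(ok)) stop("variant_spectrum requires biallelic SNPs (ACGT ref/alt)")
    pr <- canonical_pair(x$ref, x$alt)
    counts <- vapply(SPECTRUM_PAIRS, function(p) sum(pr == p), numeric(1))
  } else if (is.numeric(x)) {
    if (!all(SPECTRUM_PAIRS %in% names(x)))
      stop("named weights must cover all six pairs: ",
           paste(SPECTRUM_PAIRS, collapse = ", "))
    counts <- x[SPECTRUM_PAIRS]
  } else stop("unsupported input")
  ts <- unname(counts["A/G"] + counts["C/T"])
  tv <- unname(sum(counts[c("A/T", "A/C", "G/T", "C/G")]))
  structure(list(counts = counts, ts = ts, tv = tv,
                 ts_tv = if (tv > 0) ts / tv else NA_real_),
            class = "variant_spectrum")
}

#' @export
print.variant_spectrum <- function(x, ...) {
  cat("variant spectrum:\n")
  print(x$counts)
  cat(sprintf("Ts/Tv = %s\n",
              if (is.na(x$ts_tv)) "undefined (no transversions)"
              else format(round(x$ts_tv, 3))))
  invisible(x)
}

#' Transition/transversion ratio
#'
#' @param x a `variant_spectrum`, or anything [variant_spectrum()] accepts.
#' @return numeric ratio (`NA` if there are no transversions).
#' @export
ts_tv_ratio <- function(x) {
  if (!inherits(x, "variant_spectrum")) x <- variant_spectrum(x)
  x$ts_tv
}

#' Panel-level summary of marker statistics
#'
#' Mean, minimum and maximum of each diversity statistic over a marker
#' panel, plus the fraction of markers whose gene diversity falls in a
#' band (default `[0.4, 0.5]`, inclusive at both ends — loci at the
#' biallelic maximum of exactly 0.5 count as in-band).
#'
#' @param stats data.frame with columns `maf`, `pic`, `het_obs`,
#'   `gene_diversity`, `missing_rate` (e.g. from [marker_stats_all()]).
#' @param band length-2 numeric, the inclusive gene-diversity band.
#' @return list with `n_markers`, a `summary` data.frame (rows mean/min/max)
#'   and `gene_diversity_band` (`lower`, `upper`, `fraction`).
#' @export
panel_summary <- function(stats, band = c(0.4, 0.5)) {
  stopifnot(nrow(stats) > 0, length(band) == 2, band[1] <= band[2])
  cols <- intersect(c("maf", "pic", "het_obs", "gene_diversity",
                      "missing_rate"), names(stats))
  sm <- sapply(stats[cols], function(v)
    c(mean = mean(v, na.rm = TRUE), min = min(v, na.rm = TRUE),
      max = max(v, na.rm = TRUE)))
  gd <- stats$gene_diversity
  frac <- mean(gd >= band[1] & gd <= band[2], na.rm = TRUE)
  list(n_markers = nrow(stats),
       summary = as.data.frame(sm),
       gene_diversity_band = list(lower = band[1], upper = band[2],
                                  fraction = frac))
}

#' Bundled reference panel: 41 cauliflower core KASP markers
#'
#' Published per-marker statistics (PIC, MAF, gene diversity, observed
#' heterozygosity) for a 41-marker cauliflower core KASP panel genotyped
#' on 329 market cultivars; used as a regression fixture for the
#' statistics formulas and as a worked-example input.
#'
#' @return data.frame with columns `marker`, `chrom`, `pos`, `ref`, `alt`,
#'   `pic`, `maf`, `gene_diversity`, `heterozygosity`.
#' @export
core_markers <- function() {
  read.delim(system.file("extdata", "core_markers_cauliflower.tsv",
                         package = "snpfinger"),
             colClasses = c(pos = "integer"))
}

#' Bundled reference spectrum: variant-type percentages of a 1662-SNP pool
#'
#' Percentages of the six substitution types in the screened candidate
#' pool the core panel was drawn from (transitions A/G and C/T dominant).
#'
#' @return named numeric vector over the six substitution types.
#' @export
candidate_pool_spectrum <- function() {
  d <- read.delim(system.file("extdata", "candidate_pool_spectrum.tsv",
                              package = "snpfinger"))
  setNames(d$percent, d$pair)
}

#' Write a per-marker statistics TSV
#'
#' @param stats data.frame from [marker_stats_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
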