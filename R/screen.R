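CRITERIA_ORDER <- c("biallelic", "fourfold", "heterozygosity", "missing",
                    "maf", "flank")

#' Candidate-marker filter criteria
#'
#' The six screening criteria applied, in order, to a raw variant set:
#' (1) biallelic SNP; (2) fourfold-degenerate site; (3) observed
#' heterozygosity below `max_heterozygosity`; (4) missing rate below
#' `max_missing`; (5) minor allele frequency above `min_maf`; (6) no other
#' variant (SNP or InDel) within `clean_flank_bp` of the site. All
#' threshold comparisons are strict (`<`, `>`): a marker with MAF exactly
#' equal to `min_maf`, or heterozygosity exactly at `max_heterozygosity`,
#' is rejected. This boundary behaviour affects survivor counts and is
#' deliberate.
#'
#' @param require_biallelic,require_4d enable criteria 1 and 2.
#' @param max_heterozygosity exclusive upper bound on observed
#'   heterozygosity (default 0.2).
#' @param max_missing exclusive upper bound on missing rate (default 0.05).
#' @param min_maf exclusive lower bound on minor allele frequency
#'   (default 0.3).
#' @param clean_flank_bp flank radius in bp that must contain no other
#'   variant (default 100).
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(require_biallelic = TRUE, require_4d = TRUE,
                            max_heterozygosity = 0.2, max_missing = 0.05,
                            min_maf = 0.3, clean_flank_bp = 100L) {
  stopifnot(max_heterozygosity >= 0, max_heterozygosity <= 1,
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, clean_flank_bp >= 0)
  structure(list(require_biallelic = isTRUE(require_biallelic),
                 require_4d = isTRUE(require_4d),
                 max_heterozygosity = max_heterozygosity,
                 max_missing = max_missing, min_maf = min_maf,
                 clean_flank_bp = as.integer(clean_flank_bp)),
            class = "filter_criteria")
}

# TRUE where a marker has another variant within +/- flank bp on the same
# chromosome. `all_variants` holds every raw variant position, including
# the markers themselves; a variant at the marker's own (chrom, pos) is
# not a neighbour.
has_flank_neighbor <- function(markers, all_variants, flank) {
  vapply(seq_len(nrow(markers)), function(i) {
    same <- all_variants$chrom == markers$chrom[i]
    d <- abs(all_variants$pos[same] - markers$pos[i])
    any(d <= flank & d > 0)
  }, logical(1))
}

#' Filter a raw variant set down to candidate markers
#'
#' Applies the enabled [filter_criteria()] to every marker of a genotype
#' matrix. The surviving set is the intersection of the per-criterion pass
#' sets (so the outcome is order-independent); for the report, each
#' rejected marker is attributed to its first failing criterion in the
#' order biallelic, fourfold, heterozygosity, missing, MAF, flank.
#' Per-marker statistics are computed over the full sample set with
#' [marker_stats()], independently of the other criteria.
#'
#' @param x a `genotype_matrix`.
#' @param criteria a [filter_criteria()] object.
#' @param fold_classes character vector of fold classes, one per marker
#'   (from [classify_sites()]); required when `require_4d` is enabled.
#' @param all_variants data.frame (`chrom`, `pos`) of every raw variant,
#'   InDels included, used for flank cleanliness. Defaults to the matrix's
#'   own markers.
#' @return list with `matrix` (the surviving `genotype_matrix`), `report`
#'   (a `filter_report`: `input_count`, `surviving_count`, named
#'   `rejections`) and `detail` (per-marker pass/fail table).
#' @export
filter_candidates <- function(x, criteria = filter_criteria(),
                              fold_classes = NULL, all_variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(criteria, "filter_criteria"))
  m <- x$markers
  n <- nrow(m)
  if (criteria$require_4d && is.null(fold_classes))
    stop("require_4d is enabled but no fold_classes were supplied ",
         "(run classify_sites() with a genome and annotation)")
  if (!is.null(fold_classes) && length(fold_classes) != n)
    stop("fold_classes must have one entry per marker")
  if (is.null(all_variants)) all_variants <- m[, c("chrom", "pos")]
  st <- marker_stats_all(x)
  pass <- data.frame(
    biallelic = if (criteria$require_biallelic) m$is_snp & m$is_biallelic
                else rep(TRUE, n),
    fourfold = if (criteria$require_4d) fold_classes == "FOURFOLD"
               else rep(TRUE, n),
    heterozygosity = st$het_obs < criteria$max_heterozygosity,
    missing = st$missing_rate < criteria$max_missing,
    maf = st$maf > criteria$min_maf,
    flank = !has_flank_neighbor(m, all_variants, criteria$clean_flank_bp))
  pass[is.na(pass)] <- FALSE  # all-missing markers have NA het/maf: fail
  keep <- Reduce(`&`, pass)
  first_fail <- apply(!pass, 1, function(f)
    if (any(f)) CRITERIA_ORDER[which(f)[1]] else NA_character_)
  rejections <- vapply(CRITERIA_ORDER, function(cr)
    sum(first_fail == cr, na.rm = TRUE), integer(1))
  report <- structure(list(input_count = n,
                           surviving_count = sum(keep),
                           rejections = rejections),
                      class = "filter_report")
  detail <- cbind(st, pass, rejected_by = first_fail)
  list(matrix = subset_markers(x, which(keep)), report = report,
       detail = detail)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d in, %d surviving\n",
              x$input_count, x$surviving_count))
  for (cr in names(x$rejections))
    cat(sprintf("  rejected by %-14s %d\n", paste0(cr, ":"), x$rejections[[cr]]))
  invisible(x)
}

#' Validate one marker as a KASP assay candidate
#'
#' Extracts the upstream and downstream flanks (default 100 bp each) around
#' the site, giving a window of `2 * flank_bp + 1` bases, and checks the
#' window-level design constraints: GC content strictly below `max_gc`,
#' no other variant inside the window (`flank_clean`), and window
#' uniqueness in the genome by exact forward-strand substring search
#' (`unique_in_genome`) — a deterministic stand-in for an alignment-based
#' specificity screen. A candidate is `designable` iff all three hold.
#' Flanks truncated at a contig edge are flagged (`at_contig_edge`), not
#' fatal. Primer-level properties (melting temperature, product size) are
#' out of scope: they belong to primer design software downstream.
#'
#' @param marker one-row data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genome genome from [read_genome()].
#' @param all_variants data.frame (`chrom`, `pos`) of every raw variant.
#' @param flank_bp flank length on each side (default 100).
#' @param max_gc exclusive GC-fraction ceiling over the window
#'   (default 0.60).
#' @return an object of class `kasp_candidate`: list with the marker row,
#'   `flank_up`, `flank_down`, `window`, `gc_content`, `flank_clean`,
#'   `unique_in_genome`, `at_contig_edge`, `designable`.
#' @export
validate_kasp_candidate <- function(marker, genome, all_variants,
                                    flank_bp = 100L, max_gc = 0.60) {
  chrom <- marker$chrom[1]; pos <- marker$pos[1]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  up <- genome_fetch(genome, chrom, pos - flank_bp, pos - 1)
  down <- genome_fetch(genome, chrom, pos + 1, pos + flank_bp)
  site <- genome_fetch(genome, chrom, pos, pos)
  window <- paste0(up, site, down)
  at_edge <- nchar(up) < flank_bp || nchar(down) < flank_bp
  gc <- if (nchar(window) > 0) {
    w <- Biostrings::DNAString(window)
    sum(Biostrings::letterFrequency(w, c("G", "C"))) / nchar(window)
  } else NA_real_
  same <- all_variants$chrom == chrom
  d <- abs(all_variants$pos[same] - pos)
  flank_clean <- !any(d <= flank_bp & d > 0)
  hits <- sum(Biostrings::vcountPattern(window, genome))
  unique_in_genome <- hits == 1
  structure(list(marker = marker, flank_up = up, flank_down = down,
                 window = window, gc_content = gc,
                 flank_clean = flank_clean,
                 unique_in_genome = unique_in_genome,
                 at_contig_edge = at_edge,
                 designable = !is.na(gc) && gc < max_gc && flank_clean &&
                   unique_in_genome),
            class = "kasp_candidate")
}

#' @export
print.kasp_candidate <- function(x, ...) {
  cat(sprintf("KASP candidate %s (%s:%d %s>%s)\n", x$marker$id[1],
              x$marker$chrom[1], x$marker$pos[1], x$marker$ref[1],
              x$marker$alt[1]))
  cat(sprintf("  GC %.1f%%; flank clean: %s; unique: %s; designable: %s\n",
              100 * x$gc_content, x$flank_clean, x$unique_in_genome,
              x$designable))
  invisible(x)
}

#' Screen every marker of a matrix for KASP designability
#'
#' @param x a `genotype_matrix`.
#' @inheritParams validate_kasp_candidate
#' @return data.frame, one row per marker, with `gc_content`,
#'   `flank_clean`, `unique_in_genome`, `at_contig_edge`, `designable`.
#' @export
kasp_screen <- function(x, genome, all_variants, flank_bp = 100L,
                        max_gc = 0.60) {
  rows <- lapply(seq_len(n_markers(x)), function(i) {
    k <- validate_kasp_candidate(x$markers[i, , drop = FALSE], genome,
                                 all_variants, flank_bp, max_gc)
    data.frame(id = x$markers$id[i], chrom = x$markers$chrom[i],
               pos = x$markers$pos[i], gc_content = k$gc_content,
               flank_clean = k$flank_clean,
               unique_in_genome = k$unique_in_genome,
               at_contig_edge = k$at_contig_edge,
               designable = k$designable)
  })
  do.call(rbind, rows)
}
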