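BARCODE_CODES <- c("R", "H", "A")  # hom-ref, het, hom-alt; "N" = missing

calls_to_codes <- function(calls) {
  out <- rep("N", length(calls))
  ok <- !is.na(calls)
  out[ok] <- BARCODE_CODES[calls[ok] + 1L]
  out
}

codes_to_calls <- function(codes) {
  out <- rep(NA_integer_, length(codes))
  for (i in seq_along(BARCODE_CODES))
    out[codes == BARCODE_CODES[i]] <- i - 1L
  if (any(!codes %in% c(BARCODE_CODES, "N")))
    stop("invalid barcode symbol(s): ",
         paste(unique(setdiff(codes, c(BARCODE_CODES, "N"))), collapse = ", "))
  out
}

#' Identity hash of a marker panel
#'
#' MD5 of the canonical panel definition (id, chrom, pos, ref, alt, in
#' panel order), truncated to 12 hex characters. Embedded in barcode
#' payloads so fingerprints can never be decoded against the wrong panel
#' silently.
#'
#' @param markers marker data.frame (panel order significant).
#' @return character scalar.
#' @export
panel_hash <- function(markers) {
  canon <- paste(markers$id, markers$chrom, markers$pos, markers$ref,
                 markers$alt, sep = ":", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

#' Build a cultivar fingerprint database
#'
#' Computes, over a fixed ordered marker panel, the genotype string of
#' every sample and the partition of samples into identical-genotype
#' groups. The number of groups equals `n_unique` of the panel's
#' [discernibility()] under the same missing-data mode; singleton groups
#' are the fully distinguished samples.
#'
#' @param x a `genotype_matrix`.
#' @param panel character vector of marker ids (order fixed; defaults to
#'   all markers of `x`).
#' @param missing_mode as in [discernibility()].
#' @return object of class `fingerprint_db`: `panel` (marker table),
#'   `panel_hash`, `entries` (named genotype strings), `calls` (samples x
#'   panel call codes), `groups` (list of sample-id vectors),
#'   `missing_mode`.
#' @export
build_db <- function(x, panel = x$markers$id,
                     missing_mode = c("distinct", "wildcard")) {
  missing_mode <- match.arg(missing_mode)
  if (length(panel) == 0) stop("empty panel")
  idx <- match(panel, x$markers$id)
  if (anyNA(idx)) stop("unknown marker id(s) in panel")
  tok <- genotype_tokens(x, panel)
  entries <- setNames(apply(tok, 1, paste, collapse = "|"), x$samples)
  groups <- genotype_groups(tok, missing_mode)
  structure(list(panel = x$markers[idx, , drop = FALSE],
                 panel_hash = panel_hash(x$markers[idx, , drop = FALSE]),
                 entries = entries,
                 calls = x$calls[, idx, drop = FALSE],
                 groups = groups, missing_mode = missing_mode),
            class = "fingerprint_db")
}

#' @export
print.fingerprint_db <- function(x, ...) {
  n <- length(x$entries)
  singles <- sum(lengths(x$groups) == 1)
  cat(sprintf("fingerprint database: %d samples, %d markers, hash %s\n",
              n, nrow(x$panel), x$panel_hash))
  cat(sprintf("  %d distinct genotypes; %d samples fully distinguished; %d in duplicate groups\n",
              length(x$groups), singles, n - singles))
  invisible(x)
}

#' Report duplicate-genotype groups
#'
#' Lists every group of two or more samples sharing a genotype string,
#' sorted by group size descending, then by first member id. An empty
#' table means all samples are fully distinguished.
#'
#' @param db a `fingerprint_db`.
#' @return data.frame with `group`, `size`, `members` (comma-joined),
#'   `genotype`.
#' @export
duplicate_report <- function(db) {
  dup <- db$groups[lengths(db$groups) >= 2]
  if (length(dup) == 0)
    return(data.frame(group = integer(0), size = integer(0),
                      members = character(0), genotype = character(0)))
  dup <- lapply(dup, sort)
  ord <- order(-lengths(dup), vapply(dup, `[`, character(1), 1))
  dup <- dup[ord]
  data.frame(group = seq_along(dup), size = lengths(dup),
             members = vapply(dup, paste, character(1), collapse = ","),
             genotype = vapply(dup, function(g) db$entries[[g[1]]],
                               character(1)),
             row.names = NULL)
}

#' Export the fingerprint matrix as TSV
#'
#' Markers as rows, samples as columns, cells in `{0/0, 0/1, 1/1, ./.}` —
#' the orientation of a fingerprint heat-map. Round-trips through
#' [read_genotype_table()] with `orientation = "markers"`. Output is
#' deterministic (panel order, sample order).
#'
#' @param db a `fingerprint_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(db, path) {
  gt <- matrix(call_to_gt(db$calls), nrow = nrow(db$calls),
               dimnames = dimnames(db$calls))
  d <- data.frame(marker = colnames(gt), t(gt), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode a sample's fingerprint as a barcode payload
#'
#' Plain-text, machine-decodable payload:
#' `sample_id|panel_hash|<one symbol per marker>` with symbols `R`
#' (hom-ref), `H` (het), `A` (hom-alt), `N` (missing). The payload is the
#' string a 2D-barcode image would carry; image rendering is outside the
#' package.
#'
#' @param db a `fingerprint_db`.
#' @param sample sample identifier present in the database.
#' @return character scalar payload.
#' @export
encode_barcode <- function(db, sample) {
  if (!sample %in% names(db$entries)) stop("unknown sample: ", sample)
  codes <- paste(calls_to_codes(db$calls[sample, ]), collapse = "")
  paste(sample, db$panel_hash, codes, sep = "|")
}

#' Decode a barcode payload back to call codes
#'
#' Verifies the embedded panel hash against the supplied panel and fails
#' loudly on mismatch, then maps symbols back to call codes. Exact inverse
#' of [encode_barcode()] given the same panel.
#'
#' @param payload payload string from [encode_barcode()].
#' @param panel marker data.frame (or a `fingerprint_db`) defining the
#'   expected panel.
#' @return list with `sample`, `calls` (integer codes, named by marker id).
#' @export
decode_barcode <- function(payload, panel) {
  if (inherits(panel, "fingerprint_db")) panel <- panel$panel
  parts <- strsplit(payload, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("malformed barcode payload")
  expected <- panel_hash(panel)
  if (parts[2] != expected)
    stop("panel hash mismatch: payload carries ", parts[2],
         " but the supplied panel hashes to ", expected)
  codes <- strsplit(parts[3], "")[[1]]
  if (length(codes) != nrow(panel))
    stop("payload length does not match panel size")
  list(sample = parts[1],
       calls = setNames(codes_to_calls(codes), panel$id))
}

#' Dump a fingerprint database to JSON
#'
#' @param db a `fingerprint_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
db_to_json <- function(db, path) {
  jsonlite::write_json(
    list(panel = db$panel, panel_hash = db$panel_hash,
         missing_mode = db$missing_mode,
         entries = as.list(db$entries),
         groups = db$groups),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
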