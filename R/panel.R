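# Token matrix: samples x panel markers, each cell the unordered allele
# pair ("AA", "AG", ...) or "NN" for missing. Heterozygous tokens are
# alphabetically sorted so the encoding is phase- and order-insensitive.
genotype_tokens <- function(x, panel) {
  idx <- match(panel, x$markers$id)
  if (anyNA(idx)) stop("unknown marker id(s): ",
                       paste(panel[is.na(idx)], collapse = ", "))
  ref <- x$markers$ref[idx]; alt <- x$markers$alt[idx]
  het <- paste0(pmin(ref, alt), pmax(ref, alt))
  tok <- matrix("NN", nrow = n_samples(x), ncol = length(idx),
                dimnames = list(x$samples, x$markers$id[idx]))
  calls <- x$calls[, idx, drop = FALSE]
  for (j in seq_along(idx)) {
    cj <- calls[, j]
    tok[!is.na(cj) & cj == 0L, j] <- strrep(ref[j], 2)
    tok[!is.na(cj) & cj == 1L, j] <- het[j]
    tok[!is.na(cj) & cj == 2L, j] <- strrep(alt[j], 2)
  }
  tok
}

#' Genotype string of one sample over a marker panel
#'
#' One token per panel marker, in panel order: hom-ref `ref+ref`, het
#' the alphabetically sorted allele pair, hom-alt `alt+alt`, missing
#' `"NN"`; tokens joined with `sep`.
#'
#' @param x a `genotype_matrix`.
#' @param sample sample identifier.
#' @param panel character vector of marker ids (panel order is kept).
#' @param sep token separator (default `"|"`).
#' @return character scalar.
#' @export
genotype_string <- function(x, sample, panel, sep = "|") {
  if (!sample %in% x$samples) stop("unknown sample: ", sample)
  tok <- genotype_tokens(x, panel)
  paste(tok[sample, ], collapse = sep)
}

#' Genotype strings for all samples over a panel
#'
#' @inheritParams genotype_string
#' @return named character vector (one string per sample).
#' @export
genotype_strings <- function(x, panel, sep = "|") {
  tok <- genotype_tokens(x, panel)
  setNames(apply(tok, 1, paste, collapse = sep), x$samples)
}

# Group samples by genotype identity. In "distinct" mode missing tokens
# compare as an ordinary symbol (two samples both missing at a marker
# match there). In "wildcard" mode a missing token matches anything —
# matching is then not transitive, so groups are the connected components
# of the pairwise match graph (conservative duplicate calling).
genotype_groups <- function(tok, missing_mode = c("distinct", "wildcard"),
                            sep = "|") {
  missing_mode <- match.arg(missing_mode)
  n <- nrow(tok)
  if (missing_mode == "distinct") {
    strs <- apply(tok, 1, paste, collapse = sep)
    return(unname(split(rownames(tok), factor(strs, levels = unique(strs)))))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ti <- tok[i, ]; tj <- tok[j, ]
    if (all(ti == tj | ti == "NN" | tj == "NN")) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(rownames(tok), factor(roots, levels = unique(roots))))
}

#' Discernibility of a marker panel
#'
#' The fraction of distinct genotype strings among the cohort:
#' `discernibility = n_unique / n_samples`. Equals 1 iff every sample is
#' fully distinguished; never below `1 / n_samples`.
#'
#' @param x a `genotype_matrix`.
#' @param panel character vector of marker ids (non-empty).
#' @param missing_mode `"distinct"` (default: missing is an ordinary
#'   symbol) or `"wildcard"` (missing matches anything; groups become
#'   connected components of the match relation).
#' @return object of class `panel_result`: `marker_ids` (sorted),
#'   `discernibility`, `n_unique`, `n_samples`, `fraction` (exact rational
#'   as a string), `missing_mode`.
#' @export
discernibility <- function(x, panel, missing_mode = c("distinct", "wildcard")) {
  missing_mode <- match.arg(missing_mode)
  if (length(panel) == 0) stop("empty panel")
  if (n_samples(x) == 0) stop("no samples")
  tok <- genotype_tokens(x, panel)
  groups <- genotype_groups(tok, missing_mode)
  n_unique <- length(groups)
  structure(list(marker_ids = sort(panel),
                 discernibility = n_unique / n_samples(x),
                 n_unique = n_unique, n_samples = n_samples(x),
                 fraction = paste0(n_unique, "/", n_samples(x)),
                 missing_mode = missing_mode),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("panel of %d markers: discernibility %s = %.4f (%d groups / %d samples)\n",
              length(x$marker_ids), x$fraction, x$discernibility,
              x$n_unique, x$n_samples))
  invisible(x)
}

#' Simulation configuration for randomized panel selection
#'
#' @param panel_sizes integer vector of subset sizes to evaluate.
#' @param reps_per_size random subsets drawn per size (default 5000; the
#'   cumulative efficiency curve conventionally uses 10000).
#' @param seed RNG seed; every simulation is reproducible given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(panel_sizes, reps_per_size = 5000L, seed = 1L) {
  panel_sizes <- as.integer(panel_sizes)
  stopifnot(length(panel_sizes) >= 1, all(panel_sizes >= 1),
            reps_per_size >= 1)
  structure(list(panel_sizes = panel_sizes,
                 reps_per_size = as.integer(reps_per_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Score of one column subset of a precomputed token matrix
score_subset <- function(tok, idx) {
  length(unique(do.call(paste, as.data.frame(tok[, idx, drop = FALSE],
                                             stringsAsFactors = FALSE))))
}

#' Randomized panel-combination simulation
#'
#' For each requested size `k`, draws `reps_per_size` uniform random
#' `k`-subsets of the markers (each subset without replacement of markers;
#' repeats across draws are allowed and not deduplicated), scores each by
#' discernibility, and retains every distinct subset achieving that size's
#' maximum. Results are byte-reproducible given the seed; the caller's RNG
#' state is left untouched. Retained subsets are reported with marker ids
#' sorted lexicographically.
#'
#' @param x a `genotype_matrix`.
#' @param config a [sim_config()].
#' @param missing_mode as in [discernibility()] (`"distinct"` is the mode
#'   the string-join comparison implies and the default).
#' @return list with one element per size: `size`, `best_discernibility`,
#'   `best_n_unique`, `best_subsets` (list of sorted id vectors), `reps`;
#'   plus attribute `meta` recording seed and RNG kind.
#' @export
simulate_combinations <- function(x, config,
                                  missing_mode = c("distinct", "wildcard")) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(inherits(config, "sim_config"))
  m <- n_markers(x)
  if (any(config$panel_sizes > m))
    stop("panel size exceeds marker count (", m, ")")
  if (missing_mode == "wildcard")
    return(simulate_combinations_slow(x, config))
  tok <- genotype_tokens(x, x$markers$id)
  res <- withr::with_seed(config$seed, {
    lapply(config$panel_sizes, function(k) {
      best <- -1L
      best_sets <- list()
      for (r in seq_len(config$reps_per_size)) {
        idx <- sample.int(m, k)
        s <- score_subset(tok, idx)
        if (s > best) {
          best <- s
          best_sets <- list(sort(x$markers$id[idx]))
        } else if (s == best) {
          ids <- sort(x$markers$id[idx])
          if (!any(vapply(best_sets, identical, logical(1), y = ids)))
            best_sets <- c(best_sets, list(ids))
        }
      }
      ord <- order(vapply(best_sets, paste, character(1), collapse = "|"))
      list(size = k, best_discernibility = best / n_samples(x),
           best_n_unique = best, best_subsets = best_sets[ord],
           reps = config$reps_per_size)
    })
  })
  names(res) <- paste0("k", config$panel_sizes)
  attr(res, "meta") <- list(seed = config$seed, rng_kind = RNGkind()[1],
                            n_markers = m, n_samples = n_samples(x),
                            missing_mode = missing_mode)
  res
}

# wildcard mode has no fast string path; reuse discernibility() per draw
simulate_combinations_slow <- function(x, config) {
  m <- n_markers(x)
  res <- withr::with_seed(config$seed, {
    lapply(config$panel_sizes, function(k) {
      best <- -1L; best_sets <- list()
      for (r in seq_len(config$reps_per_size)) {
        ids <- x$markers$id[sample.int(m, k)]
        s <- discernibility(x, ids, "wildcard")$n_unique
        if (s > best) { best <- s; best_sets <- list(sort(ids)) }
        else if (s == best) {
          ids <- sort(ids)
          if (!any(vapply(best_sets, identical, logical(1), y = ids)))
            best_sets <- c(best_sets, list(ids))
        }
      }
      ord <- order(vapply(best_sets, paste, character(1), collapse = "|"))
      list(size = k, best_discernibility = best / n_samples(x),
           best_n_unique = best, best_subsets = best_sets[ord],
           reps = config$reps_per_size)
    })
  })
  names(res) <- paste0("k", config$panel_sizes)
  attr(res, "meta") <- list(seed = config$seed, rng_kind = RNGkind()[1],
                            n_markers = m, n_samples = n_samples(x),
                            missing_mode = "wildcard")
  res
}

#' Exhaustive panel enumeration (small marker sets)
#'
#' Enumerates every `k`-subset of the markers and returns the true optimum
#' — the oracle counterpart of [simulate_combinations()], practical for
#' roughly 20 markers or fewer.
#'
#' @inheritParams discernibility
#' @param k subset size.
#' @param max_subsets guard on `choose(m, k)` (default 2e6).
#' @return list as one element of [simulate_combinations()]'s result, with
#'   `reps` equal to the number of subsets enumerated.
#' @export
exhaustive_panels <- function(x, k, missing_mode = c("distinct", "wildcard"),
                              max_subsets = 2e6) {
  missing_mode <- match.arg(missing_mode)
  m <- n_markers(x)
  stopifnot(k >= 1, k <= m)
  if (choose(m, k) > max_subsets)
    stop("choose(", m, ",", k, ") exceeds max_subsets")
  tok <- genotype_tokens(x, x$markers$id)
  combos <- utils::combn(m, k)
  scores <- apply(combos, 2, function(idx)
    if (missing_mode == "distinct") score_subset(tok, idx)
    else length(genotype_groups(tok[, idx, drop = FALSE], "wildcard")))
  best <- max(scores)
  keep <- which(scores == best)
  sets <- lapply(keep, function(j) sort(x$markers$id[combos[, j]]))
  ord <- order(vapply(sets, paste, character(1), collapse = "|"))
  list(size = k, best_discernibility = best / n_samples(x),
       best_n_unique = best, best_subsets = sets[ord], reps = ncol(combos))
}

#' Smallest panel matching full-panel discernibility
#'
#' Scans panel sizes in ascending order and returns the first size whose
#' best simulated (or exhaustively enumerated) discernibility equals the
#' discernibility of the complete marker set, together with the achieving
#' subsets. The full panel always achieves its own score, so the scan
#' terminates.
#'
#' @inheritParams simulate_combinations
#' @param exhaustive enumerate all subsets instead of random draws
#'   (small marker sets only).
#' @return list with `k`, `target_discernibility`, `target_n_unique`,
#'   `best_subsets`, and `per_size` (the scanned results).
#' @export
minimal_panel_size <- function(x, config,
                               missing_mode = c("distinct", "wildcard"),
                               exhaustive = FALSE) {
  missing_mode <- match.arg(missing_mode)
  full <- discernibility(x, x$markers$id, missing_mode)
  sizes <- sort(config$panel_sizes)
  per_size <- list()
  for (k in sizes) {
    r <- if (exhaustive) exhaustive_panels(x, k, missing_mode)
         else simulate_combinations(x, sim_config(k, config$reps_per_size,
                                                  config$seed),
                                    missing_mode)[[1]]
    per_size[[paste0("k", k)]] <- r
    if (r$best_n_unique >= full$n_unique)
      return(list(k = k, target_discernibility = full$discernibility,
                  target_n_unique = full$n_unique,
                  best_subsets = r$best_subsets, per_size = per_size))
  }
  # ensure the full size itself is present as the fallback answer
  k <- n_markers(x)
  r <- list(size = k, best_discernibility = full$discernibility,
            best_n_unique = full$n_unique,
            best_subsets = list(sort(x$markers$id)), reps = 1L)
  per_size[[paste0("k", k)]] <- r
  list(k = k, target_discernibility = full$discernibility,
       target_n_unique = full$n_unique, best_subsets = r$best_subsets,
       per_size = per_size)
}

#' Cumulative marker-efficiency curve
#'
#' Best simulated discernibility per panel size, together with the running
#' maximum over sizes. The per-size maxima from random draws can dip
#' non-monotonically by sampling noise; the running maximum is the smoothed
#' curve conventionally plotted.
#'
#' @inheritParams simulate_combinations
#' @return data.frame with `size`, `best_discernibility`, `running_max`,
#'   `reps`.
#' @export
efficiency_curve <- function(x, config,
                             missing_mode = c("distinct", "wildcard")) {
  missing_mode <- match.arg(missing_mode)
  res <- simulate_combinations(x, config, missing_mode)
  d <- data.frame(size = vapply(res, `[[`, integer(1), "size"),
                  best_discernibility = vapply(res, `[[`, numeric(1),
                                               "best_discernibility"),
                  reps = vapply(res, `[[`, integer(1), "reps"))
  d <- d[order(d$size), , drop = FALSE]
  d$running_max <- cummax(d$best_discernibility)
  rownames(d) <- NULL
  d[, c("size", "best_discernibility", "running_max", "reps")]
}
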