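# Dual-index barcode design: fixed-length index sets with a minimum
# pairwise edit-distance guarantee and balanced per-position base
# composition.

#' Levenshtein (or Hamming) distance between two sequences
#'
#' Plain dynamic-programming implementation (insertions, deletions and
#' substitutions all cost 1), used as the package's independent verifier
#' for constructed index sets.
#'
#' @param a,b Character scalars.
#' @param metric `"levenshtein"` or `"hamming"` (Hamming requires equal
#'   lengths).
#' @return Integer distance.
#' @export
edit_distance <- function(a, b, metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (metric == "hamming") {
    if (length(x) != length(y))
      stop("hamming distance needs equal lengths")
    return(sum(x != y))
  }
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# Minimum pairwise distance within a set, by the package DP.
min_pairwise_distance <- function(seqs, metric = "levenshtein") {
  if (length(seqs) < 2) return(Inf)
  best <- Inf
  for (i in seq_len(length(seqs) - 1))
    for (j in (i + 1):length(seqs))
      best <- min(best, edit_distance(seqs[i], seqs[j], metric))
  best
}

# Fast pairwise distances during construction (utils::adist for
# Levenshtein; vectorized comparison for Hamming).
construction_dist <- function(candidate, accepted, metric) {
  if (!length(accepted)) return(numeric(0))
  if (metric == "levenshtein")
    as.numeric(utils::adist(candidate, accepted))
  else
    vapply(strsplit(accepted, ""), function(y)
      sum(strsplit(candidate, "")[[1]] != y), 0)
}

position_freqs <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  apply(m, 2, function(col)
    table(factor(col, levels = DNA_BASES)) / length(seqs))
}

balance_violation <- function(seqs, tol) {
  f <- position_freqs(seqs)
  sum(pmax(abs(f - 0.25) - tol, 0))
}

# Pick `size` sequences from `pool` with per-position base frequencies
# within `tol` of 0.25. Hill-climbs by first-improvement swaps from
# several starting subsets (the swap landscape has local minima for
# small sizes); NULL if no start reaches zero violation.
balanced_subset <- function(pool, size, tol, n_starts = 25) {
  if (length(pool) < size) return(NULL)
  if (!is.finite(tol)) return(pool[seq_len(size)])
  # descend on the smooth sum-of-squares deviation from uniform (the
  # thresholded violation is flat over wide regions and strands the
  # search); stop as soon as the tolerance itself is met
  smooth <- function(sel) sum((position_freqs(pool[sel]) - 0.25)^2)
  climb <- function(sel) {
    v <- smooth(sel)
    repeat {
      if (balance_violation(pool[sel], tol) <= 0) return(sel)
      improved <- FALSE
      outside <- setdiff(seq_along(pool), sel)
      for (i in seq_len(size)) {
        for (j in outside) {
          cand <- sel
          cand[i] <- j
          v2 <- smooth(cand)
          if (v2 < v - 1e-12) {
            sel <- cand
            v <- v2
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) return(NULL)
    }
  }
  res <- climb(seq_len(size))
  start <- 1
  while (is.null(res) && start < n_starts) {
    res <- climb(sample(length(pool), size))
    start <- start + 1
  }
  if (is.null(res)) NULL else pool[res]
}

#' Generate balanced dual-index barcode sets
#'
#' Builds two disjoint sets of fixed-length DNA indexes (one for each
#' primer side) whose pairwise edit distance within each set is at least
#' `min_edit_distance` and whose per-position base frequencies are within
#' `balance_tolerance` of uniform. Construction is a randomized greedy
#' scan over a seeded shuffle of candidate sequences, followed by a
#' balance-driven subset search, with up to `restarts` restarts;
#' deterministic given `seed`. Fails explicitly when infeasible within
#' the restart budget.
#'
#' The constructed sets are re-verified with the package's own
#' dynamic-programming [edit_distance()] rather than trusted from
#' construction.
#'
#' @param length Index length in nt (>= `min_edit_distance`).
#' @param set_size Number of indexes per set.
#' @param min_edit_distance Pairwise distance floor within each set.
#' @param balance_tolerance Allowed deviation of per-position base
#'   frequencies from 0.25.
#' @param seed Integer seed.
#' @param restarts Maximum restarts before giving up.
#' @param metric `"levenshtein"` (default) or `"hamming"`.
#' @param cross_set_min_dist Optional distance floor enforced between
#'   the two sets as well (default: within-set only).
#' @return List of class `index_design`: `p5` and `p7` (each of class
#'   `index_set` with `sequences`, `length`, `min_distance`,
#'   `composition`), plus `metric` and `attempts`.
#' @export
generate_indexes <- function(length = 7, set_size = 30,
                             min_edit_distance = 4,
                             balance_tolerance = 0.15, seed = 1,
                             restarts = 50,
                             metric = c("levenshtein", "hamming"),
                             cross_set_min_dist = NULL) {
  metric <- match.arg(metric)
  stopifnot_scalar_count(set_size, "set_size", min = 1)
  stopifnot_scalar_count(length, "length", min = 1)
  if (min_edit_distance < 1 || min_edit_distance > length)
    stop("need length >= min_edit_distance >= 1")

  universe <- if (length <= 8) {
    do.call(paste0, expand.grid(rep(list(DNA_BASES), length),
                                stringsAsFactors = FALSE))
  } else NULL
  # composition near 0.25 per position is unattainable by pigeonhole for
  # very small sets; the balance constraint applies from 8 sequences up
  tol_eff <- if (set_size < 8) Inf else balance_tolerance
  pool_cap <- max(4L * set_size, set_size + 20L)

  for (attempt in seq_len(restarts)) {
    sets <- with_seed(derive_seed(seed, attempt), {
      cand <- if (is.null(universe)) {
        unique(vapply(seq_len(200000), function(i)
          paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""),
          ""))
      } else sample(universe)
      p5_pool <- greedy_pool(cand, min_edit_distance, metric, pool_cap)
      p5 <- balanced_subset(p5_pool, set_size, tol_eff)
      if (is.null(p5)) NULL else {
        cand2 <- setdiff(cand, p5)
        if (!is.null(cross_set_min_dist)) {
          ok <- vapply(cand2, function(s)
            all(construction_dist(s, p5, metric) >= cross_set_min_dist),
            TRUE)
          cand2 <- cand2[ok]
        }
        p7_pool <- greedy_pool(cand2, min_edit_distance, metric, pool_cap)
        p7 <- balanced_subset(p7_pool, set_size, tol_eff)
        if (is.null(p7)) NULL else list(p5 = p5, p7 = p7)
      }
    })
    if (!is.null(sets)) {
      out <- list(p5 = as_index_set(sets$p5, metric),
                  p7 = as_index_set(sets$p7, metric),
                  metric = metric, attempts = attempt)
      for (side in c("p5", "p7"))
        if (out[[side]]$min_distance < min_edit_distance)
          stop("internal error: constructed set fails distance floor")
      class(out) <- "index_design"
      return(out)
    }
  }
  stop("index construction failed after ", restarts, " attempts; ",
       "parameters are likely infeasible (set_size too large for the ",
       "distance-", min_edit_distance, " code capacity at length ",
       length, ")")
}

# Greedy packing: accept candidates whose distance to all accepted
# sequences meets the floor. Scans the whole candidate stream so the
# pool is as large as this shuffle allows.
greedy_pool <- function(candidates, floor, metric, max_pool = 200) {
  accepted <- character(0)
  for (s in candidates) {
    if (!length(accepted) ||
        min(construction_dist(s, accepted, metric)) >= floor)
      accepted <- c(accepted, s)
    if (length(accepted) >= max_pool) break
  }
  accepted
}

as_index_set <- function(seqs, metric) {
  structure(list(sequences = seqs,
                 length = nchar(seqs[1]),
                 min_distance = min_pairwise_distance(seqs, metric),
                 composition = position_freqs(seqs)),
            class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index_set: %d sequences of %d nt, min pairwise distance %d\n",
              length(x$sequences), x$length, x$min_distance))
  invisible(x)
}

#' @export
print.index_design <- function(x, ...) {
  cat(sprintf("index_design (%s): P5 %d + P7 %d indexes (attempt %d)\n",
              x$metric, length(x$p5$sequences), length(x$p7$sequences),
              x$attempts))
  invisible(x)
}

#' Write index sets as a two-column TSV
#'
#' @param design A [generate_indexes()] result.
#' @param path Output path.
#' @export
write_index_sets <- function(design, path) {
  df <- rbind(data.frame(set = "P5", index = design$p5$sequences),
              data.frame(set = "P7", index = design$p7$sequences))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
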