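# Per-gene maximum-likelihood tree estimation: NJ start, per-branch Brent
# branch-length optimization, first-improvement NNI hill-climb, and
# nonparametric bootstrap support.

# Internal-edge bipartitions keyed by edge row index.
edge_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  desc <- descendant_tips(tree)
  internal <- which(tree$edge[, 2] > n)
  split <- vapply(internal, function(e) {
    side <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  data.frame(edge = internal, split = split, stringsAsFactors = FALSE)
}

total_loglik <- function(enc, tree, model, cat_rates = NULL) {
  sum(enc$weights * pruning_pattern_loglik(enc, tree, model, cat_rates))
}

# Cycle per-branch Brent optimization until the log-likelihood improves
# by less than `tol`.
optimize_branch_lengths <- function(tree, enc, model, cat_rates = NULL,
                                    max_cycles = 20, tol = 1e-4,
                                    brent_tol = 1e-6, upper = 10) {
  cur <- total_loglik(enc, tree, model, cat_rates)
  for (cycle in seq_len(max_cycles)) {
    prev <- cur
    for (k in seq_len(nrow(tree$edge))) {
      tr_k <- tree
      f <- function(x) {
        tr_k$edge.length[k] <- x
        total_loglik(enc, tr_k, model, cat_rates)
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = brent_tol)
      if (opt$objective > cur) {
        tree$edge.length[k] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  attr(tree, "logLik") <- cur
  tree
}

#' Estimate a maximum-likelihood gene tree
#'
#' Neighbor-joining start from JC-corrected distances, per-branch Brent
#' branch-length optimization, and a first-improvement NNI hill-climb on
#' the log-likelihood. Deterministic: NNI candidates are scanned in a
#' fixed canonical order and the first strictly improving rearrangement
#' is accepted.
#'
#' @param alignment Character matrix (>= 3 sequences).
#' @param model A [substitution_model()]. If `gamma_shape` is `NA` the
#'   shape is estimated by bounded 1-D optimization in [0.02, 100].
#' @param search_config List: `nni` (logical, default TRUE),
#'   `max_nni_rounds` (default 20), `bl_cycles`, `upper` branch-length
#'   bound.
#' @return Unrooted `phylo` with optimized branch lengths; attributes
#'   `logLik` and (when estimated) `gamma_shape`.
#' @export
estimate_gene_tree <- function(alignment, model = substitution_model("JC"),
                               search_config = list()) {
  check_alignment(alignment)
  if (nrow(alignment) < 3) stop("need >= 3 sequences")
  cfg <- utils::modifyList(list(nni = TRUE, max_nni_rounds = 20,
                                bl_cycles = 20, candidate_cycles = 2,
                                upper = 10, jitter = 0, seed = 1),
                           search_config)
  start <- nj_start_tree(alignment, jitter = cfg$jitter, seed = cfg$seed)
  enc <- encode_alignment(alignment[start$tip.label, , drop = FALSE])

  estimate_shape <- !is.null(model$gamma_shape) && is.na(model$gamma_shape)
  shape <- if (estimate_shape) 1 else model$gamma_shape
  cat_rates <- if (is.null(shape)) 1
               else discrete_gamma_rates(shape, model$n_categories)

  tree <- optimize_branch_lengths(start, enc, model, cat_rates,
                                  max_cycles = cfg$bl_cycles,
                                  upper = cfg$upper)
  if (estimate_shape) {
    for (it in 1:2) {
      opt <- stats::optimize(function(a)
        total_loglik(enc, tree, model,
                     discrete_gamma_rates(a, model$n_categories)),
        c(0.02, 100), maximum = TRUE, tol = 1e-3)
      shape <- opt$maximum
      cat_rates <- discrete_gamma_rates(shape, model$n_categories)
      tree <- optimize_branch_lengths(tree, enc, model, cat_rates,
                                      max_cycles = cfg$bl_cycles,
                                      upper = cfg$upper)
    }
  }

  if (cfg$nni && length(start$tip.label) >= 4) {
    for (round in seq_len(cfg$max_nni_rounds)) {
      cur <- attr(tree, "logLik")
      improved <- FALSE
      neighbors <- phangorn::nni(tree)
      for (nb_i in seq_along(neighbors)) {
        nb <- neighbors[[nb_i]]   # `[[` restores tip labels on multiPhylo
        if (is.null(nb$edge.length))
          nb$edge.length <- rep(mean(tree$edge.length), nrow(nb$edge))
        # cheap screening cycles first; full optimization on acceptance
        cand <- optimize_branch_lengths(nb, enc, model, cat_rates,
                                        max_cycles = cfg$candidate_cycles,
                                        upper = cfg$upper)
        if (attr(cand, "logLik") > cur + 1e-8) {
          tree <- optimize_branch_lengths(cand, enc, model, cat_rates,
                                          max_cycles = cfg$bl_cycles,
                                          upper = cfg$upper)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  if (estimate_shape) attr(tree, "gamma_shape") <- shape
  tree
}

# `jitter` adds symmetric noise to the NJ distances (resolves ties on
# signal-free data; off by default so searches are reproducible).
nj_start_tree <- function(alignment, jitter = 0, seed = 1) {
  d <- jc_distance(alignment)
  if (jitter > 0) {
    m <- as.matrix(d)
    noise <- with_seed(seed, {
      x <- matrix(stats::runif(length(m), 0, jitter), nrow(m))
      (x + t(x)) / 2
    })
    diag(noise) <- 0
    d <- stats::as.dist(m + noise)
  }
  tr <- ape::unroot(ape::nj(d))
  tr$edge.length[tr$edge.length < 0] <- 1e-8
  tr
}

#' Jukes-Cantor corrected pairwise distances
#'
#' Pairwise deletion of non-ACGT residues; saturated pairs (p >= 0.75)
#' are capped at 3 substitutions per site.
#'
#' @param alignment Character matrix.
#' @return A `dist` object.
#' @export
jc_distance <- function(alignment) {
  n <- nrow(alignment)
  m <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  al <- toupper(alignment)
  ok <- al %in% DNA_BASES
  dim(ok) <- dim(al)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    p <- if (any(use)) mean(al[i, use] != al[j, use]) else 0
    d <- if (p >= 0.75) 3 else -0.75 * log(1 - 4 * p / 3)
    m[i, j] <- m[j, i] <- d
  }
  stats::as.dist(m)
}

#' Nonparametric bootstrap support for a gene tree
#'
#' Resamples alignment columns with replacement, re-estimates the tree
#' for each replicate with [estimate_gene_tree()], and reports for every
#' internal branch of the best tree the percentage of replicate trees
#' containing the same bipartition. The mean support is the arithmetic
#' mean over internal branches (pendant branches are excluded).
#'
#' @param alignment Character matrix.
#' @param model A [substitution_model()].
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; replicate `b` uses a stream derived from
#'   `(seed, b)`.
#' @param search_config Passed to [estimate_gene_tree()].
#' @return List of class `bootstrap_result`: `tree` (node labels carry
#'   the supports), `supports` (named by bipartition), `mean_support`.
#' @export
bootstrap_support <- function(alignment, model = substitution_model("JC"),
                              n_replicates = 100, seed = 1,
                              search_config = list()) {
  stopifnot_scalar_count(n_replicates, "n_replicates", min = 1)
  best <- estimate_gene_tree(alignment, model, search_config)
  splits <- edge_bipartitions(best)
  splits <- splits[!is.na(splits$split), , drop = FALSE]
  counts <- stats::setNames(rep(0, nrow(splits)), splits$split)
  for (b in seq_len(n_replicates)) {
    cols <- with_seed(derive_seed(seed, b),
                      sample.int(ncol(alignment), replace = TRUE))
    cfg_b <- search_config
    cfg_b$seed <- derive_seed(seed, 100000 + b)
    rep_tree <- estimate_gene_tree(alignment[, cols, drop = FALSE],
                                   model, cfg_b)
    present <- tree_bipartitions(rep_tree)
    hit <- names(counts) %in% present
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_replicates
  n <- length(best$tip.label)
  labels <- rep("", best$Nnode)
  for (i in seq_len(nrow(splits))) {
    node <- best$edge[splits$edge[i], 2]
    labels[node - n] <- format(supports[i], digits = 4)
  }
  best$node.label <- labels
  structure(list(tree = best, supports = supports,
                 mean_support = if (length(supports)) mean(supports)
                                else NA_real_),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d internal branches, mean support %.1f\n",
              length(x$supports), x$mean_support))
  invisible(x)
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' @param gene_alignments Named list of character matrices; names are
#'   gene ids (must be unique). Samples absent from a gene are filled
#'   with `-`.
#' @return List of class `supermatrix`: `alignment` and `partitions`
#'   (`gene`, `start`, `end`, 1-based inclusive, in input gene order).
#' @export
concatenate_alignments <- function(gene_alignments) {
  if (length(gene_alignments) < 1) stop("need >= 1 gene")
  ids <- names(gene_alignments)
  if (is.null(ids) || anyDuplicated(ids))
    stop("gene ids must be unique and named")
  samples <- sort(unique(unlist(lapply(gene_alignments, rownames))))
  widths <- vapply(gene_alignments, ncol, 0L)
  total <- sum(widths)
  aln <- matrix("-", length(samples), total,
                dimnames = list(samples, NULL))
  at <- 0L
  parts <- data.frame(gene = ids, start = integer(length(ids)),
                      end = integer(length(ids)), stringsAsFactors = FALSE)
  for (k in seq_along(gene_alignments)) {
    g <- gene_alignments[[k]]
    span <- (at + 1L):(at + ncol(g))
    aln[rownames(g), span] <- toupper(g)
    parts$start[k] <- at + 1L
    parts$end[k] <- at + ncol(g)
    at <- at + ncol(g)
  }
  structure(list(alignment = aln, partitions = parts),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d samples x %d bp, %d partitions\n",
              nrow(x$alignment), ncol(x$alignment), nrow(x$partitions)))
  invisible(x)
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `DNA, <gene> = <start>-<end>` (1-based inclusive).
#'
#' @param supermatrix A [concatenate_alignments()] result.
#' @param path Output path.
#' @export
write_partition_file <- function(supermatrix, path) {
  p <- supermatrix$partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$gene, p$start, p$end), path)
  invisible(path)
}

#' Root a tree on an outgroup
#'
#' Fails (rather than silently forcing) when the outgroup is not a clade
#' of the unrooted tree.
#'
#' @param tree Unrooted (or rooted) `phylo`.
#' @param outgroup_labels Non-empty character vector of tip labels.
#' @return Rooted `phylo`; the ingroup topology is unchanged.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  if (length(outgroup_labels) == 0) stop("outgroup must be non-empty")
  if (!all(outgroup_labels %in% tree$tip.label))
    stop("outgroup labels missing from tree")
  n <- length(tree$tip.label)
  if (length(outgroup_labels) > 1 && length(outgroup_labels) < n - 1) {
    want <- paste(sort(outgroup_labels), collapse = "|")
    anchor <- sort(tree$tip.label)[1]
    comp <- paste(sort(setdiff(tree$tip.label, outgroup_labels)),
                  collapse = "|")
    splits <- tree_bipartitions(tree)
    key <- if (anchor %in% outgroup_labels) comp else want
    if (!key %in% splits)
      stop("outgroup is not monophyletic in the unrooted tree")
  }
  ape::root(ape::unroot(tree), outgroup = outgroup_labels,
            resolve.root = TRUE)
}
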