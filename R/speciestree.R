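# Quartet-based coalescent species-tree estimation: quartet score,
# exhaustive search for small species sets (greedy insertion + NNI above
# that), per-branch quartet support for the three resolutions, and local
# posterior probabilities under the multispecies-coalescent quartet law.

# Materialize a multiPhylo as a plain list (the `[[` method restores
# compressed tip labels; `for`/`vapply` over the raw object does not).
tree_list <- function(x) lapply(seq_along(x), function(i) x[[i]])

canonical_mapping <- function(gene_trees, mapping) {
  if (is.null(mapping)) {
    inds <- sort(unique(unlist(lapply(gene_trees,
                                      function(t) t$tip.label))))
    mapping <- data.frame(individual = inds, species = inds,
                          stringsAsFactors = FALSE)
  }
  leaves <- unique(unlist(lapply(gene_trees, function(t) t$tip.label)))
  unmapped <- setdiff(leaves, mapping$individual)
  if (length(unmapped))
    stop("gene-tree leaf not in mapping: ", paste(unmapped, collapse = ", "))
  mapping
}

# Resolution of quartet (a,b,c,d) from a topological distance matrix:
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved (tie).
resolve_quartet <- function(D, a, b, c, d) {
  s <- c(D[a, b] + D[c, d], D[a, c] + D[b, d], D[a, d] + D[b, c])
  i <- which.min(s)
  if (sum(s == s[i]) > 1) 0L else i
}

# Tally, per species 4-subset and canonical resolution, the number of
# (gene tree, individual combination) induced quartets. Canonical order:
# subsets are columns of combn(sorted species, 4); resolution 1 pairs the
# two lowest-sorted species.
quartet_tallies <- function(gene_trees, mapping, species = NULL) {
  if (is.null(species)) species <- sort(unique(mapping$species))
  if (length(species) < 4) stop("need >= 4 species")
  subsets <- utils::combn(species, 4)
  counts <- matrix(0, 3, ncol(subsets))
  inds <- split(mapping$individual, mapping$species)
  for (g in gene_trees) {
    D <- topo_dist(g)
    present <- rownames(D)
    for (s in seq_len(ncol(subsets))) {
      sp4 <- subsets[, s]
      combos <- expand.grid(lapply(inds[sp4], function(v)
        v[v %in% present]), stringsAsFactors = FALSE)
      if (!nrow(combos)) next
      for (r in seq_len(nrow(combos))) {
        res <- resolve_quartet(D, combos[r, 1], combos[r, 2],
                               combos[r, 3], combos[r, 4])
        if (res > 0) counts[res, s] <- counts[res, s] + 1
      }
    }
  }
  list(species = species, subsets = subsets, counts = counts)
}

# Resolution index of every tallied subset induced by a species tree
# (0 where the tree does not cover the subset).
tree_subset_resolutions <- function(tree, tallies) {
  D <- topo_dist(tree)
  have <- rownames(D)
  vapply(seq_len(ncol(tallies$subsets)), function(s) {
    sp4 <- tallies$subsets[, s]
    if (!all(sp4 %in% have)) return(0L)
    as.integer(resolve_quartet(D, sp4[1], sp4[2], sp4[3], sp4[4]))
  }, 0L)
}

score_from_tallies <- function(tree, tallies) {
  res <- tree_subset_resolutions(tree, tallies)
  ok <- res > 0
  sum(tallies$counts[cbind(res[ok], which(ok))])
}

#' Quartet score of a species tree against gene trees
#'
#' The total number of (gene tree, four-leaf subset) induced quartet
#' topologies that agree with the species tree's induced quartet over the
#' corresponding species; with several individuals per species the count
#' runs over all individual choices.
#'
#' @param species_tree Binary `phylo` over species labels.
#' @param gene_trees List of `phylo` over individual labels.
#' @param mapping Data frame (`individual`, `species`), or `NULL` when
#'   gene-tree leaves are species labels.
#' @return Integer score.
#' @export
quartet_score <- function(species_tree, gene_trees, mapping = NULL) {
  mapping <- canonical_mapping(gene_trees, mapping)
  tallies <- quartet_tallies(gene_trees, mapping,
                             sort(species_tree$tip.label))
  score_from_tallies(species_tree, tallies)
}

#' Estimate a species tree by maximizing the quartet score
#'
#' For up to `exact_max_taxa` species the maximizer is found by scoring
#' every unrooted topology; above that, species are inserted greedily in
#' order of decreasing appearance frequency and the result is refined by
#' a first-improvement NNI hill-climb on the quartet score. Ties are
#' broken by enumeration order, so the search is deterministic.
#'
#' @param gene_trees List of `phylo` gene trees.
#' @param mapping Data frame (`individual`, `species`) or `NULL`.
#' @param search_config List: `exact_max_taxa` (default 8).
#' @return List of class `species_tree_result`: `tree` (unrooted
#'   `phylo`), `score`, `support` (per-branch [quartet_support()] table),
#'   `n_genes`.
#' @export
estimate_species_tree <- function(gene_trees, mapping = NULL,
                                  search_config = list()) {
  cfg <- utils::modifyList(list(exact_max_taxa = 8), search_config)
  if (length(gene_trees) < 1) stop("need >= 1 gene tree")
  mapping <- canonical_mapping(gene_trees, mapping)
  species <- sort(unique(mapping$species))
  if (length(species) < 4) stop("need >= 4 species")
  tallies <- quartet_tallies(gene_trees, mapping, species)

  if (length(species) <= cfg$exact_max_taxa) {
    cand <- tree_list(phangorn::allTrees(length(species), rooted = FALSE,
                                         tip.label = species))
    scores <- vapply(cand, score_from_tallies, 0, tallies = tallies)
    best <- cand[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    freq <- vapply(species, function(sp) {
      inds <- mapping$individual[mapping$species == sp]
      sum(vapply(gene_trees, function(g) any(inds %in% g$tip.label), TRUE))
    }, 0)
    ord <- species[order(-freq, species)]
    cand4 <- tree_list(phangorn::allTrees(4, rooted = FALSE,
                                          tip.label = sort(ord[1:4])))
    s4 <- vapply(cand4, score_from_tallies, 0, tallies = tallies)
    best <- cand4[[which.max(s4)]]
    for (sp in ord[-(1:4)]) {
      trials <- lapply(seq_len(nrow(best$edge)), function(e)
        bind_tip_to_edge(best, sp, e))
      sc <- vapply(trials, score_from_tallies, 0, tallies = tallies)
      best <- trials[[which.max(sc)]]
    }
    best_score <- score_from_tallies(best, tallies)
    repeat {
      improved <- FALSE
      for (nb in tree_list(phangorn::nni(best))) {
        s <- score_from_tallies(nb, tallies)
        if (s > best_score) {
          best <- nb; best_score <- s; improved <- TRUE; break
        }
      }
      if (!improved) break
    }
  }
  best$edge.length <- NULL
  support <- quartet_support(best, gene_trees, mapping, tallies = tallies)
  structure(list(tree = best, score = best_score, support = support,
                 n_genes = length(gene_trees)),
            class = "species_tree_result")
}

#' @export
print.species_tree_result <- function(x, ...) {
  cat(sprintf("species_tree_result: %d species, %d gene trees, quartet score %d\n",
              length(x$tree$tip.label), x$n_genes, x$score))
  cat(sprintf("  mean q1 over %d internal branches: %.3f\n",
              nrow(x$support), mean(x$support$q1)))
  invisible(x)
}

# Insert a new tip halfway along edge `edge`; works on topology-only
# trees by giving every edge unit length first.
bind_tip_to_edge <- function(tree, label, edge) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
              edge.length = 1, Nnode = 1L)
  class(tip) <- "phylo"
  out <- ape::bind.tree(tree, tip, where = tree$edge[edge, 2],
                        position = tree$edge.length[edge] / 2)
  out$edge.length <- rep(1, nrow(out$edge))
  out
}

# Quadripartition (A, B, C, D) of species around every internal edge.
edge_quadripartitions <- function(tree) {
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  children <- vector("list", max(tree$edge))
  parent <- integer(max(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    children[[p]] <- c(children[[p]], ch)
    parent[ch] <- p
  }
  tips <- function(v) tree$tip.label[desc[[v]]]
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch <= n) next
    p <- tree$edge[k, 1]
    kids <- children[[ch]]
    if (length(kids) != 2) next
    A <- tips(kids[1]); B <- tips(kids[2])
    sibs <- setdiff(children[[p]], ch)
    if (length(sibs) == 1) {
      C <- tips(sibs[1])
      D <- setdiff(tree$tip.label, c(A, B, C))
    } else {
      C <- tips(sibs[1]); D <- tips(sibs[2])
    }
    if (!length(D)) next
    out[[length(out) + 1]] <- list(edge = k, node = ch,
                                   groups = list(A = A, B = B, C = C, D = D))
  }
  out
}

#' Per-branch quartet support for the three resolutions
#'
#' For each internal branch of the species tree, tallies over all
#' species quartets spanning the branch's quadripartition (and all gene
#' trees and individual choices) how many induced quartets support the
#' species-tree resolution (`n1`, grouping A+B) versus the two
#' alternatives. Gene-tree quartets that do not resolve the subset
#' (polytomies) are excluded from numerator and denominator.
#'
#' @param species_tree Binary `phylo` over species labels.
#' @param gene_trees List of gene trees.
#' @param mapping Data frame (`individual`, `species`) or `NULL`.
#' @param tallies Internal precomputation, for reuse.
#' @return Data frame: `node` (child node id of the branch), `groups`,
#'   `n1`, `n2`, `n3`, `m`, `q1`, `q2`, `q3`.
#' @export
quartet_support <- function(species_tree, gene_trees, mapping = NULL,
                            tallies = NULL) {
  mapping <- canonical_mapping(gene_trees, mapping)
  species <- sort(unique(c(mapping$species, species_tree$tip.label)))
  if (is.null(tallies))
    tallies <- quartet_tallies(gene_trees, mapping, species)
  key <- apply(tallies$subsets, 2, paste, collapse = "|")
  quads <- edge_quadripartitions(species_tree)
  rows <- lapply(quads, function(qd) {
    g <- qd$groups
    n <- c(0, 0, 0)
    for (a in g$A) for (b in g$B) for (cc in g$C) for (d in g$D) {
      sp4 <- sort(c(a, b, cc, d))
      s <- match(paste(sp4, collapse = "|"), key)
      if (is.na(s)) next
      # canonical resolution r pairs sp4[1] with sp4[r+1]; map each to
      # the branch frame where resolution 1 is AB|CD.
      partners <- sp4[2:4]
      grp <- function(x) c("A", "B", "C", "D")[
        c(x %in% g$A, x %in% g$B, x %in% g$C, x %in% g$D)][1]
      g1 <- grp(sp4[1])
      branch_res <- vapply(partners, function(p2) {
        g2 <- grp(p2)
        pair <- sort(c(g1, g2))
        if (identical(pair, c("A", "B")) || identical(pair, c("C", "D")))
          1L
        else if (identical(pair, c("A", "C")) || identical(pair, c("B", "D")))
          2L
        else 3L
      }, 0L)
      for (r in 1:3) n[branch_res[r]] <- n[branch_res[r]] +
          tallies$counts[r, s]
    }
    m <- sum(n)
    data.frame(node = qd$node,
               groups = paste(vapply(g, paste, "", collapse = ","),
                              collapse = " | "),
               n1 = n[1], n2 = n[2], n3 = n[3], m = m,
               q1 = if (m > 0) n[1] / m else NA_real_,
               q2 = if (m > 0) n[2] / m else NA_real_,
               q3 = if (m > 0) n[3] / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Local posterior probabilities for a branch
#'
#' Posterior probability that each of the three resolutions around a
#' branch is the true species-tree resolution, under the multispecies
#' coalescent where resolving gene-tree quartets follow frequencies
#' `(1 - (2/3) e^{-d}, (1/3) e^{-d}, (1/3) e^{-d})` for internal branch
#' length `d` (coalescent units) with an exponential(`prior_lambda`)
#' prior on `d`. Computed by adaptive quadrature on `d` in (0, 20] with
#' log-domain likelihood evaluation.
#'
#' @param support Either a numeric vector `c(n1, n2, n3)` or one row of a
#'   [quartet_support()] table.
#' @param prior_lambda Rate of the exponential branch-length prior.
#' @return Numeric vector `c(pp1, pp2, pp3)` summing to 1.
#' @export
local_posterior <- function(support, prior_lambda = 0.5) {
  n <- if (is.data.frame(support)) c(support$n1, support$n2, support$n3)
       else as.numeric(support)
  if (length(n) != 3 || any(n < 0)) stop("need counts (n1, n2, n3)")
  m <- sum(n)
  if (m == 0) stop("undefined support: no resolving quartets (m = 0)")
  log_int <- vapply(1:3, function(i) {
    logf <- function(d)
      n[i] * log1p(-(2 / 3) * exp(-d)) +
        (m - n[i]) * (log(1 / 3) - d) +
        log(prior_lambda) - prior_lambda * d
    M <- max(logf(seq(1e-6, 20, length.out = 2001)))
    I <- stats::integrate(function(d) exp(logf(d) - M), 0, 20,
                          rel.tol = 1e-8, abs.tol = 0,
                          subdivisions = 400L)$value
    log(I) + M
  }, 0)
  pp <- exp(log_int - max(log_int))
  pp / sum(pp)
}

#' Annotate a species tree with quartet support and local posteriors
#'
#' Produces a Newick string with the branch's `pp1` as internal-node
#' label and the quartet frequencies in a bracketed comment, plus a
#' summary of the fraction of branches with `pp1 > 0.9`.
#'
#' @param species_tree `phylo` over species (typically
#'   `estimate_species_tree()$tree`).
#' @param supports A [quartet_support()] table covering every internal
#'   branch of the tree.
#' @param prior_lambda Passed to [local_posterior()].
#' @return List of class `annotated_species_tree`: `tree` (node labels =
#'   `pp1`), `newick` (annotated string), `table` (per-branch `n`, `q`,
#'   `pp`), `fraction_pp_high`.
#' @export
annotate_species_tree <- function(species_tree, supports,
                                  prior_lambda = 0.5) {
  quads <- edge_quadripartitions(species_tree)
  need <- vapply(quads, function(q) q$node, 0L)
  if (!all(need %in% supports$node))
    stop("supports do not cover all internal branches")
  pp <- t(vapply(seq_len(nrow(supports)), function(i)
    local_posterior(supports[i, ], prior_lambda), c(0, 0, 0)))
  tab <- cbind(supports, pp1 = pp[, 1], pp2 = pp[, 2], pp3 = pp[, 3])
  n <- length(species_tree$tip.label)
  tree <- species_tree
  tree$node.label <- rep("", tree$Nnode)
  for (i in seq_len(nrow(tab)))
    tree$node.label[tab$node[i] - n] <- sprintf("%.17g", tab$pp1[i])
  comment_of <- stats::setNames(sprintf("[&q1=%.6g,q2=%.6g,q3=%.6g]",
                                        tab$q1, tab$q2, tab$q3), tab$node)
  newick <- write_newick_annotated(tree, comment_of)
  structure(list(tree = tree, newick = newick, table = tab,
                 fraction_pp_high = mean(tab$pp1 > 0.9)),
            class = "annotated_species_tree")
}

#' @export
print.annotated_species_tree <- function(x, ...) {
  cat(sprintf("annotated species tree: %d internal branches, %.0f%% with pp1 > 0.9\n",
              nrow(x$table), 100 * x$fraction_pp_high))
  invisible(x)
}

# Newick serializer with per-internal-node comments after the label.
write_newick_annotated <- function(tree, comment_of = character(0)) {
  n <- length(tree$tip.label)
  children <- vector("list", max(tree$edge))
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]],
                                     tree$edge[k, 2])
  lens <- if (is.null(tree$edge.length)) NULL else {
    l <- numeric(max(tree$edge))
    l[tree$edge[, 2]] <- tree$edge.length
    l
  }
  rec <- function(v) {
    lab <- if (v <= n) tree$tip.label[v] else {
      kids <- paste(vapply(children[[v]], rec, ""), collapse = ",")
      nl <- if (!is.null(tree$node.label)) tree$node.label[v - n] else ""
      cm <- if (as.character(v) %in% names(comment_of))
        comment_of[[as.character(v)]] else ""
      paste0("(", kids, ")", nl, cm)
    }
    if (!is.null(lens) && v != n + 1) paste0(lab, ":", lens[v]) else lab
  }
  paste0(rec(n + 1L), ";")
}

#' Strip bracketed comments and parse an annotated Newick string
#'
#' Inverse of the annotated serializer: removes `[&...]` comment blocks
#' and parses the remainder, so node labels (the `pp1` values) are
#' recovered.
#'
#' @param newick Annotated Newick string.
#' @return A `phylo` with `node.label`.
#' @export
read_newick_annotated <- function(newick) {
  ape::read.tree(text = gsub("\\[[^]]*\\]", "", newick))
}
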