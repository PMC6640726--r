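# Felsenstein pruning likelihood with discrete-gamma rate mixing.

# Per-pattern site log-likelihoods by postorder pruning.
# enc: output of encode_alignment(); lengths are tree$edge.length scaled
# by the caller. Returns a vector over patterns.
pruning_pattern_loglik <- function(enc, tree, model, cat_rates = NULL) {
  if (is.null(cat_rates)) cat_rates <- model_cat_rates(model)
  npat <- length(enc$weights)
  attr(tree, "order") <- NULL   # stale order attributes defeat reorder()
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge
  elen <- tr$edge.length
  if (is.null(elen)) stop("tree has no branch lengths")
  if (any(elen < -1e-12)) stop("negative branch length")
  elen[elen < 0] <- 0
  ntip <- length(tr$tip.label)
  nnode <- max(edges)
  missing_tip <- setdiff(tr$tip.label, names(enc$tips))
  if (length(missing_tip))
    stop("tree leaf without sequence: ", paste(missing_tip, collapse = ", "))
  root <- edges[nrow(edges), 1]

  lik <- rep(0, npat)
  for (r in cat_rates) {
    partial <- vector("list", nnode)
    logscale <- rep(0, npat)
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      P <- transition_prob(model, elen[k] * r)
      L <- if (ch <= ntip) enc$tips[[tr$tip.label[ch]]] else partial[[ch]]
      contrib <- P %*% L
      if (is.null(partial[[p]])) partial[[p]] <- contrib
      else partial[[p]] <- partial[[p]] * contrib
      pp <- partial[[p]]
      mx <- pmax(pp[1, ], pp[2, ], pp[3, ], pp[4, ])
      if (min(mx) < 1e-200) {
        sc <- pmax(mx, 1e-300)
        partial[[p]] <- pp / rep(sc, each = 4)
        logscale <- logscale + log(sc)
      }
    }
    lik <- lik + exp(log(colSums(model$base_freq * partial[[root]])) +
                       logscale) / length(cat_rates)
  }
  log(lik)
}

#' Phylogenetic log-likelihood of an alignment on a tree
#'
#' Exact log-likelihood under a reversible substitution model with
#' optional discrete-gamma rate mixing, computed by Felsenstein's pruning
#' algorithm over compressed site patterns. Gaps, `N` and IUPAC ambiguity
#' codes contribute partial likelihood 1 for each compatible state.
#'
#' @param alignment Character matrix (rows = samples).
#' @param tree `phylo` tree whose tip labels are a subset of the alignment
#'   samples; branch lengths in expected substitutions per site.
#' @param model A [substitution_model()].
#' @return Total log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(alignment, tree, model) {
  check_alignment(alignment)
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop("tree leaf without sequence")
  enc <- encode_alignment(alignment[tree$tip.label, , drop = FALSE])
  sum(enc$weights * pruning_pattern_loglik(enc, tree, model))
}
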