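# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the likelihood oracle enumerates interior
# states, the coalescent oracle tracks lineage merges without building
# trees, and quartet tallies go through ape::keep.tip topology comparison.

# Exponential-time likelihood by summing over all interior-state
# assignments, per site. Only for tiny complete-data fixtures.
brute_force_loglik <- function(alignment, tree, model, cat_rates = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- max(tr$edge)
  internals <- (ntip + 1):nn
  root <- tr$edge[nrow(tr$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  al <- toupper(alignment)[tr$tip.label, , drop = FALSE]
  obs <- matrix(match(al, c("A", "C", "G", "T")), nrow = ntip)
  ll <- 0
  for (site in seq_len(ncol(al))) {
    sl <- 0
    for (r in cat_rates) {
      P <- lapply(seq_len(nrow(tr$edge)), function(k)
        transition_prob(model, tr$edge.length[k] * r))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[seq_len(ntip)] <- obs[, site]
        st[internals] <- grid[g, ]
        pr <- model$base_freq[st[root]]
        for (k in seq_len(nrow(tr$edge)))
          pr <- pr * P[[k]][st[tr$edge[k, 1]], st[tr$edge[k, 2]]]
        tot <- tot + pr
      }
      sl <- sl + tot / length(cat_rates)
    }
    ll <- ll + log(sl)
  }
  ll
}

# Independent coalescent sampler for the 4-taxon caterpillar species
# tree (((A,B):d,C):e,D): returns TRUE when the sampled gene tree's
# unrooted quartet is AB|CD. Works directly in coalescent units and
# never builds a tree.
caterpillar_quartet_match <- function(d, e = 1) {
  # a and b enter the internal branch of length d
  t_ab <- stats::rexp(1, 1)
  if (t_ab <= d) return(TRUE)          # a+b coalesce below ABC ancestor
  # three lineages (a, b, c) in the branch of length e above
  lin <- c("a", "b", "c")
  t <- 0
  while (length(lin) > 1) {
    k <- length(lin)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    if (t > e && k == 3) {
      # fourth lineage d joins at the root: all pairs exchangeable from
      # here on; first merge decides the quartet
      lin <- c(lin, "d")
      pair <- sample(4, 2)
      first <- sort(lin[pair])
      return(identical(first, c("a", "b")) || identical(first, c("c", "d")))
    }
    pair <- sample(k, 2)
    merged <- paste(sort(lin[pair]), collapse = "")
    if (k == 3) return(merged == "ab") # first merge among a,b,c decides
    lin <- c(lin[-pair], merged)
  }
  TRUE
}

# Does a gene tree restricted to four leaves show the split ab|cd?
# Independent route: ape::keep.tip + comparison against the reference
# quartet topology with ape::dist.topo.
quartet_is <- function(gene_tree, a, b, c, d) {
  sub <- ape::unroot(ape::keep.tip(gene_tree, c(a, b, c, d)))
  ref <- ape::read.tree(text = sprintf("((%s,%s),%s,%s);", a, b, c, d))
  ape::dist.topo(sub, ref) == 0
}

# Brute-force quartet score: loop over every 4-subset of species and
# every gene tree through quartet_is().
brute_force_quartet_score <- function(species_tree, gene_trees) {
  species <- species_tree$tip.label
  subsets <- utils::combn(sort(species), 4)
  total <- 0
  for (s in seq_len(ncol(subsets))) {
    sp4 <- subsets[, s]
    sub <- ape::unroot(ape::keep.tip(species_tree, sp4))
    # find the species-tree resolution by testing all three
    for (g in gene_trees) {
      for (perm in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))) {
        p <- sp4[perm]
        if (quartet_is(sub, p[1], p[2], p[3], p[4])) {
          total <- total + quartet_is(g, p[1], p[2], p[3], p[4])
          break
        }
      }
    }
  }
  total
}

# Caterpillar species tree in time units with AB internal branch d
# (coalescent units at theta = 1).
caterpillar_tree <- function(d, e = 1) {
  ape::read.tree(text = sprintf(
    "(((A:1,B:1):%g,C:%g):%g,D:%g);", d, 1 + d, e, 1 + d + e))
}

random_variant_fixture <- function(n_samples = 6, n_sites = 10, seed = 1) {
  al <- matrix(sample(c("A", "C", "G", "T"), n_samples * n_sites,
                      replace = TRUE),
               n_samples, n_sites,
               dimnames = list(paste0("s", seq_len(n_samples)), NULL))
  simulate_variant_table(list(r1 = al), seed = seed)
}
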