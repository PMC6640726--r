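# Synthetic multispecies-coalescent data: species trees, gene trees with
# incomplete lineage sorting, GTR+Gamma alignments, variant tables and
# gene metadata. Every generator is a pure function of its arguments and
# seed; per-gene streams are derived by stable mixing of (seed, gene).

#' Simulate an ultrametric Yule species tree
#'
#' @param n_species Number of species (>= 2).
#' @param birth_rate Speciation rate per unit time (> 0).
#' @param seed Integer seed.
#' @return Rooted, binary, ultrametric `phylo` with tips `sp01`, `sp02`, ...
#'   Branch lengths are in time units; divide by `theta` for coalescent
#'   units.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot_scalar_count(n_species, "n_species", min = 2)
  if (birth_rate <= 0) stop("`birth_rate` must be > 0")
  tr <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Gene lineages coalesce within the branches of `species_tree` at rate
#' `choose(k, 2) / theta` per unit tree time (so a branch of duration `t`
#' spans `t / theta` coalescent units). As `theta -> 0` every gene tree
#' topologically matches the species tree.
#'
#' @param species_tree Ultrametric rooted `phylo` (time units).
#' @param mapping Data frame with columns `individual` and `species`
#'   assigning >= 1 sampled individual to every species, or `NULL` for one
#'   individual per species named like the species.
#' @param n_genes Number of gene trees.
#' @param theta Coalescent population-size parameter (> 0), constant
#'   across branches.
#' @param seed Integer master seed; gene `g` uses a stream derived from
#'   `(seed, g)`.
#' @param subst_scale Substitutions per unit tree time; gene-tree branch
#'   lengths are time durations multiplied by this factor.
#' @return List of `phylo` gene trees over the individual labels.
#' @export
simulate_gene_trees <- function(species_tree, mapping = NULL, n_genes,
                                theta, seed = 1, subst_scale = 1) {
  if (theta <= 0) stop("`theta` must be > 0")
  stopifnot_scalar_count(n_genes, "n_genes", min = 0)
  sp <- species_tree$tip.label
  if (is.null(mapping))
    mapping <- data.frame(individual = sp, species = sp,
                          stringsAsFactors = FALSE)
  if (nrow(mapping) == 0) stop("empty individual-to-species mapping")
  if (!all(c("individual", "species") %in% names(mapping)))
    stop("mapping needs columns `individual` and `species`")
  if (!all(sp %in% mapping$species))
    stop("mapping must assign >= 1 individual to every species")
  if (anyDuplicated(mapping$individual))
    stop("individual labels must be unique")

  ctx <- msc_context(species_tree, mapping)
  lapply(seq_len(max(n_genes, 0)), function(g) {
    with_seed(derive_seed(seed, g), msc_one_gene(ctx, theta, subst_scale))
  })
}

# Precomputed species-tree geometry shared across genes.
msc_context <- function(species_tree, mapping) {
  nt <- length(species_tree$tip.label)
  depth <- ape::node.depth.edgelength(species_tree)
  age <- max(depth) - depth
  age[seq_len(nt)][age[seq_len(nt)] < 1e-12] <- 0
  children <- vector("list", max(species_tree$edge))
  for (k in seq_len(nrow(species_tree$edge))) {
    p <- species_tree$edge[k, 1]
    children[[p]] <- c(children[[p]], species_tree$edge[k, 2])
  }
  inds <- split(mapping$individual, mapping$species)
  list(tree = species_tree, n_tip = nt, age = age, children = children,
       root = nt + 1L, inds = inds,
       internal_order = order(age[(nt + 1):max(species_tree$edge)]) + nt)
}

# One coalescent gene tree, built as a Newick string.
msc_one_gene <- function(ctx, theta, subst_scale) {
  # lineage state: parallel vectors of newick fragments and their ages
  lin_lab <- vector("list", max(ctx$tree$edge))
  lin_age <- vector("list", max(ctx$tree$edge))
  for (i in seq_len(ctx$n_tip)) {
    ind <- ctx$inds[[ctx$tree$tip.label[i]]]
    lin_lab[[i]] <- as.list(ind)
    lin_age[[i]] <- rep(ctx$age[i], length(ind))
  }
  coalesce_interval <- function(lab, age, t0, t1) {
    t <- t0
    while (length(lab) >= 2) {
      k <- length(lab)
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2 / theta)
      if (t > t1) break
      pair <- sample.int(k, 2)
      i <- pair[1]; j <- pair[2]
      merged <- sprintf("(%s:%.10g,%s:%.10g)",
                        lab[[i]], (t - age[[i]]) * subst_scale,
                        lab[[j]], (t - age[[j]]) * subst_scale)
      keep <- setdiff(seq_len(k), c(i, j))
      lab <- c(lab[keep], merged)
      age <- c(age[keep], t)
    }
    list(lab = lab, age = age)
  }
  for (v in ctx$internal_order) {
    lab <- list(); age <- numeric(0)
    for (ch in ctx$children[[v]]) {
      res <- coalesce_interval(lin_lab[[ch]], lin_age[[ch]],
                               ctx$age[ch], ctx$age[v])
      lab <- c(lab, res$lab); age <- c(age, res$age)
    }
    lin_lab[[v]] <- lab; lin_age[[v]] <- age
  }
  res <- coalesce_interval(lin_lab[[ctx$root]], lin_age[[ctx$root]],
                           ctx$age[ctx$root], Inf)
  ape::read.tree(text = paste0(res$lab[[1]], ";"))
}

#' Simulate a sequence alignment on a gene tree
#'
#' Forward simulation under a reversible substitution model with
#' continuous mean-one gamma site-rate variation. Branch `b` and site `i`
#' evolve with effective length `len(b) * r_i * rate_multiplier`.
#'
#' @param gene_tree `phylo` with branch lengths in substitutions per site.
#' @param length Alignment length in bp (>= 1).
#' @param model A [substitution_model()] (its discrete-gamma settings are
#'   ignored here; use `gamma_shape`).
#' @param gamma_shape Shape of the continuous gamma site-rate law, or
#'   `NULL` for rate-homogeneous sites.
#' @param rate_multiplier Per-gene rate multiplier (> 0).
#' @param seed Integer seed.
#' @return Character matrix (rows = tips); true per-site rates are
#'   attached as attribute `site_rates`.
#' @export
simulate_alignment <- function(gene_tree, length,
                               model = substitution_model("JC"),
                               gamma_shape = NULL, rate_multiplier = 1,
                               seed = 1) {
  stopifnot_scalar_count(length, "length", min = 1)
  if (!is.numeric(rate_multiplier) || rate_multiplier <= 0)
    stop("`rate_multiplier` must be > 0")
  if (is.null(gene_tree$edge.length) || any(gene_tree$edge.length < 0))
    stop("gene tree must have non-negative branch lengths")
  with_seed(seed, {
    rates <- if (is.null(gamma_shape)) rep(1, length)
             else stats::rgamma(length, shape = gamma_shape, rate = gamma_shape)
    rates <- rates * rate_multiplier
    tr <- ape::reorder.phylo(gene_tree, "cladewise")
    ntip <- length(tr$tip.label)
    nnode <- max(tr$edge)
    states <- matrix(NA_integer_, nnode, length)
    root <- tr$edge[1, 1]
    states[root, ] <- sample.int(4, length, replace = TRUE,
                                 prob = model$base_freq)
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      states[ch, ] <- evolve_states(states[p, ], tr$edge.length[k] * rates,
                                    model)
    }
    aln <- matrix(DNA_BASES[states[seq_len(ntip), , drop = FALSE]],
                  nrow = ntip)
    rownames(aln) <- tr$tip.label
    attr(aln, "site_rates") <- rates
    aln
  })
}

# Vectorized single-branch evolution: per-site branch lengths `t`.
evolve_states <- function(parent, t, model) {
  out <- integer(length(parent))
  E <- exp(outer(t, model$eig_values))          # n x 4
  u <- stats::runif(length(parent))
  for (p in 1:4) {
    idx <- which(parent == p)
    if (!length(idx)) next
    M <- (E[idx, , drop = FALSE] *
            matrix(model$V[p, ], length(idx), 4, byrow = TRUE)) %*% model$Vinv
    M[M < 0] <- 0
    M <- M / rowSums(M)
    cum <- t(apply(M, 1, cumsum))
    out[idx] <- 1L + rowSums(u[idx] > cum + 1e-15)
  }
  pmin(out, 4L)
}

#' Simulate a per-region variant table from alignments
#'
#' Emits one record per site per region in the style of all-sites variant
#' calling: reference allele from a designated sample or the column
#' consensus, per-sample diploid genotype (homozygous for the simulated
#' base), negative-binomial per-genotype depth, bounded-integer site
#' quality, a configurable fraction of sites flagged as indels, and
#' random genotype missingness.
#'
#' @param alignments Named list of character matrices sharing one sample
#'   set (one matrix per target region).
#' @param reference_choice `"consensus"` or the name of a sample.
#' @param depth_params `list(mean=, size=)` for the negative binomial
#'   (`size` is the dispersion parameter; smaller = more overdispersed).
#' @param quality_params `list(mean=, sd=, max=)` for rounded, clamped
#'   Gaussian site qualities (floor 0).
#' @param missing_fraction Fraction of genotypes set missing, in [0, 1).
#' @param indel_fraction Fraction of sites flagged as indels.
#' @param seed Integer seed.
#' @return A [variant_table] with attributes `regions` (BED-like 0-based
#'   half-open region table) and `reference` (named vector of region
#'   reference sequences).
#' @export
simulate_variant_table <- function(alignments,
                                   reference_choice = "consensus",
                                   depth_params = list(mean = 30, size = 10),
                                   quality_params = list(mean = 60, sd = 15,
                                                         max = 99),
                                   missing_fraction = 0,
                                   indel_fraction = 0,
                                   seed = 1) {
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    stop("`alignments` must be a named list of regions")
  samples <- rownames(alignments[[1]])
  for (a in alignments)
    if (!identical(sort(rownames(a)), sort(samples)))
      stop("alignments do not share one sample set")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must be in [0, 1)")

  with_seed(seed, {
    sites_l <- list(); gt_l <- list(); dp_l <- list(); ref_l <- character(0)
    for (rg in names(alignments)) {
      al <- toupper(alignments[[rg]])[samples, , drop = FALSE]
      w <- ncol(al)
      ref <- if (identical(reference_choice, "consensus")) {
        apply(al, 2, function(col) {
          col <- col[col %in% DNA_BASES]
          if (!length(col)) return("N")
          tb <- table(factor(col, levels = DNA_BASES))
          DNA_BASES[which.max(tb)]
        })
      } else {
        if (!reference_choice %in% samples)
          stop("reference sample not found: ", reference_choice)
        al[reference_choice, ]
      }
      gt <- matrix("./.", w, length(samples),
                   dimnames = list(NULL, samples))
      alt <- character(w)
      for (j in seq_len(w)) {
        bases <- al[, j]
        alts <- sort(setdiff(unique(bases[bases %in% DNA_BASES]), ref[j]))
        alt[j] <- paste(alts, collapse = ",")
        code <- function(b) {
          if (!(b %in% DNA_BASES)) return("./.")
          i <- if (b == ref[j]) 0L else match(b, alts)
          paste0(i, "/", i)
        }
        gt[j, ] <- vapply(bases, code, "")
      }
      if (missing_fraction > 0) {
        drop <- stats::runif(length(gt)) < missing_fraction
        gt[drop] <- "./."
      }
      dp <- matrix(stats::rnbinom(w * length(samples),
                                  mu = depth_params$mean,
                                  size = depth_params$size),
                   w, length(samples), dimnames = list(NULL, samples))
      qual <- pmin(pmax(round(stats::rnorm(w, quality_params$mean,
                                           quality_params$sd)), 0),
                   quality_params$max)
      indel <- stats::runif(w) < indel_fraction
      sites_l[[rg]] <- data.frame(region = rg, pos = seq_len(w),
                                  ref = ref, alt = alt, qual = qual,
                                  indel = indel, stringsAsFactors = FALSE)
      gt_l[[rg]] <- gt; dp_l[[rg]] <- dp
      ref_l[rg] <- paste(ref, collapse = "")
    }
    vt <- variant_table(do.call(rbind, sites_l), do.call(rbind, gt_l),
                        do.call(rbind, dp_l))
    attr(vt, "regions") <- data.frame(
      region = names(alignments), chrom = names(alignments), start = 0L,
      end = vapply(alignments, ncol, 0L), stringsAsFactors = FALSE,
      row.names = NULL)
    attr(vt, "reference") <- ref_l
    vt
  })
}

#' Simulate per-gene selection metadata
#'
#' Fixture generator for the locus-selection filters: copy-number flags,
#' chromosome assignment (with a configurable fraction relegated to
#' unplaced scaffolds), overlap with a pre-existing bait kit, synthetic
#' informativeness scores, mean bootstrap values, bait counts and lengths.
#'
#' @param n_genes Number of records.
#' @param fraction_single_copy Probability a gene is single-copy.
#' @param n_chromosomes Number of chromosomes (labels `chr1..chrN`).
#' @param fraction_on_scaffold Probability a gene sits on an unplaced
#'   scaffold instead of a chromosome.
#' @param fraction_in_other_kit Probability a gene is already covered by
#'   the existing kit.
#' @param bait_count_params `list(mean=, size=)` negative binomial for
#'   bait counts.
#' @param seed Integer seed.
#' @return Data frame with one row per gene.
#' @export
make_gene_metadata <- function(n_genes, fraction_single_copy = 0.9,
                               n_chromosomes = 16,
                               fraction_on_scaffold = 0.1,
                               fraction_in_other_kit = 0.05,
                               bait_count_params = list(mean = 9, size = 6),
                               seed = 1) {
  stopifnot_scalar_count(n_genes, "n_genes", min = 0)
  stopifnot_scalar_count(n_chromosomes, "n_chromosomes", min = 1)
  for (f in c(fraction_single_copy, fraction_on_scaffold,
              fraction_in_other_kit))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  if (n_genes == 0)
    return(data.frame(gene_id = character(0), single_copy = logical(0),
                      chromosome = character(0), in_other_kit = logical(0),
                      pi_score = numeric(0), mean_bootstrap = numeric(0),
                      bait_count = integer(0), length = integer(0)))
  with_seed(seed, {
    chrom <- ifelse(stats::runif(n_genes) < fraction_on_scaffold,
                    sprintf("scaffold%04d", sample.int(9999, n_genes,
                                                       replace = TRUE)),
                    sprintf("chr%d", sample.int(n_chromosomes, n_genes,
                                                replace = TRUE)))
    data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      single_copy = stats::runif(n_genes) < fraction_single_copy,
      chromosome = chrom,
      in_other_kit = stats::runif(n_genes) < fraction_in_other_kit,
      pi_score = stats::rlnorm(n_genes, meanlog = 0, sdlog = 1),
      mean_bootstrap = round(stats::runif(n_genes, 30, 100), 1),
      bait_count = stats::rnbinom(n_genes, mu = bait_count_params$mean,
                                  size = bait_count_params$size),
      length = sample(500:13000, n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
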