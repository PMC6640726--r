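# Synthetic-data generators: Yule species trees, multispecies-coalescent
# gene trees, sequence simulation, variant tables and gene metadata.

test_that("Yule species trees are ultrametric, binary and deterministic", {
  tr <- simulate_species_tree(8, birth_rate = 1, seed = 11)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.ultrametric(tr))
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_species_tree(8, 1, seed = 11)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_species_tree(8, 1,
                                                               seed = 12))))
  expect_error(simulate_species_tree(1), "n_species")
})

test_that("a two-species tree is a cherry with equal tip branches", {
  tr <- simulate_species_tree(2, seed = 3)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$edge.length[1], tr$edge.length[2])
})

test_that("binary-tree combinatorics: n - 3 internal branches, always", {
  for (s in 1:20) {
    tr <- ape::unroot(simulate_species_tree(50, seed = s))
    internal <- sum(tr$edge[, 2] > length(tr$tip.label))
    expect_identical(internal, 47L)
  }
})

test_that("theta -> 0 forces every gene tree onto the species tree", {
  st <- simulate_species_tree(7, seed = 5)
  gts <- simulate_gene_trees(st, NULL, n_genes = 25, theta = 1e-6, seed = 2)
  expect_length(gts, 25)
  for (g in gts)
    expect_equal(ape::dist.topo(ape::unroot(g), ape::unroot(st)), 0,
                 ignore_attr = TRUE)
})

test_that("MSC quartet law holds against the closed form and an independent sampler", {
  n <- 3000
  for (d in c(0.5, 2)) {
    st <- caterpillar_tree(d)
    gts <- simulate_gene_trees(st, NULL, n_genes = n, theta = 1,
                               seed = 17)
    match <- vapply(gts, quartet_is, TRUE, a = "A", b = "B", c = "C",
                    d = "D")
    p_theory <- 1 - (2 / 3) * exp(-d)
    se <- sqrt(p_theory * (1 - p_theory) / n)
    expect_lt(abs(mean(match) - p_theory), 3 * se)
    # independent lineage-merge sampler agrees too
    set.seed(99)
    oracle <- mean(replicate(n, caterpillar_quartet_match(d)))
    expect_lt(abs(oracle - p_theory), 3 * se)
    # the two minor topologies are exchangeable
    minor1 <- vapply(gts, quartet_is, TRUE, a = "A", b = "C", c = "B",
                     d = "D")
    minor2 <- vapply(gts, quartet_is, TRUE, a = "A", b = "D", c = "B",
                     d = "C")
    expect_lt(abs(mean(minor1) - mean(minor2)),
              4 * sqrt(2 * mean(minor1) / n + 1e-6))
  }
})

test_that("gene-tree simulation is deterministic and respects the mapping", {
  st <- simulate_species_tree(4, seed = 1)
  mapping <- data.frame(
    individual = c("i1", "i2", "i3", "i4", "i5"),
    species = c("sp01", "sp01", "sp02", "sp03", "sp04"))
  g1 <- simulate_gene_trees(st, mapping, 3, theta = 0.5, seed = 8)
  g2 <- simulate_gene_trees(st, mapping, 3, theta = 0.5, seed = 8)
  expect_identical(lapply(g1, ape::write.tree), lapply(g2, ape::write.tree))
  expect_setequal(g1[[1]]$tip.label, mapping$individual)
  expect_error(simulate_gene_trees(st, mapping[0, ], 3, 0.5, 1), "empty")
})

test_that("zero branch lengths give identical sequences", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- simulate_alignment(tr, 50, seed = 2)
  expect_equal(aln["a", ], aln["b", ])
  expect_equal(aln["a", ], aln["c", ])
})

test_that("simulated divergence matches the Jukes-Cantor expectation", {
  # path length d = 0.3831 gives expected p = (3/4)(1 - exp(-4d/3)) = 0.30
  d <- -0.75 * log(1 - 4 * 0.3 / 3)
  tr <- ape::read.tree(text = sprintf("(a:%.6f,b:%.6f);", d / 2, d / 2))
  aln <- simulate_alignment(tr, 100000, seed = 21)
  p <- mean(aln["a", ] != aln["b", ])
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / 100000))
})

test_that("simulation is stationary at the supplied base frequencies", {
  bf <- c(0.4, 0.3, 0.2, 0.1)
  m <- substitution_model("GTR", rates = c(1, 2, 1, 1, 2, 1),
                          base_freq = bf)
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  aln <- simulate_alignment(tr, 100000, model = m, seed = 33)
  for (row in c("a", "b")) {
    f <- table(factor(aln[row, ], levels = c("A", "C", "G", "T"))) / 1e5
    expect_lt(max(abs(as.numeric(f) - bf)), 4 * sqrt(0.4 * 0.6 / 1e5))
  }
})

test_that("JC-corrected distances recover true path lengths on long alignments", {
  tr <- ape::read.tree(
    text = "((a:0.15,b:0.05):0.1,(c:0.2,d:0.1):0.05,e:0.3);")
  aln <- simulate_alignment(tr, 50000, seed = 44)
  est <- as.matrix(jc_distance(aln))
  true <- ape::cophenetic.phylo(tr)[rownames(est), colnames(est)]
  rel <- abs(est - true) / pmax(true, 1e-9)
  expect_lt(max(rel[upper.tri(rel)]), 0.05)
})

test_that("gamma site-rate variation is applied and recorded", {
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  aln <- simulate_alignment(tr, 5000, gamma_shape = 0.3,
                            rate_multiplier = 2, seed = 7)
  r <- attr(aln, "site_rates")
  expect_length(r, 5000)
  expect_equal(mean(r), 2, tolerance = 0.15)
  # fast sites differ more often than slow sites
  fast <- r > stats::quantile(r, 0.8)
  slow <- r < stats::quantile(r, 0.2)
  diff <- aln["a", ] != aln["b", ]
  expect_gt(mean(diff[fast]), mean(diff[slow]))
  expect_error(simulate_alignment(tr, 100, rate_multiplier = 0), "rate")
})

test_that("variant tables are deterministic and emit stable VCF", {
  st <- simulate_species_tree(4, seed = 2)
  gts <- simulate_gene_trees(st, NULL, 2, theta = 0.1, seed = 3,
                             subst_scale = 0.05)
  alns <- list(g1 = simulate_alignment(gts[[1]], 30, seed = 4),
               g2 = simulate_alignment(gts[[2]], 40, seed = 5))
  vt <- simulate_variant_table(alns, missing_fraction = 0.1,
                               indel_fraction = 0.05, seed = 6)
  expect_s3_class(vt, "variant_table")
  expect_equal(nrow(vt$sites), 70)
  expect_equal(attr(vt, "regions")$end, c(30, 40), ignore_attr = TRUE)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(vt, f1)
  write_vcf(simulate_variant_table(alns, missing_fraction = 0.1,
                                   indel_fraction = 0.05, seed = 6), f2)
  expect_identical(readLines(f1), readLines(f2))
  # high depth, high quality, no missingness: nothing filtered
  clean <- simulate_variant_table(alns, depth_params = list(mean = 100,
                                                            size = 1e6),
                                  quality_params = list(mean = 99, sd = 0,
                                                        max = 99),
                                  seed = 1)
  kept <- filter_sites(clean)
  expect_equal(nrow(kept$sites), 70)
  # depth far below the 8x threshold: all genotypes masked, sites fail
  shallow <- simulate_variant_table(alns, depth_params = list(mean = 1,
                                                              size = 1e6),
                                    seed = 1)
  expect_equal(nrow(filter_sites(shallow)$sites), 0)
})

test_that("gene metadata generation honours fractions and determinism", {
  md <- make_gene_metadata(500, fraction_single_copy = 1,
                           fraction_on_scaffold = 0,
                           fraction_in_other_kit = 0, seed = 9)
  expect_true(all(md$single_copy))
  expect_true(all(grepl("^chr", md$chromosome)))
  expect_false(any(md$in_other_kit))
  expect_identical(md, make_gene_metadata(500, 1, 16, 0, 0, seed = 9))
  expect_equal(nrow(make_gene_metadata(0)), 0)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_species_tree(5, seed = 1))
  invisible(make_gene_metadata(10, seed = 4))
  expect_identical(.Random.seed, before)
})
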