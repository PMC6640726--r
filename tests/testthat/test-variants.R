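# Site filtering and full-sequence alignment extraction.

test_that("filters match the independent per-rule enumeration on the fixture", {
  vt <- make_enumerated_fixture()
  cfg <- filter_config()
  out <- filter_sites(vt, cfg)
  expect_equal(out$sites$pos, per_rule_oracle(vt, cfg))
  # boundary semantics: quality 21 survives (strict > 20), 20 does not;
  # depth 8 survives (inclusive), 7 is masked
  expect_true(3 %in% out$sites$pos)
  expect_false(2 %in% out$sites$pos)
  expect_false(4 %in% out$sites$pos)
  i3 <- which(out$sites$pos == 3)
  expect_equal(unname(out$gt[i3, c("s1", "s2")]), c("./.", "1/1"))
  # indel sites 5 and 10 are gone; site 6 fails post-masking missingness
  expect_false(any(c(5, 6, 10) %in% out$sites$pos))
  # per-rule audit trail
  removed <- attr(out, "removed_sites")
  expect_setequal(removed$pos, setdiff(1:10, out$sites$pos))
  expect_equal(removed$reason[removed$pos == 5], "indel")
  expect_equal(removed$reason[removed$pos == 6], "missingness")
  expect_equal(removed$reason[removed$pos == 2], "quality")
})

test_that("an empty table filters to an empty table", {
  vt <- make_enumerated_fixture()
  empty <- variant_table(vt$sites[0, ], vt$gt[0, , drop = FALSE],
                         vt$dp[0, , drop = FALSE])
  expect_equal(nrow(filter_sites(empty)$sites), 0)
})

test_that("filtering is idempotent", {
  vt <- make_enumerated_fixture()
  cfg <- filter_config()
  once <- filter_sites(vt, cfg)
  twice <- filter_sites(once, cfg)
  expect_equal(twice$sites, once$sites)
  expect_equal(twice$gt, once$gt)
})

test_that("tightening any threshold never increases surviving sites", {
  for (seed in 1:5) {
    vt <- random_variant_fixture(6, 40, seed = seed)
    base <- nrow(filter_sites(vt, filter_config())$sites)
    expect_lte(nrow(filter_sites(vt, filter_config(min_quality = 40))$sites),
               base)
    expect_lte(nrow(filter_sites(vt, filter_config(min_depth = 20))$sites),
               base)
    expect_lte(nrow(filter_sites(vt, filter_config(max_missing = 0.1))$sites),
               base)
  }
})

test_that("unsorted coordinates are rejected", {
  vt <- make_enumerated_fixture()
  bad <- vt$sites
  bad$pos <- rev(bad$pos)
  expect_error(variant_table(bad, vt$gt, vt$dp), "increasing")
})

test_that("alignment extraction reproduces the naive per-sample oracle", {
  set.seed(31)
  samples <- paste0("s", 1:4)
  width <- 200
  refseq <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                  collapse = "")
  # 12 variant records at known positions
  pos <- sort(sample(width, 12))
  ref <- strsplit(refseq, "")[[1]][pos]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), "")
  gt_pool <- c("0/0", "0/1", "1/1", "./.")
  gt <- matrix(sample(gt_pool, 12 * 4, replace = TRUE), 12, 4,
               dimnames = list(NULL, samples))
  sites <- data.frame(region = "rA", pos = pos, ref = ref, alt = alt,
                      qual = 50, indel = FALSE, stringsAsFactors = FALSE)
  vt <- variant_table(sites, gt, matrix(30L, 12, 4,
                                        dimnames = list(NULL, samples)))
  regions <- data.frame(region = "rA", chrom = "rA", start = 0L,
                        end = width)
  aln <- variants_to_alignments(vt, regions, c(rA = refseq))[["rA"]]
  expect_equal(dim(aln), c(4, width))
  # columnwise oracle
  iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  for (j in seq_len(width)) {
    k <- match(j, pos)
    for (s in samples) {
      expected <- if (is.na(k)) substr(refseq, j, j) else {
        g <- gt[k, s]
        if (g == "0/0") ref[k]
        else if (g == "1/1") alt[k]
        else if (g == "./.") "N"
        else iupac[paste(sort(c(ref[k], alt[k])), collapse = "")]
      }
      expect_identical(unname(aln[s, j]), unname(expected))
    }
  }
})

test_that("a record-free table reproduces the reference everywhere", {
  samples <- c("x", "y")
  vt <- variant_table(
    data.frame(region = character(0), pos = integer(0), ref = character(0),
               alt = character(0), qual = numeric(0), indel = logical(0)),
    matrix("", 0, 2, dimnames = list(NULL, samples)),
    matrix(0L, 0, 2, dimnames = list(NULL, samples)))
  regions <- data.frame(region = "r", chrom = "r", start = 0L, end = 6L)
  aln <- variants_to_alignments(vt, regions, c(r = "ACGTAC"))[["r"]]
  expect_equal(paste(aln["x", ], collapse = ""), "ACGTAC")
  expect_equal(paste(aln["y", ], collapse = ""), "ACGTAC")
  expect_error(variants_to_alignments(vt,
    data.frame(region = "q", chrom = "q", start = 0L, end = 3L),
    c(r = "ACGTAC")), "absent")
})

test_that("heterozygotes map to IUPAC codes, including multi-allelic sites", {
  samples <- c("h1", "h2")
  sites <- data.frame(region = "r", pos = 1:2, ref = c("A", "A"),
                      alt = c("G", "C,T"), qual = 50, indel = FALSE,
                      stringsAsFactors = FALSE)
  gt <- matrix(c("0/1", "0/0", "1/2", "2/2"), 2, 2, byrow = TRUE,
               dimnames = list(NULL, samples))
  vt <- variant_table(sites, gt, matrix(30L, 2, 2,
                                        dimnames = list(NULL, samples)))
  regions <- data.frame(region = "r", chrom = "r", start = 0L, end = 2L)
  aln <- variants_to_alignments(vt, regions, c(r = "AA"))[["r"]]
  expect_equal(unname(aln["h1", ]), c("R", "Y"))  # A/G, then C/T
  expect_equal(unname(aln["h2", ]), c("A", "T"))
})

test_that("removed sites surface as N in extracted alignments", {
  st <- simulate_species_tree(4, seed = 6)
  gts <- simulate_gene_trees(st, NULL, 1, theta = 0.2, seed = 7,
                             subst_scale = 0.05)
  alns <- list(g1 = simulate_alignment(gts[[1]], 50, seed = 8))
  vt <- simulate_variant_table(alns, quality_params = list(mean = 25,
                                                           sd = 8,
                                                           max = 99),
                               seed = 9)
  filtered <- filter_sites(vt)
  removed <- attr(filtered, "removed_sites")
  expect_gt(nrow(removed), 0)
  out <- variants_to_alignments(filtered)[["g1"]]
  for (p in removed$pos)
    expect_true(all(out[, p] == "N"))
})

test_that("summary statistics match hand-enumerated values", {
  vt <- make_enumerated_fixture()
  out <- filter_sites(vt)
  s <- variant_summary(vt, out)
  expect_equal(s$n_regions_total, 1)
  expect_equal(s$n_regions_recovered, 1)
  expect_equal(s$n_sites_after, nrow(out$sites))
  # surviving sites are 1, 3, 7, 8, 9 (per-rule oracle); site 3 has one
  # depth-masked genotype and site 8 keeps two of its original calls
  expect_equal(out$sites$pos, c(1, 3, 7, 8, 9))
  called <- out$gt != "./."
  expect_equal(s$total_bases, sum(called))
  expect_equal(s$missing_fraction, mean(!called))
  expect_equal(s$n_snps, 4)   # sites 1, 3, 8, 9 are polymorphic; 7 is not
  expect_equal(s$mean_depth, mean(out$dp[called]))
  # monomorphic, fully observed table
  clean <- variant_table(
    data.frame(region = "r", pos = 1:3, ref = "A", alt = "", qual = 50,
               indel = FALSE),
    matrix("0/0", 3, 2, dimnames = list(NULL, c("a", "b"))),
    matrix(30L, 3, 2, dimnames = list(NULL, c("a", "b"))))
  cs <- variant_summary(clean, filter_sites(clean))
  expect_equal(cs$n_snps, 0)
  expect_equal(cs$missing_fraction, 0)
})

test_that("VCF writing and reading round-trips tables", {
  st <- simulate_species_tree(4, seed = 2)
  gts <- simulate_gene_trees(st, NULL, 2, theta = 0.1, seed = 3,
                             subst_scale = 0.08)
  alns <- list(g1 = simulate_alignment(gts[[1]], 25, seed = 4),
               g2 = simulate_alignment(gts[[2]], 25, seed = 5))
  vt <- simulate_variant_table(alns, missing_fraction = 0.05,
                               indel_fraction = 0.1, seed = 6)
  f <- tempfile(fileext = ".vcf")
  write_vcf(vt, f)
  back <- read_vcf(f)
  expect_equal(back$sites$region, vt$sites$region)
  expect_equal(back$sites$pos, vt$sites$pos)
  expect_equal(back$sites$ref, vt$sites$ref)
  expect_equal(back$sites$alt, vt$sites$alt)
  expect_equal(back$sites$qual, vt$sites$qual)
  expect_equal(back$sites$indel, vt$sites$indel)
  expect_equal(unname(back$gt), unname(vt$gt))
  expect_equal(unname(back$dp), unname(vt$dp), ignore_attr = TRUE)
})

test_that("BED-like region tables round-trip", {
  regions <- data.frame(region = c("g1", "g2"), chrom = c("c1", "c2"),
                        start = c(0L, 100L), end = c(50L, 180L))
  f <- tempfile(fileext = ".bed")
  write_regions_bed(regions, f)
  back <- read_regions_bed(f)
  expect_equal(back, regions[, c("region", "chrom", "start", "end")])
})
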