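# Bait-budget arithmetic, exon tiling, the six-criterion gene filter and
# bait export.

test_that("bait budget and kit composition arithmetic", {
  expect_equal(bait_budget(20000, 2909), 17091)
  expect_equal(bait_budget(100, 100), 0)
  expect_error(bait_budget(100, 101), "exceeds")
  expect_equal(kit_target_count(4051, 133), 4184)
})

test_that("bait tiling enumerates starts with a right-aligned last bait", {
  # exon of 360 bp, 120-nt baits at 2x tiling: starts 0, 60, ..., 240
  tl <- tile_baits(data.frame(start = 0, end = 360), 120, 2)
  expect_equal(tl$count, 5)
  expect_equal(tl$intervals$start, c(0, 60, 120, 180, 240))
  expect_equal(tl$intervals$end - tl$intervals$start, rep(120, 5))
  # exon exactly one bait long
  one <- tile_baits(data.frame(start = 10, end = 130), 120, 1)
  expect_equal(one$count, 1)
  expect_equal(one$intervals$start, 10)
  # non-multiple length: last bait right-aligned at end - bait_length
  odd <- tile_baits(data.frame(start = 0, end = 400), 120, 2)
  expect_equal(odd$intervals$start, c(0, 60, 120, 180, 240, 280))
  # short exons: kept at >= half a bait, dropped below
  expect_equal(tile_baits(data.frame(start = 0, end = 70), 120, 2)$count, 1)
  expect_equal(tile_baits(data.frame(start = 0, end = 50), 120, 2)$count, 0)
  # empty exon list
  expect_equal(tile_baits(data.frame(start = numeric(0),
                                     end = numeric(0)))$count, 0)
  expect_error(tile_baits(data.frame(start = 10, end = 5)), "malformed")
  expect_error(tile_baits(data.frame(start = c(0, 50), end = c(100, 150))),
               "overlap")
})

make_selection_fixture <- function(n = 1000, seed = 42) {
  md <- make_gene_metadata(n, fraction_single_copy = 0.85,
                           fraction_on_scaffold = 0.15,
                           fraction_in_other_kit = 0.08, seed = seed)
  md$bait_count <- md$bait_count + 1L
  md
}

# Independent set-algebra oracle for the pure filter (no budget).
selection_oracle <- function(md, cfg) {
  ord_pi <- order(-md$pi_score, md$gene_id)
  pi_rank <- integer(nrow(md)); pi_rank[ord_pi] <- seq_len(nrow(md))
  ord_bs <- order(-md$mean_bootstrap, md$gene_id)
  bs_rank <- integer(nrow(md)); bs_rank[ord_bs] <- seq_len(nrow(md))
  s1 <- md$gene_id[md$single_copy]
  s2 <- md$gene_id[md$chromosome %in% cfg$chromosomes]
  s3 <- md$gene_id[!md$in_other_kit]
  s4 <- union(md$gene_id[pi_rank <= cfg$top_k],
              md$gene_id[bs_rank <= cfg$top_k])
  s5 <- md$gene_id[md$mean_bootstrap > cfg$min_mean_bootstrap]
  s6 <- md$gene_id[md$bait_count >= cfg$min_baits]
  Reduce(intersect, list(s1, s2, s3, s4, s5, s6))
}

test_that("the six-criterion filter equals the set-intersection oracle", {
  md <- make_selection_fixture()
  cfg <- selection_config(top_k = 300, bait_budget = Inf)
  res <- select_genes(md, cfg)
  expect_setequal(res$selected$gene_id, selection_oracle(md, cfg))
  # audit covers every gene exactly once
  expect_setequal(res$audit$gene_id, md$gene_id)
  expect_equal(nrow(res$audit), nrow(md))
  expect_equal(sum(res$audit$status == "selected"), nrow(res$selected))
})

test_that("boundary semantics: bootstrap 60 and 4 baits are excluded", {
  md <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    single_copy = TRUE, chromosome = "chr1", in_other_kit = FALSE,
    pi_score = c(3, 2, 1),
    mean_bootstrap = c(60, 61, 61),
    bait_count = c(10L, 4L, 5L), stringsAsFactors = FALSE)
  res <- select_genes(md, selection_config(top_k = 10))
  expect_equal(res$selected$gene_id, "g3")
  audit <- stats::setNames(res$audit$status, res$audit$gene_id)
  expect_equal(unname(audit["g1"]), "low_bootstrap")   # exactly 60: out
  expect_equal(unname(audit["g2"]), "too_few_baits")   # 4 < 5: out
})

test_that("criterion 4 is the union of the two top-k sets", {
  md <- data.frame(
    gene_id = sprintf("g%02d", 1:4),
    single_copy = TRUE, chromosome = "chr1", in_other_kit = FALSE,
    pi_score = c(10, 9, 1, 2),
    mean_bootstrap = c(61, 62, 99, 98),
    bait_count = 8L, stringsAsFactors = FALSE)
  res <- select_genes(md, selection_config(top_k = 2))
  # g01, g02 qualify by informativeness; g03, g04 by bootstrap
  expect_setequal(res$selected$gene_id, md$gene_id)
})

test_that("relaxing a threshold never removes a previously selected gene", {
  md <- make_selection_fixture(seed = 7)
  tight <- select_genes(md, selection_config(top_k = 200,
                                             min_mean_bootstrap = 70,
                                             min_baits = 8))
  loose <- select_genes(md, selection_config(top_k = 400,
                                             min_mean_bootstrap = 60,
                                             min_baits = 5))
  expect_true(all(tight$selected$gene_id %in% loose$selected$gene_id))
})

test_that("budget enforcement drops worst-ranked genes until the cap holds", {
  md <- make_selection_fixture(seed = 3)
  cfg_free <- selection_config(top_k = 400, bait_budget = Inf)
  free <- select_genes(md, cfg_free)
  budget <- floor(sum(free$selected$bait_count) * 0.6)
  capped <- select_genes(md, selection_config(top_k = 400,
                                              bait_budget = budget))
  expect_lte(capped$total_baits, budget)
  expect_true(all(capped$selected$gene_id %in% free$selected$gene_id))
  # over-budget genes are audited as such
  expect_true(any(capped$audit$status == "over_budget"))
  # removing the cap recovers the pure-filter survivor set
  expect_setequal(free$selected$gene_id,
                  select_genes(md, cfg_free)$selected$gene_id)
  # dropped genes have no better composite rank than any kept gene
  kept <- capped$selected
  dropped <- free$selected[!free$selected$gene_id %in% kept$gene_id, ]
  worst_kept <- max(pmax(kept$pi_rank, kept$bs_rank))
  expect_true(all(pmax(dropped$pi_rank, dropped$bs_rank) >=
                    max(pmax(kept$pi_rank, kept$bs_rank)) - 1))
})

test_that("missing fields are reported", {
  md <- make_selection_fixture()
  md$bait_count <- NULL
  expect_error(select_genes(md), "bait_count")
})

test_that("bait export emits one full-length sequence per bait and round-trips", {
  set.seed(12)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  exons <- data.frame(start = c(100, 700), end = c(460, 790))
  tl <- tile_baits(exons, 120, 2)
  sel <- data.frame(gene_id = "gX", chromosome = "chr1",
                    stringsAsFactors = FALSE)
  kit <- export_kit(sel, list(gX = tl$intervals), c(chr1 = chrom))
  expect_length(kit, tl$count)
  expect_true(all(nchar(kit) == 120))
  expect_equal(names(kit)[1], "gX_1")
  # full-length baits equal the reference substring
  expect_equal(unname(kit[1]), substr(chrom, 101, 220))
  # re-tiling the same exons yields identical intervals
  expect_equal(tile_baits(exons, 120, 2)$intervals, tl$intervals)
  # empty selection
  expect_length(export_kit(sel[0, ], list(), c(chr1 = chrom)), 0)
})
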