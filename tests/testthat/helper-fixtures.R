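# Shared fixtures for the filtering tests and acceptance checks.

# Hand-enumerable 6-sample x 10-site fixture. Depths and qualities are
# chosen so every rule fires at least once.
make_enumerated_fixture <- function() {
  samples <- paste0("s", 1:6)
  sites <- data.frame(
    region = "r1", pos = 1:10,
    ref = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
    alt = c("G", "", "A", "C", "T", "T", "", "A", "C", "A"),
    qual = c(50, 20, 21, 19, 60, 99, 35, 21, 80, 45),
    indel = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
              FALSE, TRUE),
    stringsAsFactors = FALSE)
  gt <- matrix("0/0", 10, 6, dimnames = list(NULL, samples))
  gt[1, ] <- c("0/0", "0/1", "1/1", "0/0", "0/0", "0/0")
  gt[3, ] <- c("1/1", "1/1", "0/0", "0/1", "0/0", "./.")
  gt[6, ] <- c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0")
  gt[8, ] <- c("./.", "./.", "0/0", "0/0", "1/1", "0/1")
  gt[9, ] <- c("1/1", "0/0", "0/0", "0/0", "0/0", "0/0")
  dp <- matrix(30L, 10, 6, dimnames = list(NULL, samples))
  dp[3, 1:2] <- c(7L, 8L)          # one masked, one kept at the boundary
  dp[6, ] <- c(2L, 3L, 4L, 5L, 6L, 7L)   # all below 8x -> all masked
  dp[8, 3] <- 0L   # with s1, s2 uncalled this puts site 8 at exactly 50%
  dp[10, 1:3] <- 3L
  variant_table(sites, gt, dp)
}

# Independent per-rule enumeration: apply each filter rule in isolation
# on the raw records and intersect the surviving site sets.
per_rule_oracle <- function(vt, cfg) {
  masked <- vt$gt
  masked[vt$dp < cfg$min_depth] <- "./."
  pass_quality <- which(vt$sites$qual > cfg$min_quality)
  pass_indel <- which(cfg$allow_indels | !vt$sites$indel)
  pass_missing <- which(rowMeans(masked == "./.") <= cfg$max_missing)
  sort(intersect(intersect(pass_quality, pass_indel), pass_missing))
}

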