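# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes: each code -> the set of bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Reverse lookup: unordered base pair -> ambiguity code.
iupac_code <- function(b1, b2) {
  pair <- paste(sort(c(b1, b2)), collapse = "")
  code <- c(AA = "A", CC = "C", GG = "G", TT = "T",
            AG = "R", CT = "Y", CG = "S", AT = "W",
            GT = "K", AC = "M")[pair]
  if (is.na(code)) stop("not a base pair: ", b1, "/", b2)
  unname(code)
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards, so generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Stable per-stream seed derivation from (master seed, stream index).
# Linear congruential mixing mod 2^31 - 1; all intermediates < 2^53 so the
# arithmetic is exact in doubles.
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  y <- (abs(as.double(index)) %% m)
  h <- (x * 48271 + y + 1) %% m
  h <- (h * 16807 + 12345) %% m
  as.integer(h)
}

# Canonical bipartitions of an unrooted tree: for each internal edge, the
# tip-label set on the side not containing the alphabetically first label,
# serialized as a sorted, "|"-collapsed string.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  anchor <- sort(tree$tip.label)[1]
  desc <- descendant_tips(tree)
  internal <- which(tree$edge[, 2] > n)
  out <- character(0)
  for (e in internal) {
    side <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# List: node id -> integer vector of descendant tip indices (tips map to
# themselves). Works on rooted or unrooted phylo objects.
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Pairwise topological (unit-branch-length) distances between tips.
topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- stats::cophenetic(t2)
  d[tree$tip.label, tree$tip.label]
}

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop("`", name, "` must be a single integer >= ", min)
}
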