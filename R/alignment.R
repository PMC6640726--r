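# Alignments are character matrices (rows = samples, columns = sites),
# upper-case, over A/C/G/T, IUPAC ambiguity codes, 'N' and '-'.

#' Read a FASTA alignment
#'
#' @param path Path to a FASTA file of equal-length sequences.
#' @return Character matrix with one row per sequence.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1)
    stop("sequences in ", path, " are not equal-length")
  m <- toupper(as.character(as.matrix(seqs)))
  rownames(m) <- names(seqs)
  m
}

#' Write a FASTA alignment
#'
#' @param alignment Character matrix (rows = samples).
#' @param path Output path.
#' @export
write_fasta_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in rownames(alignment)) {
    writeLines(paste0(">", s), con)
    writeLines(paste(alignment[s, ], collapse = ""), con)
  }
  invisible(path)
}

check_alignment <- function(alignment) {
  if (!is.matrix(alignment) || !is.character(alignment))
    stop("alignment must be a character matrix")
  if (is.null(rownames(alignment)))
    stop("alignment must have sample names as rownames")
  invisible(alignment)
}

# Encode tips as 4 x n_pattern partial-likelihood matrices after collapsing
# identical columns. Gaps, N and ambiguity codes contribute partial
# likelihood 1 for each compatible state. Returns list(tips=, weights=,
# patterns= site -> pattern index).
encode_alignment <- function(alignment) {
  check_alignment(alignment)
  al <- toupper(alignment)
  key <- apply(al, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  pat_of_site <- match(key, key[u])
  weights <- tabulate(pat_of_site, nbins = sum(u))
  cols <- which(u)
  codes <- names(IUPAC_SETS)
  lut <- sapply(IUPAC_SETS, function(b) as.numeric(DNA_BASES %in% b))
  lut <- cbind(lut, `-` = rep(1, 4), `?` = rep(1, 4))
  tips <- lapply(rownames(al), function(s) {
    ch <- al[s, cols, drop = TRUE]
    bad <- !(ch %in% colnames(lut))
    if (any(bad)) stop("unknown residue '", ch[bad][1], "' in sample ", s)
    matrix(lut[, ch], nrow = 4)
  })
  names(tips) <- rownames(al)
  list(tips = tips, weights = weights, pattern_of_site = pat_of_site,
       n_sites = ncol(al))
}
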