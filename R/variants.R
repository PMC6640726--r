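# Variant tables, site filtering and full-sequence alignment extraction.

#' Variant table constructor
#'
#' A per-site, per-sample genotype container for all-sites variant calls.
#'
#' @param sites Data frame with columns `region`, `pos` (1-based within
#'   region chromosome), `ref`, `alt` (comma-separated, possibly empty),
#'   `qual`, `indel` (logical). Coordinates must be strictly increasing
#'   within a region.
#' @param gt Character matrix (sites x samples) of diploid genotypes
#'   (`"0/0"`, `"0/1"`, ... , `"./."` for missing).
#' @param dp Integer matrix (sites x samples) of per-genotype depths.
#' @return Object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp) {
  need <- c("region", "pos", "ref", "alt", "qual", "indel")
  if (!all(need %in% names(sites)))
    stop("`sites` needs columns: ", paste(need, collapse = ", "))
  if (nrow(sites) != nrow(gt) || nrow(sites) != nrow(dp))
    stop("sites, gt and dp must have one row per site")
  if (any(dp < 0)) stop("depths must be >= 0")
  for (rg in unique(sites$region)) {
    p <- sites$pos[sites$region == rg]
    if (any(diff(p) <= 0))
      stop("coordinates must be strictly increasing within region ", rg)
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites, %d regions, %d samples\n",
              nrow(x$sites), length(unique(x$sites$region)), ncol(x$gt)))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), ncol(x$gt))

#' Site filter configuration
#'
#' Defaults are the standard capture-data filters: site quality strictly
#' greater than 20, no indel sites, per-sample depth of at least 8x, and
#' at most 50% missing genotypes per site.
#'
#' @param min_quality Sites with quality <= this are removed (strict).
#' @param allow_indels Keep indel-flagged sites?
#' @param min_depth Genotypes with depth below this are set missing
#'   (inclusive: depth == `min_depth` survives).
#' @param max_missing Maximum tolerated fraction of missing genotypes per
#'   site, computed after depth masking.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_quality = 20, allow_indels = FALSE,
                          min_depth = 8, max_missing = 0.5) {
  if (min_quality < 0 || min_depth < 0) stop("thresholds must be >= 0")
  if (max_missing < 0 || max_missing > 1)
    stop("`max_missing` must be in [0, 1]")
  structure(list(min_quality = min_quality, allow_indels = allow_indels,
                 min_depth = min_depth, max_missing = max_missing),
            class = "filter_config")
}

#' Apply site filters to a variant table
#'
#' Filtering proceeds in four steps: (a) genotypes with depth below
#' `min_depth` are set missing; (b) sites with quality <= `min_quality`
#' are removed; (c) indel sites are removed unless allowed; (d) sites
#' whose post-masking missing-genotype fraction exceeds `max_missing` are
#' removed. Surviving records are otherwise unchanged and keep their
#' order. The removed sites are recorded in attribute `removed_sites`
#' (columns `region`, `pos`, `reason`) so that downstream alignment
#' extraction can mark them as `N`.
#'
#' @param table A [variant_table].
#' @param config A [filter_config()].
#' @return Filtered `variant_table`.
#' @export
filter_sites <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "variant_table"),
            inherits(config, "filter_config"))
  gt <- table$gt
  gt[table$dp < config$min_depth] <- "./."
  miss_frac <- rowMeans(gt == "./.")
  reason <- rep(NA_character_, nrow(table$sites))
  reason[miss_frac > config$max_missing] <- "missingness"
  if (!config$allow_indels) reason[table$sites$indel] <- "indel"
  reason[table$sites$qual <= config$min_quality] <- "quality"
  keep <- is.na(reason)
  removed <- data.frame(region = table$sites$region[!keep],
                        pos = table$sites$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  prior <- attr(table, "removed_sites")
  if (!is.null(prior)) removed <- rbind(prior, removed)
  out <- variant_table(table$sites[keep, , drop = FALSE],
                       gt[keep, , drop = FALSE],
                       table$dp[keep, , drop = FALSE])
  attr(out, "removed_sites") <- removed
  attr(out, "regions") <- attr(table, "regions")
  attr(out, "reference") <- attr(table, "reference")
  out
}

genotype_to_base <- function(gt, ref, alts) {
  if (gt %in% c("./.", ".", ".|.")) return("N")
  al <- as.integer(strsplit(gt, "[/|]")[[1]])
  if (length(al) != 2 || any(is.na(al))) return("N")
  alleles <- c(ref, alts)
  b1 <- alleles[al[1] + 1]; b2 <- alleles[al[2] + 1]
  if (is.na(b1) || is.na(b2)) return("N")
  if (b1 == b2) b1 else iupac_code(b1, b2)
}

#' Extract full-sequence per-region alignments from a variant table
#'
#' Reconstructs, for every target region, one equal-width alignment
#' spanning the full region: the reference base where a site is absent or
#' homozygous reference, the alternate base for homozygous alternate
#' calls, the IUPAC ambiguity code for heterozygotes, and `N` for missing
#' genotypes and for sites removed by filtering.
#'
#' @param table A (typically filtered) [variant_table].
#' @param regions BED-like data frame (`region`, `chrom`, `start`, `end`;
#'   0-based half-open). Defaults to the table's `regions` attribute.
#' @param reference Named character vector of chromosome sequences.
#'   Defaults to the table's `reference` attribute.
#' @return Named list of character matrices, one per region.
#' @export
variants_to_alignments <- function(table, regions = attr(table, "regions"),
                                   reference = attr(table, "reference")) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(regions) || is.null(reference))
    stop("`regions` and `reference` are required")
  samples <- colnames(table$gt)
  removed <- attr(table, "removed_sites")
  out <- list()
  for (k in seq_len(nrow(regions))) {
    rg <- regions$region[k]; chrom <- regions$chrom[k]
    if (!chrom %in% names(reference))
      stop("region ", rg, " absent from reference")
    start <- regions$start[k]; end <- regions$end[k]
    refseq <- strsplit(toupper(reference[[chrom]]), "")[[1]]
    if (end > length(refseq))
      stop("region ", rg, " extends past reference ", chrom)
    cols <- refseq[(start + 1):end]
    aln <- matrix(rep(cols, each = length(samples)), nrow = length(samples),
                  dimnames = list(samples, NULL))
    rows <- which(table$sites$region == rg &
                    table$sites$pos > start & table$sites$pos <= end)
    for (i in rows) {
      j <- table$sites$pos[i] - start
      alts <- strsplit(table$sites$alt[i], ",")[[1]]
      aln[, j] <- vapply(table$gt[i, ], genotype_to_base, "",
                         ref = table$sites$ref[i], alts = alts)
    }
    if (!is.null(removed)) {
      gone <- removed$pos[removed$region == rg]
      gone <- gone[gone > start & gone <= end]
      if (length(gone)) aln[, gone - start] <- "N"
    }
    out[[rg]] <- aln
  }
  out
}

#' Summary statistics for a filtering run
#'
#' Reports the number of regions recovered (regions retaining at least
#' one surviving site), total aligned bases (non-missing called bases
#' over surviving sites and samples), the SNP count (polymorphic
#' surviving sites), the mean per-genotype depth over surviving
#' non-missing genotypes, and the overall missing-genotype fraction.
#'
#' @param table_before Variant table before filtering.
#' @param table_after The corresponding [filter_sites()] output.
#' @param alignments Optional [variants_to_alignments()] output for the
#'   filtered table; adds `total_alignment_columns`.
#' @return A one-row data frame.
#' @export
variant_summary <- function(table_before, table_after, alignments = NULL) {
  gt <- table_after$gt
  dp <- table_after$dp
  called <- gt != "./."
  polymorphic <- vapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, called[i, ]]
    length(unique(g)) > 1 || any(g != "0/0")
  }, TRUE)
  data.frame(
    n_regions_total = length(unique(table_before$sites$region)),
    n_regions_recovered = length(unique(table_after$sites$region)),
    n_sites_before = nrow(table_before$sites),
    n_sites_after = nrow(table_after$sites),
    total_bases = sum(called),
    n_snps = sum(polymorphic),
    mean_depth = if (any(called)) mean(dp[called]) else NA_real_,
    missing_fraction = if (length(gt)) mean(!called) else 0,
    total_alignment_columns = if (is.null(alignments)) NA_integer_
      else sum(vapply(alignments, ncol, 0L)))
}

#' Write a variant table as VCF 4.2
#'
#' Emits QUAL, an `INDEL` INFO flag, and per-genotype `GT:DP` fields.
#'
#' @param table A [variant_table].
#' @param path Output path.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phylocap",
    "##INFO=<ID=INDEL,Number=0,Type=Flag,Description=\"Indel site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(table$gt)), collapse = "\t")), con)
  alt <- ifelse(table$sites$alt == "", ".", table$sites$alt)
  info <- ifelse(table$sites$indel, "INDEL", ".")
  gtdp <- matrix(paste(table$gt, table$dp, sep = ":"),
                 nrow = nrow(table$gt))
  lines <- paste(table$sites$region, table$sites$pos, ".",
                 table$sites$ref, alt, table$sites$qual, ".", info,
                 "GT:DP", apply(gtdp, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses `vcfR` for parsing; keeps `GT` and `DP` per genotype and flags
#' indels from the `INDEL` INFO flag or from allele lengths.
#'
#' @param path Path to a VCF (4.x) file.
#' @return A [variant_table].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gt[is.na(gt)] <- "./."
  gt <- gsub("\\|", "/", gt)
  dp[is.na(dp)] <- 0
  alt <- ifelse(is.na(fix$ALT) | fix$ALT == ".", "", fix$ALT)
  indel <- grepl("(^|;)INDEL(;|$|=)", ifelse(is.na(fix$INFO), "", fix$INFO)) |
    nchar(fix$REF) > 1 |
    vapply(strsplit(alt, ","), function(a) any(nchar(a) > 1), TRUE)
  sites <- data.frame(region = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = alt,
                      qual = as.numeric(fix$QUAL), indel = indel,
                      stringsAsFactors = FALSE)
  rownames(gt) <- NULL
  rownames(dp) <- NULL
  variant_table(sites, gt, dp)
}

#' Read a BED-like region table
#'
#' Tab-separated columns `chrom`, `start`, `end`, optional `name`
#' (0-based half-open). Region ids default to `chrom:start-end`.
#'
#' @param path Path to the table (no header).
#' @return Data frame with columns `region`, `chrom`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  region <- if (ncol(b) >= 4) b[[4]]
            else paste0(b$chrom, ":", b$start, "-", b$end)
  data.frame(region = region, chrom = b$chrom, start = b$start,
             end = b$end, stringsAsFactors = FALSE)
}

#' Write a BED-like region table
#' @param regions Data frame with `region`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "region")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
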