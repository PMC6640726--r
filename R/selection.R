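# Locus selection under a bait budget: kit arithmetic, exon bait tiling,
# the six-criterion filter with a per-gene audit, and bait export.

#' Bait budget left after accounting for an existing kit
#'
#' @param total_capacity Total bait capacity of the combined kit.
#' @param existing_kit_size Baits already committed to the existing kit.
#' @return `total_capacity - existing_kit_size`.
#' @examples
#' bait_budget(20000, 2909)  # 17091
#' @export
bait_budget <- function(total_capacity, existing_kit_size) {
  if (existing_kit_size > total_capacity)
    stop("existing kit exceeds total capacity")
  total_capacity - existing_kit_size
}

#' Total number of target regions in a capture kit
#'
#' @param n_gene_regions Number of genic target regions.
#' @param n_neutral_regions Number of non-genic (neutral) regions.
#' @return Their sum.
#' @examples
#' kit_target_count(4051, 133)  # 4184
#' @export
kit_target_count <- function(n_gene_regions, n_neutral_regions) {
  stopifnot_scalar_count(n_gene_regions, "n_gene_regions")
  stopifnot_scalar_count(n_neutral_regions, "n_neutral_regions")
  n_gene_regions + n_neutral_regions
}

#' Tile baits across exon intervals
#'
#' Baits of `bait_length` nt are placed per exon at step
#' `bait_length / tiling_factor` (integer step, >= 1), with the last bait
#' right-aligned to the exon end. Exons shorter than a bait get one bait
#' (the exon itself) iff the exon is at least `min_exon_fraction` of a
#' bait long, else none.
#'
#' @param exon_intervals Data frame or 2-column matrix of 0-based
#'   half-open `(start, end)` intervals; must be non-overlapping, sorted.
#' @param bait_length Bait length in nt (default 120).
#' @param tiling_factor Tiling density (default 2 = 2x tiling).
#' @param min_exon_fraction Minimum exon length, as a fraction of
#'   `bait_length`, for a short exon to receive a bait.
#' @return List: `count`, `intervals` (data frame `start`, `end`,
#'   `exon`).
#' @export
tile_baits <- function(exon_intervals, bait_length = 120,
                       tiling_factor = 2, min_exon_fraction = 0.5) {
  stopifnot_scalar_count(bait_length, "bait_length", min = 1)
  if (tiling_factor < 1) stop("`tiling_factor` must be >= 1")
  ex <- as.data.frame(exon_intervals)
  if (ncol(ex) < 2) {
    if (nrow(ex) == 0)
      return(list(count = 0L,
                  intervals = data.frame(start = integer(0),
                                         end = integer(0),
                                         exon = integer(0))))
    stop("exon intervals need start and end columns")
  }
  names(ex)[1:2] <- c("start", "end")
  if (nrow(ex) == 0)
    return(list(count = 0L,
                intervals = data.frame(start = integer(0), end = integer(0),
                                       exon = integer(0))))
  if (any(ex$end <= ex$start)) stop("malformed exon interval")
  o <- order(ex$start)
  if (any(ex$end[o][-nrow(ex)] > ex$start[o][-1]))
    stop("exon intervals overlap")
  step <- max(1L, as.integer(bait_length / tiling_factor))
  out <- list()
  for (i in seq_len(nrow(ex))) {
    len <- ex$end[i] - ex$start[i]
    if (len < bait_length) {
      if (len >= min_exon_fraction * bait_length)
        out[[length(out) + 1]] <- data.frame(start = ex$start[i],
                                             end = ex$end[i], exon = i)
      next
    }
    starts <- seq(0L, len - bait_length, by = step)
    if (starts[length(starts)] != len - bait_length)
      starts <- c(starts, len - bait_length)
    out[[length(out) + 1]] <- data.frame(start = ex$start[i] + starts,
                                         end = ex$start[i] + starts +
                                           bait_length, exon = i)
  }
  intervals <- if (length(out)) do.call(rbind, out)
               else data.frame(start = integer(0), end = integer(0),
                               exon = integer(0))
  list(count = nrow(intervals), intervals = intervals)
}

#' Selection configuration
#'
#' Defaults follow the standard capture-kit reduction criteria: keep
#' single-copy genes on the configured chromosomes, not already covered
#' by the existing kit, in the top 500 by informativeness and/or by mean
#' bootstrap, with mean bootstrap strictly above 60 and at least 5 baits;
#' then enforce the bait budget.
#'
#' @param top_k Rank cutoff for criterion 4.
#' @param min_mean_bootstrap Strict lower bound for criterion 5.
#' @param min_baits Minimum bait count (inclusive) for criterion 6.
#' @param bait_budget Maximum total bait count, or `Inf` for no cap.
#' @param chromosomes Allowed chromosome labels.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(top_k = 500, min_mean_bootstrap = 60,
                             min_baits = 5, bait_budget = Inf,
                             chromosomes = paste0("chr", 1:16)) {
  stopifnot_scalar_count(top_k, "top_k", min = 1)
  stopifnot_scalar_count(min_baits, "min_baits", min = 1)
  structure(list(top_k = top_k, min_mean_bootstrap = min_mean_bootstrap,
                 min_baits = min_baits, bait_budget = bait_budget,
                 chromosomes = chromosomes),
            class = "selection_config")
}

#' Select genes by the six capture-kit criteria and a bait budget
#'
#' Survivors satisfy, in order: (1) single-copy; (2) located on an
#' allowed chromosome; (3) not in the existing kit; (4) in the top
#' `top_k` by informativeness score and/or by mean bootstrap; (5) mean
#' bootstrap strictly above `min_mean_bootstrap`; (6) at least
#' `min_baits` baits. If the survivors' total bait count exceeds the
#' budget, genes are dropped in order of worst composite rank (the max of
#' the two ranks, ties by informativeness rank, then gene id) until it
#' fits. Every input gene is audited with the first criterion that
#' removed it.
#'
#' @param records Data frame with columns `gene_id`, `single_copy`,
#'   `chromosome`, `in_other_kit`, `pi_score` (or `pi_rank`),
#'   `mean_bootstrap`, `bait_count`.
#' @param config A [selection_config()].
#' @return List of class `gene_selection`: `selected` (surviving
#'   records), `audit` (`gene_id`, `status`), `total_baits`.
#' @export
select_genes <- function(records, config = selection_config()) {
  need <- c("gene_id", "single_copy", "chromosome", "in_other_kit",
            "mean_bootstrap", "bait_count")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records missing fields: ", paste(missing, collapse = ", "))
  if (!"pi_rank" %in% names(records)) {
    if (!"pi_score" %in% names(records))
      stop("records missing fields: pi_score or pi_rank")
    records$pi_rank <- rank_desc(records$pi_score, records$gene_id)
  }
  records$bs_rank <- rank_desc(records$mean_bootstrap, records$gene_id)

  status <- rep("selected", nrow(records))
  fail <- function(cond, label) {
    hit <- cond & status == "selected"
    status[hit] <<- label
  }
  fail(!records$single_copy, "not_single_copy")
  fail(!(records$chromosome %in% config$chromosomes), "off_chromosome")
  fail(records$in_other_kit, "in_other_kit")
  fail(!(records$pi_rank <= config$top_k |
           records$bs_rank <= config$top_k), "not_top_k")
  fail(records$mean_bootstrap <= config$min_mean_bootstrap, "low_bootstrap")
  fail(records$bait_count < config$min_baits, "too_few_baits")

  sel <- records[status == "selected", , drop = FALSE]
  if (is.finite(config$bait_budget) &&
      sum(sel$bait_count) > config$bait_budget) {
    composite <- pmax(sel$pi_rank, sel$bs_rank)
    # drop worst composite rank first; ties by informativeness rank,
    # then (reverse-alphabetical) gene id so the order is total
    drop_order <- order(composite, sel$pi_rank, sel$gene_id,
                        decreasing = TRUE)
    keep <- rep(TRUE, nrow(sel))
    total <- sum(sel$bait_count)
    for (i in drop_order) {
      if (total <= config$bait_budget) break
      keep[i] <- FALSE
      total <- total - sel$bait_count[i]
    }
    status[records$gene_id %in% sel$gene_id[!keep]] <- "over_budget"
    sel <- sel[keep, , drop = FALSE]
  }
  structure(list(selected = sel,
                 audit = data.frame(gene_id = records$gene_id,
                                    status = status,
                                    stringsAsFactors = FALSE),
                 total_baits = sum(sel$bait_count)),
            class = "gene_selection")
}

# Dense rank by decreasing value, ties broken by id (stable, 1 = best).
rank_desc <- function(value, id) {
  ord <- order(-value, id)
  r <- integer(length(value))
  r[ord] <- seq_along(value)
  r
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %d of %d genes kept, %d baits total\n",
              nrow(x$selected), nrow(x$audit), x$total_baits))
  tb <- table(x$audit$status)
  for (s in names(tb)) cat(sprintf("  %-16s %d\n", s, tb[[s]]))
  invisible(x)
}

#' Export bait sequences for selected genes
#'
#' One sequence per bait, id `geneid_baitindex`. Bait intervals shorter
#' than `bait_length` (short exons) are extended symmetrically into the
#' flanking reference, clipped at the chromosome ends, so every exported
#' bait has the full bait length where possible.
#'
#' @param selection A [select_genes()] result (or a data frame with
#'   `gene_id` and `chromosome`).
#' @param bait_intervals Named list (by gene id) of [tile_baits()]
#'   interval tables (0-based half-open, chromosome coordinates).
#' @param reference Named character vector of chromosome sequences.
#' @param bait_length Target bait length.
#' @return Named character vector of bait sequences.
#' @export
export_kit <- function(selection, bait_intervals, reference,
                       bait_length = 120) {
  sel <- if (inherits(selection, "gene_selection")) selection$selected
         else selection
  out <- character(0)
  for (i in seq_len(nrow(sel))) {
    gid <- sel$gene_id[i]
    iv <- bait_intervals[[gid]]
    if (is.null(iv) || nrow(iv) == 0) next
    chrom <- sel$chromosome[i]
    if (!chrom %in% names(reference))
      stop("chromosome ", chrom, " absent from reference")
    seqlen <- nchar(reference[[chrom]])
    for (b in seq_len(nrow(iv))) {
      s <- iv$start[b]; e <- iv$end[b]
      if (e - s < bait_length) {
        pad <- bait_length - (e - s)
        s <- max(0, s - floor(pad / 2))
        e <- min(seqlen, s + bait_length)
        s <- max(0, e - bait_length)
      }
      if (s < 0 || e > seqlen)
        stop("bait interval outside reference for ", gid)
      out[sprintf("%s_%d", gid, b)] <-
        substr(reference[[chrom]], s + 1, e)
    }
  }
  out
}
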