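# Preprocessing: read/validate tables, depth-filter, rarefy, convert to
# relative abundance, aggregate by rank, and derive the reliability cutoff
# from technical replicates. The pipeline order is fixed:
# depth filter -> rarefy -> relative -> aggregate -> cutoff.

#' Read and reconcile a count table and its sample metadata
#'
#' @param counts_path Path to a TSV (or `.biom`) count table, see
#'   [read_count_table()].
#' @param metadata_path Path to a TSV metadata table, see
#'   [read_metadata()].
#' @return List with `table` (a [taxon_table()]) and `metadata`, columns
#'   aligned; any count sample missing from the metadata is a hard error
#'   naming the offenders, metadata rows without counts are dropped with a
#'   warning.
#' @export
read_tables <- function(counts_path, metadata_path) {
  table <- read_count_table(counts_path)
  metadata <- read_metadata(metadata_path)
  missing <- setdiff(colnames(table$counts), metadata$sample_id)
  if (length(missing)) {
    stop("samples missing metadata: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, colnames(table$counts))
  if (length(extra)) {
    warning(length(extra), " metadata rows without counts dropped")
    metadata <- metadata[!metadata$sample_id %in% extra, ]
  }
  metadata <- metadata[match(colnames(table$counts), metadata$sample_id), ]
  rownames(metadata) <- NULL
  list(table = table, metadata = metadata)
}

#' Exclude samples below a minimum read depth
#'
#' Samples with strictly fewer than `min_reads` total reads are removed,
#' matching the convention of discarding samples with fewer than 10,000
#' reads before rarefaction.
#'
#' @param table A [taxon_table()].
#' @param min_reads Depth threshold (default 10,000).
#' @return List with `table` (retained samples) and `excluded` (character
#'   vector of removed sample ids).
#' @export
filter_low_depth <- function(table, min_reads = 10000) {
  stopifnot(inherits(table, "taxon_table"))
  totals <- sample_totals(table)
  drop <- names(totals)[totals < min_reads]
  keep <- setdiff(colnames(table$counts), drop)
  if (!length(keep)) stop("no samples survive depth filter")
  list(table = subset_samples(table, keep), excluded = drop)
}

# one multivariate hypergeometric draw: subsample `depth` reads without
# replacement from a count vector, via a chain of univariate rhyper draws
rmvhyper <- function(counts, depth) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  need <- depth
  for (i in seq_along(counts)) {
    if (need == 0L) break
    xi <- stats::rhyper(1, counts[i], remaining - counts[i], need)
    out[i] <- xi
    need <- need - xi
    remaining <- remaining - counts[i]
  }
  out
}

#' Rarefy a count table to a common depth
#'
#' Each sample is subsampled once, without replacement, from its read
#' multiset (an exact multivariate hypergeometric draw), so every retained
#' sample has exactly `depth` reads. Samples already at `depth` are
#' returned unchanged. Deterministic given `seed`.
#'
#' @param table A [taxon_table()]; every sample must have >= `depth` reads
#'   (run [filter_low_depth()] first).
#' @param depth Target depth (default 10,000).
#' @param seed Integer seed.
#' @return A [taxon_table()] with all column sums equal to `depth`.
#' @export
rarefy <- function(table, depth = 10000, seed = 1L) {
  stopifnot(inherits(table, "taxon_table"))
  totals <- sample_totals(table)
  low <- names(totals)[totals < depth]
  if (length(low)) {
    stop("samples below rarefaction depth (filter first): ",
         paste(low, collapse = ", "))
  }
  with_seed(derive_seed(seed, "rarefy"), {
    counts <- table$counts
    for (j in seq_len(ncol(counts))) {
      if (totals[j] == depth) next
      counts[, j] <- rmvhyper(counts[, j], as.integer(depth))
    }
    taxon_table(counts, table$lineage)
  })
}

#' Convert counts to relative abundance
#'
#' @param table A [taxon_table()] with positive sample totals.
#' @return A `rel_abundance` object; every sample column sums to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  totals <- sample_totals(table)
  if (any(totals <= 0)) {
    stop("zero-total samples: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  depths <- unique(totals)
  rel_abundance(sweep(table$counts, 2L, totals, "/"), table$lineage,
                depth = if (length(depths) == 1L) depths else NA_real_)
}

rank_labels <- function(lineage, rank) {
  rank <- match.arg(tolower(rank), RANKS)
  lab <- lineage[[rank]]
  if (anyNA(lab)) {
    parent_rank <- RANKS[max(match(rank, RANKS) - 1L, 1L)]
    parent <- lineage[[parent_rank]]
    parent[is.na(parent)] <- "root"
    lab[is.na(lab)] <- paste0("unclassified-", parent[is.na(lab)])
  }
  if (rank == "species") lab <- paste(lineage$genus, lab, sep = "_")
  lab
}

#' Aggregate a table to a taxonomic rank
#'
#' Counts or fractions are summed over taxa sharing the rank label, so
#' per-sample mass is preserved exactly. Unclassified levels fall into an
#' explicit `unclassified-<parent>` bucket.
#'
#' @param x A [taxon_table()] or `rel_abundance`.
#' @param rank One of `"phylum"`, `"genus"`, `"species"`.
#' @return Same class as `x`, at the requested rank.
#' @export
aggregate_rank <- function(x, rank) {
  rank <- match.arg(tolower(rank), RANKS)
  mat <- if (inherits(x, "taxon_table")) x$counts else
    if (inherits(x, "rel_abundance")) x$fractions else
      stop("x must be a taxon_table or rel_abundance")
  lab <- rank_labels(x$lineage, rank)
  agg <- rowsum(mat, lab, reorder = TRUE)
  idx <- match(rownames(agg), lab)
  lin <- x$lineage[idx, , drop = FALSE]
  ri <- match(rank, RANKS)
  if (ri < length(RANKS)) lin[, RANKS[(ri + 1L):length(RANKS)]] <- NA
  rownames(lin) <- rownames(agg)
  if (inherits(x, "taxon_table")) taxon_table(agg, lin)
  else rel_abundance(agg, lin, x$depth)
}

#' Derive the abundance-reliability cutoff from technical replicates
#'
#' For every taxon and replicate group, computes the within-group mean
#' relative abundance and coefficient of variation (CV), bins the pairs on
#' a log-spaced abundance grid, smooths the per-bin mean CV with an
#' isotonic non-increasing fit (replicate CV falls as abundance rises),
#' and returns the smallest bin abundance whose smoothed CV is at or
#' below `dispersion_threshold`.
#'
#' @param rel_table A `rel_abundance` of replicate columns.
#' @param replicate_groups Data frame `sample_id`, `replicate_group`
#'   mapping each replicate column to its group (>= 5 groups).
#' @param dispersion_threshold Maximum acceptable replicate CV
#'   (default 0.3).
#' @param n_bins Number of log-spaced abundance bins (default 20).
#' @return A `cutoff_report` list: `cutoff`, `threshold`, and `grid`
#'   (data frame `abundance`, `cv`, `cv_smooth`, `n`).
#' @export
derive_cutoff <- function(rel_table, replicate_groups,
                          dispersion_threshold = 0.3, n_bins = 20L) {
  stopifnot(inherits(rel_table, "rel_abundance"))
  groups <- split(replicate_groups$sample_id,
                  replicate_groups$replicate_group)
  if (length(groups) < 5L) stop("need at least 5 replicate groups")
  fr <- rel_table$fractions
  means <- cvs <- c()
  for (ids in groups) {
    sub <- fr[, intersect(ids, colnames(fr)), drop = FALSE]
    if (ncol(sub) < 2L) next
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    keep <- m > 0
    means <- c(means, m[keep])
    cvs <- c(cvs, (s / m)[keep])
  }
  if (!length(means)) stop("no non-zero replicate observations")
  rng <- range(means)
  if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
  edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1L))
  edges[1] <- rng[1]              # exp(log(x)) can overshoot x
  edges[n_bins + 1L] <- rng[2]
  bin <- cut(means, edges, include.lowest = TRUE, labels = FALSE)
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  cv_bin <- tapply(cvs, factor(bin, levels = seq_len(n_bins)), mean)
  n_bin <- tapply(cvs, factor(bin, levels = seq_len(n_bins)), length)
  ok <- !is.na(cv_bin)
  # isotonic non-increasing smoothing of CV against abundance
  iso <- stats::isoreg(log(centers[ok]), -cv_bin[ok])
  smooth <- rep(NA_real_, n_bins)
  smooth[ok] <- -iso$yf
  grid <- data.frame(abundance = centers, cv = as.numeric(cv_bin),
                     cv_smooth = smooth,
                     n = as.integer(ifelse(is.na(n_bin), 0L, n_bin)))
  pass <- which(!is.na(smooth) & smooth <= dispersion_threshold)
  if (!length(pass)) {
    stop("no abundance bin meets the dispersion threshold ",
         dispersion_threshold, "; consider raising it")
  }
  structure(list(cutoff = centers[min(pass)],
                 threshold = dispersion_threshold, grid = grid),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf(
    "cutoff_report: cutoff %.4g (replicate CV <= %.3g)\n",
    x$cutoff, x$threshold))
  invisible(x)
}

#' Apply the low-abundance reliability cutoff
#'
#' Retains taxa whose median relative abundance across samples is at or
#' above `cutoff`, and reports the pre-filter taxon count `m_total`, which
#' downstream FDR correction must use as its hypothesis count.
#'
#' @param rel_table A `rel_abundance`.
#' @param cutoff Fraction in \[0, 1\] (default 0.01, i.e. 1%).
#' @return List with `table` (retained taxa) and `m_total`.
#' @export
apply_cutoff <- function(rel_table, cutoff = 0.01) {
  stopifnot(inherits(rel_table, "rel_abundance"))
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  med <- apply(rel_table$fractions, 1L, stats::median)
  keep <- med >= cutoff
  list(table = rel_abundance(
         rel_table$fractions[keep, , drop = FALSE],
         rel_table$lineage[keep, , drop = FALSE], rel_table$depth),
       m_total = nrow(rel_table$fractions))
}

#' Run the fixed preprocessing chain
#'
#' Depth filter, rarefaction, conversion to relative abundance, rank
#' aggregation, and cutoff filtering, in that order, for each requested
#' rank.
#'
#' @param table A [taxon_table()].
#' @param metadata Matching sample metadata.
#' @param depth Rarefaction depth (default 10,000); samples below it are
#'   excluded first.
#' @param cutoff Median relative-abundance cutoff (default 0.01). Ignored
#'   when a `cutoff_report` is supplied via `cutoff_report`.
#' @param ranks Ranks to aggregate to.
#' @param seed Integer seed for the rarefaction draw.
#' @param cutoff_report Optional [derive_cutoff()] result; its cutoff
#'   overrides `cutoff`.
#' @return List with `rel` (full rarefied species-level `rel_abundance`),
#'   `ranks` (per rank: `table` after cutoff, `m_total`), `metadata`
#'   (excluded samples dropped), `excluded`, `depth`, `cutoff`, `seed`.
#' @export
preprocess <- function(table, metadata, depth = 10000, cutoff = 0.01,
                       ranks = c("phylum", "genus", "species"), seed = 1L,
                       cutoff_report = NULL) {
  flt <- filter_low_depth(table, depth)
  rar <- rarefy(flt$table, depth, seed)
  rel <- to_relative(rar)
  if (!is.null(cutoff_report)) cutoff <- cutoff_report$cutoff
  per_rank <- lapply(ranks, function(r) {
    apply_cutoff(aggregate_rank(rel, r), cutoff)
  })
  names(per_rank) <- ranks
  metadata <- metadata[metadata$sample_id %in% colnames(rel$fractions), ]
  rownames(metadata) <- NULL
  list(rel = rel, ranks = per_rank, metadata = metadata,
       excluded = flt$excluded, depth = depth, cutoff = cutoff,
       seed = seed)
}
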