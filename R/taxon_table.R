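# Containers: taxon_table (integer counts) and rel_abundance (fractions).
# Both are thin S3 wrappers around a taxa x samples matrix plus a lineage
# data frame with phylum / genus / species labels per row.

RANKS <- c("phylum", "genus", "species")

#' Construct a taxon-by-sample count table
#'
#' @param counts Non-negative integer matrix, taxa in rows, samples in
#'   columns. Row and column names are required and must be unique.
#' @param lineage Data frame with one row per taxon and columns `phylum`,
#'   `genus`, `species`. `NA` entries are treated as unclassified at that
#'   rank and aggregate into an explicit `unclassified-<parent>` bucket.
#' @return An object of class `taxon_table`.
#' @export
taxon_table <- function(counts, lineage) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon row names and sample column names")
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (!all(RANKS %in% names(lineage))) {
    stop("lineage needs columns: ", paste(RANKS, collapse = ", "))
  }
  if (nrow(lineage) != nrow(counts)) {
    stop("lineage rows must match count rows")
  }
  rownames(lineage) <- rownames(counts)
  structure(list(counts = counts, lineage = lineage[, RANKS]),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d taxa x %d samples (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(as.double(x$counts))))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Per-sample total read counts
#' @param table A `taxon_table`.
#' @return Named numeric vector of column sums.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  colSums(table$counts)
}

# subset columns, keeping class
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "taxon_table"))
  missing <- setdiff(sample_ids, colnames(table$counts))
  if (length(missing)) {
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  }
  taxon_table(table$counts[, sample_ids, drop = FALSE], table$lineage)
}

rel_abundance <- function(fractions, lineage, depth = NA_real_) {
  structure(list(fractions = fractions, lineage = lineage, depth = depth),
            class = "rel_abundance")
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("rel_abundance: %d taxa x %d samples (rarefaction depth %s)\n",
              nrow(x$fractions), ncol(x$fractions), format(x$depth)))
  invisible(x)
}

lineage_string <- function(lineage) {
  paste0("p__", ifelse(is.na(lineage$phylum), "", lineage$phylum),
         ";g__", ifelse(is.na(lineage$genus), "", lineage$genus),
         ";s__", ifelse(is.na(lineage$species), "", lineage$species))
}

parse_lineage <- function(s) {
  pick <- function(prefix) {
    m <- regmatches(s, regexpr(paste0(prefix, "[^;]*"), s))
    out <- rep(NA_character_, length(s))
    hit <- grepl(paste0(prefix, "[^;]+"), s)
    out[hit] <- sub(prefix, "", regmatches(
      s, regexpr(paste0(prefix, "[^;]*"), s))[hit])
    out
  }
  data.frame(phylum = pick("p__"), genus = pick("g__"),
             species = pick("s__"), stringsAsFactors = FALSE)
}

#' Write a count table as TSV
#'
#' Layout: columns `taxon_id`, `lineage` (rank-prefixed
#' `p__...;g__...;s__...` string), then one integer column per sample.
#' Provenance key-value pairs are written as leading `#` comment lines.
#'
#' @param table A `taxon_table`.
#' @param path Output file path.
#' @param provenance Named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  df <- data.frame(taxon_id = rownames(table$counts),
                   lineage = lineage_string(table$lineage),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, provenance)
  invisible(path)
}

#' Read a count table from TSV or BIOM
#'
#' TSV files must follow the [write_count_table()] layout. Files ending in
#' `.biom` are read with the biomformat package when it is installed.
#'
#' @param path Input file path.
#' @return A `taxon_table`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading .biom files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
    obs <- biomformat::observation_metadata(b)
    lin <- if (is.null(obs)) {
      data.frame(phylum = NA_character_, genus = NA_character_,
                 species = NA_character_)[rep(1L, nrow(counts)), ]
    } else {
      parse_lineage(apply(as.data.frame(obs), 1L, paste, collapse = ";"))
    }
    return(taxon_table(round(counts), lin))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("taxon_id", "lineage")
  if (!all(need %in% names(df))) {
    stop("count table must have 'taxon_id' and 'lineage' columns")
  }
  samp <- setdiff(names(df), need)
  counts <- as.matrix(df[, samp, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts))) {
    stop("non-integer or missing counts in ", path)
  }
  rownames(counts) <- df$taxon_id
  taxon_table(counts, parse_lineage(df$lineage))
}

#' Write a count table in BIOM format
#'
#' @param table A `taxon_table`.
#' @param path Output `.biom` path (JSON BIOM).
#' @return `path`, invisibly.
#' @export
write_count_table_biom <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("writing .biom files requires the biomformat package")
  }
  obs <- data.frame(taxonomy = lineage_string(table$lineage),
                    row.names = rownames(table$counts))
  b <- biomformat::make_biom(table$counts, observation_metadata = obs)
  biomformat::write_biom(b, path)
  invisible(path)
}

write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write per-sample metadata as TSV
#' @param metadata Data frame with columns `sample_id`, `subject_id`,
#'   `age_days`, `group`, `platform`, `replicate_group`.
#' @param path Output path.
#' @param provenance Optional named character vector of `#` header lines.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, provenance = NULL) {
  write_tsv_prov(metadata, path, provenance)
  invisible(path)
}

#' Read per-sample metadata from TSV
#' @param path Input path.
#' @return Data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "age_days", "group")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", "))
  }
  if (any(!md$group %in% c("case", "control"))) {
    stop("metadata group must be 'case' or 'control'")
  }
  if (any(!is.finite(md$age_days)) || any(md$age_days < 0)) {
    stop("metadata ages must be non-negative")
  }
  invisible(md)
}
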