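test_that("count table round-trips through TSV and reconciles metadata", {
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  md <- tiny_metadata()
  write_count_table(tab, file.path(dir, "counts.tsv"),
                    provenance = c(seed = "1"))
  write_metadata(md, file.path(dir, "metadata.tsv"))
  rt <- read_tables(file.path(dir, "counts.tsv"),
                    file.path(dir, "metadata.tsv"))
  expect_identical(rt$table$counts, tab$counts)
  expect_identical(rt$table$lineage, tab$lineage)
  expect_equal(rt$metadata$sample_id, md$sample_id)
  expect_equal(unname(sample_totals(rt$table)), c(10000, 10000))

  # missing metadata row is a hard error naming the sample
  write_metadata(md[1, ], file.path(dir, "metadata1.tsv"))
  expect_error(read_tables(file.path(dir, "counts.tsv"),
                           file.path(dir, "metadata1.tsv")), "s2")

  # malformed counts rejected
  expect_error(taxon_table(matrix(c(-1, 2), 1,
                                  dimnames = list("t", c("a", "b"))),
                           tab$lineage[1, ]), "non-negative")
  md_dup <- rbind(md, md[1, ])
  expect_error(validate_metadata <- read_metadata(
    {p <- file.path(dir, "dup.tsv"); write_metadata(md_dup, p); p}),
    "duplicate")
})

test_that("BIOM round-trip preserves counts", {
  skip_if_not_installed("biomformat")
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  p <- file.path(dir, "counts.biom")
  write_count_table_biom(tab, p)
  rt <- read_count_table(p)
  expect_equal(rt$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
})

test_that("depth filter uses a strict threshold", {
  counts <- matrix(c(9999L, 10000L, 50000L), 1,
                   dimnames = list("Bacteroides_uniformis",
                                   c("lo", "eq", "hi")))
  lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                    species = "uniformis")
  tab <- taxon_table(counts, lin)
  f <- filter_low_depth(tab)
  expect_equal(f$excluded, "lo")
  expect_equal(colnames(f$table$counts), c("eq", "hi"))
  f2 <- filter_low_depth(f$table)
  expect_identical(f2$table, f$table)
  expect_length(f2$excluded, 0)
  expect_error(filter_low_depth(tab, min_reads = 1e6), "no samples")
})

test_that("the default cohort carries exactly three shallow samples", {
  ch <- generate_cohort(cohort_spec(rng_seed = 17L))
  cnt <- generate_counts(ch$metadata, composition_spec(), seed = 17L)
  f <- filter_low_depth(cnt)
  expect_length(f$excluded, 3L)
})

test_that("rarefaction: identity at own depth, exact totals, mean", {
  tab <- tiny_table()  # both samples at depth 10,000
  expect_identical(rarefy(tab, 10000, seed = 1L)$counts, tab$counts)

  counts <- matrix(c(20000L, 20000L), 2, 1,
                   dimnames = list(c("Bacteroides_dorei_vulgatus",
                                     "Bacteroides_uniformis"), "s"))
  lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                    species = c("dorei_vulgatus", "uniformis"))
  big <- taxon_table(counts, lin)
  draws <- vapply(1:1000, function(s)
    rarefy(big, 10000, seed = s)$counts[1, 1], numeric(1))
  # hypergeometric: N = 40,000, K = 20,000, n = 10,000
  se_hyper <- sqrt(10000 * 0.5 * 0.5 * (40000 - 10000) / (40000 - 1))
  expect_lt(abs(mean(draws) - 5000), 3 * se_hyper / sqrt(1000))
  expect_true(all(vapply(1:20, function(s)
    sum(rarefy(big, 10000, seed = s)$counts), numeric(1)) == 10000))

  expect_equal(sum(rarefy(big, 0, seed = 1L)$counts), 0)
  expect_error(rarefy(tab, 20000), "below")
  expect_identical(rarefy(big, 10000, seed = 3L)$counts,
                   rarefy(big, 10000, seed = 3L)$counts)
})

test_that("relative abundance closes to one and handles zeros", {
  counts <- matrix(c(5000L, 5000L, 10000L, 0L), 2,
                   dimnames = list(c("Bacteroides_dorei_vulgatus",
                                     "Bacteroides_uniformis"),
                                   c("a", "b")))
  lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                    species = c("dorei_vulgatus", "uniformis"))
  rel <- to_relative(taxon_table(counts, lin))
  expect_equal(unname(rel$fractions[, "a"]), c(0.5, 0.5))
  expect_equal(unname(rel$fractions[, "b"]), c(1, 0))

  z <- counts
  z[, 2] <- 0L
  expect_error(to_relative(taxon_table(z, lin)), "zero-total")

  cnt <- small_cohort(31L)$counts
  rel2 <- to_relative(cnt)
  expect_true(all(abs(colSums(rel2$fractions) - 1) < 1e-9))
})

test_that("rank aggregation preserves mass and handles identities", {
  tab <- tiny_table()
  rel <- to_relative(tab)
  gen <- aggregate_rank(rel, "genus")
  expect_equal(unname(gen$fractions["Bacteroides", "s1"]), 0.8)
  # species-level aggregation of a species table is the identity
  sp <- aggregate_rank(rel, "species")
  expect_equal(sp$fractions[rownames(rel$fractions), ], rel$fractions)
  # mass conserved at every rank
  for (r in c("phylum", "genus", "species")) {
    expect_true(all(abs(colSums(
      aggregate_rank(rel, r)$fractions) - 1) < 1e-9))
  }
  expect_error(aggregate_rank(rel, "family"), "arg")
  # unclassified species fall into an explicit bucket
  lin2 <- tab$lineage
  lin2$species[2] <- NA
  rel2 <- to_relative(taxon_table(tab$counts, lin2))
  agg <- aggregate_rank(rel2, "species")
  expect_true("Bacteroides_unclassified-Bacteroides" %in%
                rownames(agg$fractions))
})

test_that("derive_cutoff recovers the 1% reliability threshold", {
  # replicate groups spanning a log-spaced abundance ladder, default
  # abundance-dependent noise: the CV curve crosses 0.3 near 1%
  set.seed(5)
  fracs <- exp(seq(log(2e-4), log(0.35), length.out = 24))
  n_grp <- 120L
  cols <- list()
  groups <- list()
  comp <- composition_spec()
  for (g in seq_len(n_grp)) {
    f <- fracs[(g - 1L) %% length(fracs) + 1L]
    base <- round(c(f, (1 - f) / 2, (1 - f) / 2) * 357581)
    counts <- matrix(as.integer(base), 3, 1,
                     dimnames = list(c("Bacteroides_dorei_vulgatus",
                                       "Bacteroides_uniformis",
                                       "Blautia_wexlerae"),
                                     sprintf("g%03d", g)))
    lin <- data.frame(phylum = "Bacteroidetes",
                      genus = c("Bacteroides", "Bacteroides", "Blautia"),
                      species = c("dorei_vulgatus", "uniformis",
                                  "wexlerae"))
    reps <- generate_replicates(taxon_table(counts, lin), comp, k = 3L,
                                seed = g)
    cols[[g]] <- reps$table
    groups[[g]] <- reps$groups
  }
  allc <- do.call(cbind, lapply(cols, function(t) t$counts))
  tab <- taxon_table(allc, cols[[1]]$lineage)
  rel <- to_relative(rarefy(filter_low_depth(tab)$table, 10000, seed = 1L))
  rep_groups <- do.call(rbind, groups)
  rpt <- derive_cutoff(rel, rep_groups, dispersion_threshold = 0.3)
  # within one log-grid bin of 1%
  bin_step <- exp(diff(log(range(rpt$grid$abundance))) / 19)
  expect_gt(rpt$cutoff, 0.01 / bin_step^1.5)
  expect_lt(rpt$cutoff, 0.01 * bin_step^1.5)
  # smoothed CV is non-increasing in abundance
  sm <- rpt$grid$cv_smooth[!is.na(rpt$grid$cv_smooth)]
  expect_true(all(diff(sm) <= 1e-9))
})

test_that("derive_cutoff degenerate cases", {
  # noise-free replicates: cutoff lands in the lowest abundance bin
  counts <- matrix(rep(c(100L, 4900L, 5000L), 12), 3,
                   dimnames = list(c("Bacteroides_dorei_vulgatus",
                                     "Bacteroides_uniformis",
                                     "Blautia_wexlerae"),
                                   sprintf("r%02d", 1:12)))
  lin <- data.frame(phylum = "Bacteroidetes",
                    genus = c("Bacteroides", "Bacteroides", "Blautia"),
                    species = c("dorei_vulgatus", "uniformis", "wexlerae"))
  rel <- to_relative(taxon_table(counts, lin))
  grp <- data.frame(sample_id = colnames(counts),
                    replicate_group = rep(sprintf("g%d", 1:6), each = 2))
  rpt <- derive_cutoff(rel, grp, dispersion_threshold = 0.05)
  expect_equal(rpt$cutoff, min(rpt$grid$abundance))
  expect_true(all(rpt$grid$cv[!is.na(rpt$grid$cv)] == 0))
  expect_error(derive_cutoff(rel, grp[1:4, ]), "5 replicate groups")
})

test_that("apply_cutoff retains by median and reports m_total", {
  fr <- matrix(c(0.02, 0.005, 0.4, 0.03, 0.004, 0.5, 0.025, 0.006, 0.45),
               3, 3, dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  lin <- data.frame(phylum = "P", genus = "G", species = c("a", "b", "c"))
  rel <- rel_abundance <- structure(
    list(fractions = fr, lineage = lin, depth = 10000),
    class = "rel_abundance")
  res <- apply_cutoff(rel, 0.01)
  expect_equal(rownames(res$table$fractions), c("a", "c"))
  expect_equal(res$m_total, 3L)
  res0 <- apply_cutoff(rel, 0)
  expect_equal(nrow(res0$table$fractions), 3L)
  # permutation of sample columns leaves the retained set unchanged
  rel_perm <- structure(list(fractions = fr[, c(3, 1, 2)], lineage = lin,
                             depth = 10000), class = "rel_abundance")
  expect_equal(rownames(apply_cutoff(rel_perm, 0.01)$table$fractions),
               c("a", "c"))
  expect_error(apply_cutoff(rel, 1.5), "cutoff")
})

test_that("derive_cutoff is scale-consistent across sequencing depth", {
  build <- function(depth_mult) {
    set.seed(11)
    fracs <- exp(seq(log(5e-4), log(0.3), length.out = 16))
    cols <- list(); groups <- list()
    comp <- composition_spec()
    for (g in seq_len(64L)) {
      f <- fracs[(g - 1L) %% length(fracs) + 1L]
      base <- round(c(f, 1 - f) * 50000 * depth_mult)
      counts <- matrix(as.integer(base), 2, 1,
                       dimnames = list(c("Bacteroides_dorei_vulgatus",
                                         "Bacteroides_uniformis"),
                                       sprintf("h%03d", g)))
      lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                        species = c("dorei_vulgatus", "uniformis"))
      reps <- generate_replicates(taxon_table(counts, lin), comp, k = 3L,
                                  seed = 1000L + g)
      cols[[g]] <- reps$table$counts
      groups[[g]] <- reps$groups
    }
    tab <- taxon_table(do.call(cbind, cols),
                       data.frame(phylum = "Bacteroidetes",
                                  genus = "Bacteroides",
                                  species = c("dorei_vulgatus",
                                              "uniformis")))
    derive_cutoff(to_relative(tab), do.call(rbind, groups),
                  dispersion_threshold = 0.3)
  }
  c1 <- build(1)
  c10 <- build(10)
  bin_step <- exp(diff(log(range(c1$grid$abundance))) / 19)
  expect_lt(abs(log(c1$cutoff / c10$cutoff)), 1.5 * log(bin_step))
})

test_that("preprocess runs the fixed chain and drops excluded samples", {
  sc <- small_cohort(41L)
  # inject one shallow sample
  cnt <- sc$counts
  cnt$counts[, 1] <- as.integer(round(cnt$counts[, 1] * 500 /
                                        sum(cnt$counts[, 1])))
  tab <- taxon_table(cnt$counts, cnt$lineage)
  prep <- preprocess(tab, sc$metadata, seed = 2L)
  expect_equal(prep$excluded, colnames(tab$counts)[1])
  expect_false(colnames(tab$counts)[1] %in% prep$metadata$sample_id)
  expect_true(all(abs(colSums(prep$rel$fractions) - 1) < 1e-9))
  expect_equal(prep$ranks$species$m_total, nrow(tab$counts))
  expect_true(all(apply(prep$ranks$genus$table$fractions, 1, median)
                  >= 0.01))
})
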