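test_that("cohort generation matches the study design", {
  ch <- generate_cohort(cohort_spec(rng_seed = 42L))
  md <- ch$metadata
  groups <- tapply(md$group, md$subject_id, function(g) g[1])
  expect_equal(sum(groups == "case"), 29L)
  expect_equal(sum(groups == "control"), 47L)
  # monotone schedules within the study envelope
  for (s in unique(md$subject_id)) {
    a <- md$age_days[md$subject_id == s]
    expect_true(all(diff(a) > 0))
  }
  expect_true(all(md$age_days >= 122 & md$age_days <= 803))
  # cases carry seroconversion ages after their first sample
  cov <- ch$covariates
  expect_true(all(is.na(cov$seroconversion_age_days[cov$group == "control"])))
  first <- tapply(md$age_days, md$subject_id, min)[cov$subject_id]
  cases <- cov$group == "case"
  expect_true(all(cov$seroconversion_age_days[cases] > first[cases]))
  # ~947 samples under the default design
  expect_gt(nrow(md), 750)
  expect_lt(nrow(md), 1150)
})

test_that("degenerate cohort specs behave and invalid ones are rejected", {
  ch <- generate_cohort(cohort_spec(n_cases = 1L, n_controls = 1L,
                                    dropout_earliest = 150,
                                    last_sample_age = 150,
                                    n_shallow = 0L, rng_seed = 1L))
  expect_equal(nrow(ch$metadata), 2L)
  expect_error(cohort_spec(n_cases = 0L), "n_cases")
  expect_error(cohort_spec(sampling_interval = c(0, 1)), "interval")
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(rng_seed = 5L))
  b <- generate_cohort(cohort_spec(rng_seed = 5L))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(rng_seed = 6L))
  expect_false(identical(a$metadata, c$metadata))
})

test_that("realized sampling gaps match the scheduling distribution", {
  # Monte-Carlo against the truncated-normal gap distribution implied by
  # the generator parameters (mean 36, sd 11, truncated at 14 days)
  spec <- cohort_spec(n_cases = 5000L, n_controls = 5000L,
                      n_shallow = 0L, rng_seed = 99L)
  md <- generate_cohort(spec)$metadata
  gaps <- unlist(tapply(md$age_days, md$subject_id, diff))
  # the >=14 d truncation raises the mean ~0.6 d; the follow-up boundary
  # length-biases it down ~0.9 d: realized gaps sit within ~1.5 d of the
  # 36-day design value
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 36), 3 * se + 1.5)
  expect_lt(abs(sd(gaps) - 11), 2)
})

test_that("counts follow the composition: degenerate and determinism", {
  md <- tiny_metadata()
  taxa <- default_taxa()
  taxa$weight <- c(1, rep(1e-12, nrow(taxa) - 1))
  comp <- composition_spec(taxa = taxa, overdispersion = 0,
                           subject_effect_sd = 0,
                           spike_case_level = 0.999999,
                           spike_control_level = 0.99999,
                           colonization_level = 0.999999,
                           spike_width = 1e6)
  tab <- generate_counts(md, comp, seed = 1L)
  frac <- tab$counts[SPIKE, ] / colSums(tab$counts)
  expect_true(all(frac > 0.999))

  t1 <- generate_counts(md, composition_spec(), seed = 3L)
  t2 <- generate_counts(md, composition_spec(), seed = 3L)
  expect_identical(t1, t2)
  expect_error(generate_counts(md[0, ], composition_spec()), "empty")
})

test_that("case spike abundance near the peak matches the target level", {
  n <- 500L
  md <- flat_metadata(round(runif(n, 216, 246)), rep("case", n))
  set.seed(7)
  md$age_days <- as.integer(round(runif(n, 216, 246)))
  cnt <- generate_counts(md, composition_spec(), seed = 7L)
  rel <- to_relative(rarefy(cnt, 10000, seed = 7L))
  x <- rel$fractions[SPIKE, ]
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.173), 3 * se)

  md$group <- "control"
  cnt <- generate_counts(md, composition_spec(), seed = 8L)
  rel <- to_relative(rarefy(cnt, 10000, seed = 8L))
  y <- rel$fractions[SPIKE, ]
  expect_lt(abs(mean(y) - 0.0018), 3 * sd(y) / sqrt(n) + 2e-4)
})

test_that("replicates: counts, grouping and abundance-dependent noise", {
  tab <- tiny_table()
  expect_error(generate_replicates(tab, k = 1L), "k")
  ten <- small_cohort(11L)$counts
  ids <- colnames(ten$counts)[1:10]
  reps <- generate_replicates(ten, composition_spec(), k = 2L,
                              sample_ids = ids, seed = 2L)
  expect_equal(ncol(reps$table$counts), 20L)
  expect_equal(nrow(reps$groups), 20L)
  expect_setequal(unique(reps$groups$replicate_group), ids)

  # CV at low abundance exceeds CV at high abundance (500 groups)
  n <- 500L
  counts <- matrix(0L, 2, n, dimnames = list(
    c("Bacteroides_dorei_vulgatus", "Bacteroides_uniformis"),
    sprintf("r%03d", 1:n)))
  counts[1, ] <- 10L     # 0.1% at depth 10,000
  counts[2, ] <- 9990L
  lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                    species = c("dorei_vulgatus", "uniformis"))
  src <- taxon_table(counts, lin)
  reps <- generate_replicates(src, composition_spec(), k = 2L, seed = 9L)
  fr <- reps$table$counts[1, ] / colSums(reps$table$counts)
  grp <- reps$groups$replicate_group
  cv <- function(v) sd(v) / mean(v)
  cv_rare <- unlist(tapply(fr, grp, function(v)
    if (mean(v) > 0) cv(v) else NA))
  fr_hi <- reps$table$counts[2, ] / colSums(reps$table$counts)
  cv_abund <- unlist(tapply(fr_hi, grp, cv))
  expect_gt(mean(cv_rare, na.rm = TRUE), mean(cv_abund))
})

test_that("zero-noise replicates are plain multinomial resamples", {
  comp <- composition_spec(replicate_noise_scale = 0)
  tab <- tiny_table()
  reps <- generate_replicates(tab, comp, k = 3L, seed = 4L)
  expect_equal(unname(colSums(reps$table$counts)),
               rep(unname(colSums(tab$counts)), each = 3L))
  # zero counts can never reappear in a resample
  expect_true(all(reps$table$counts[tab$counts[, 1] == 0, 1:3] == 0))
})

test_that("fine-platform split recovers the species share", {
  n <- 500L
  counts <- matrix(2000L, 2, n, dimnames = list(
    c("Bacteroides_dorei_vulgatus", "Bacteroides_uniformis"),
    sprintf("f%03d", 1:n)))
  lin <- data.frame(phylum = "Bacteroidetes", genus = "Bacteroides",
                    species = c("dorei_vulgatus", "uniformis"))
  src <- taxon_table(counts, lin)
  fine <- generate_fine_platform_subset(src, composition_spec(),
                                        n_samples = n, seed = 5L)
  sp1 <- fine$counts["Bacteroides_dorei_vulgatus_sp1", ]
  sp2 <- fine$counts["Bacteroides_dorei_vulgatus_sp2", ]
  share <- sum(sp1) / sum(sp1 + sp2)
  se <- sqrt(0.75 * 0.25 / sum(sp1 + sp2))
  expect_lt(abs(share - 0.75), 3 * se)

  # dorei_fraction = 1 leaves species 2 empty
  fine1 <- generate_fine_platform_subset(
    src, composition_spec(dorei_fraction = 1), n_samples = 10L, seed = 6L)
  expect_true(all(fine1$counts["Bacteroides_dorei_vulgatus_sp2", ] == 0))

  # zero group abundance gives zero for both species
  z <- src
  z$counts[1, 1] <- 0L
  fine0 <- generate_fine_platform_subset(taxon_table(z$counts, lin),
                                         composition_spec(),
                                         n_samples = n, seed = 7L)
  col <- colnames(z$counts)[1]
  expect_equal(unname(fine0$counts[c("Bacteroides_dorei_vulgatus_sp1",
                                     "Bacteroides_dorei_vulgatus_sp2"),
                                   col]),
               c(0L, 0L))
  expect_error(generate_fine_platform_subset(src, composition_spec(),
                                             n_samples = n + 1L),
               "exceeds")
})

test_that("qPCR generator: proportionality, errors", {
  tab <- tiny_table()
  q0 <- generate_qpcr(tab, taxon = SPIKE, noise = 0,
                      total_load = c(log(1e8), 0), seed = 1L)
  rel <- tab$counts[SPIKE, ] / colSums(tab$counts)
  ratio <- c(q0$rep1, q0$rep2, q0$rep3) / rep(rel, 3)
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-9)
  expect_true(all(q0[, c("rep1", "rep2", "rep3")] > 0))
  expect_error(generate_qpcr(tab, noise = -1), "noise")
  expect_error(generate_qpcr(tab, taxon = character(0)), "taxon")
  expect_error(generate_qpcr(tab, taxon = "nope"), "taxon")
})

test_that("per-sample compositions close to one", {
  cnt <- small_cohort(21L)$counts
  rel <- to_relative(cnt)
  expect_true(all(abs(colSums(rel$fractions) - 1) < 1e-9))
})

test_that("covariate imbalance can be injected for balance checks", {
  spec <- cohort_spec(n_cases = 200L, n_controls = 200L,
                      n_shallow = 0L, rng_seed = 3L)
  bal <- generate_cohort(spec)
  chk <- covariate_balance(bal$covariates)
  expect_true(all(chk$p > 0.001, na.rm = TRUE))
  imb <- generate_cohort(spec, covariate_imbalance = list(
    delivery_mode = c(vaginal = 0.2, cesarean = 0.8)))
  chk2 <- covariate_balance(imb$covariates)
  expect_lt(chk2$p[chk2$covariate == "delivery_mode"], 0.001)
})
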