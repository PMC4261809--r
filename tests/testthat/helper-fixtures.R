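# Shared fixture builders. Everything is generated in code; no files.

# tiny hand-built count table: 3 taxa x 2 samples
tiny_table <- function() {
  counts <- matrix(c(5000L, 3000L, 2000L,
                     1000L, 8000L, 1000L), nrow = 3,
                   dimnames = list(c("Bacteroides_dorei_vulgatus",
                                     "Bacteroides_uniformis",
                                     "Blautia_wexlerae"),
                                   c("s1", "s2")))
  taxon_table(counts,
              data.frame(phylum = c("Bacteroidetes", "Bacteroidetes",
                                    "Firmicutes"),
                         genus = c("Bacteroides", "Bacteroides",
                                   "Blautia"),
                         species = c("dorei_vulgatus", "uniformis",
                                     "wexlerae")))
}

tiny_metadata <- function() {
  data.frame(sample_id = c("s1", "s2"), subject_id = c("A", "B"),
             age_days = c(200L, 300L), group = c("case", "control"),
             platform = "coarse", replicate_group = NA_character_,
             stringsAsFactors = FALSE)
}

# reduced synthetic cohort for fast integration-style tests
small_cohort <- function(seed, comp = composition_spec(),
                         n_cases = 10L, n_controls = 12L) {
  spec <- cohort_spec(n_cases = n_cases, n_controls = n_controls,
                      n_shallow = 0L, rng_seed = seed)
  ch <- generate_cohort(spec)
  counts <- generate_counts(ch$metadata, comp, seed = seed)
  list(metadata = ch$metadata, covariates = ch$covariates,
       counts = counts, comp = comp)
}

SPIKE <- "Bacteroides_dorei_vulgatus"

# metadata scaffold with given ages/groups, one subject per sample
flat_metadata <- function(ages, groups,
                          subjects = sprintf("P%04d", seq_along(ages))) {
  data.frame(sample_id = sprintf("%s_a%d", subjects, seq_along(ages)),
             subject_id = subjects, age_days = as.integer(ages),
             group = groups, platform = "coarse",
             replicate_group = NA_character_,
             scheduled_depth = NA_integer_, stringsAsFactors = FALSE)
}

# brute-force two-sided Mann-Whitney p by full enumeration of label
# assignments (oracle; independent of the package implementation)
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mid <- nx * length(y) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2L, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# brute-force BH step-up with an inflated hypothesis count (oracle)
bh_oracle <- function(p, m_total = length(p)) {
  full <- c(p, rep(1, m_total - length(p)))
  stats::p.adjust(full, method = "BH")[seq_along(p)]
}

# brute-force AUC by all-pairs enumeration (oracle)
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cs) * length(ct))
}
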