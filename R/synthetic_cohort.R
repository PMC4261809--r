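# Synthetic longitudinal case-control cohort generator. Emulates the
# structure of a 76-infant monthly-sampled 16S cohort: 29 cases / 47
# controls, samples every ~36 days from ~5 months to 2.2 years of age,
# Dirichlet-multinomial compositions dominated by Bacteroides, a
# case-specific abundance bump on one Bacteroides species group peaking at
# ~7.6 months, technical replicates with abundance-dependent noise, a
# fine-resolution paired-platform subset splitting the group into two
# species, and qPCR absolute abundances.

#' Cohort design specification
#'
#' Defaults reproduce the shape of the emulated study: 29 cases and 47
#' controls sampled roughly every 36 days (SE 11) from about 5 months of
#' age, with per-subject follow-up attrition placed so the expected cohort
#' holds ~950 samples (12.5 per subject) of which 3 are shallow (<10,000
#' reads). Case seroconversion ages are drawn from a truncated normal with
#' mean 16.8 months.
#'
#' @param n_cases,n_controls Subject counts per group (both >= 1).
#' @param first_sample_age Length-2 numeric `(mean, sd)` in days for the
#'   age at the first sample; draws are clipped to 122-183 days
#'   (4-6 months).
#' @param last_sample_age Scalar, days; sampling schedules stop here
#'   (2.2 years).
#' @param sampling_interval Length-2 numeric `(mean, sd)` in days between
#'   consecutive collected samples; draws are truncated at >= 14 days.
#' @param dropout_earliest Earliest possible end of follow-up (days).
#'   Each subject's follow-up ends uniformly between this and
#'   `last_sample_age`; the default 331 reproduces the emulated study's
#'   ~947 samples (12.5 per subject) despite a 36-day sampling interval
#'   over a nominal 2.2-year envelope.
#' @param seroconversion_age Length-2 numeric `(mean, sd)` in months for
#'   case seroconversion age; truncated above the subject's first-sample
#'   age. The default sd back-calculates the reported standard error of
#'   the mean (2.03 months at n = 29).
#' @param n_shallow Number of samples forced below the 10,000-read depth
#'   threshold, emulating the study's 3 discarded samples.
#' @param shallow_depth_range Length-2 integer range for shallow depths.
#' @param rng_seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 29L, n_controls = 47L,
                        first_sample_age = c(150, 15),
                        last_sample_age = 803,
                        sampling_interval = c(36, 11),
                        dropout_earliest = 331,
                        seroconversion_age = c(16.8, 10.9),
                        n_shallow = 3L,
                        shallow_depth_range = c(1000L, 9999L),
                        rng_seed = 1L) {
  if (n_cases < 1 || n_controls < 1) {
    stop("n_cases and n_controls must both be >= 1")
  }
  if (sampling_interval[1] <= 0) stop("sampling interval mean must be > 0")
  if (dropout_earliest > last_sample_age) {
    stop("dropout_earliest must not exceed last_sample_age")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 first_sample_age = first_sample_age,
                 last_sample_age = last_sample_age,
                 sampling_interval = sampling_interval,
                 dropout_earliest = dropout_earliest,
                 seroconversion_age = seroconversion_age,
                 n_shallow = as.integer(n_shallow),
                 shallow_depth_range = as.integer(shallow_depth_range),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Default synthetic taxon list
#'
#' Twenty gut species across five phyla with baseline concentration
#' weights shaped like an infant gut: the Bacteroides genus holds ~35% of
#' the community, followed by Ruminococcus, Faecalibacterium, Blautia,
#' Bifidobacterium, Veillonella and Coprococcus, with a long tail of rare
#' species. The `Bacteroides_dorei_vulgatus` row is the spike taxon.
#'
#' @return Data frame with columns `taxon_id`, `phylum`, `genus`,
#'   `species`, `weight`.
#' @export
default_taxa <- function() {
  tx <- rbind(
    c("Bacteroidetes", "Bacteroides", "dorei_vulgatus", 0.002),
    c("Bacteroidetes", "Bacteroides", "uniformis", 0.13),
    c("Bacteroidetes", "Bacteroides", "fragilis", 0.08),
    c("Bacteroidetes", "Bacteroides", "ovatus", 0.06),
    c("Bacteroidetes", "Bacteroides", "thetaiotaomicron", 0.05),
    c("Bacteroidetes", "Prevotella", "copri", 0.02),
    c("Bacteroidetes", "Parabacteroides", "distasonis", 0.03),
    c("Firmicutes", "Ruminococcus", "bromii", 0.08),
    c("Firmicutes", "Ruminococcus", "gnavus", 0.03),
    c("Firmicutes", "Faecalibacterium", "prausnitzii", 0.07),
    c("Firmicutes", "Blautia", "wexlerae", 0.05),
    c("Firmicutes", "Coprococcus", "comes", 0.03),
    c("Firmicutes", "Veillonella", "dispar", 0.03),
    c("Firmicutes", "Clostridium", "butyricum", 0.01),
    c("Firmicutes", "Lactobacillus", "rhamnosus", 0.005),
    c("Firmicutes", "Eubacterium", "rectale", 0.04),
    c("Actinobacteria", "Bifidobacterium", "longum", 0.05),
    c("Actinobacteria", "Bifidobacterium", "bifidum", 0.02),
    c("Proteobacteria", "Escherichia", "coli", 0.03),
    c("Verrucomicrobia", "Akkermansia", "muciniphila", 0.01))
  out <- data.frame(phylum = tx[, 1], genus = tx[, 2], species = tx[, 3],
                    weight = as.numeric(tx[, 4]),
                    stringsAsFactors = FALSE)
  out$taxon_id <- paste(out$genus, out$species, sep = "_")
  out$weight <- out$weight / sum(out$weight)
  out[, c("taxon_id", "phylum", "genus", "species", "weight")]
}

#' Composition specification for the synthetic generator
#'
#' Defaults encode the emulated study's printed values: a spike taxon
#' reaching 17.3% mean relative abundance in cases at a 231-day
#' (7.6-month) peak against 0.18% in controls, the fine-platform species
#' making up 75% of the merged group, and read depths log-normal around
#' 357,581 reads per sample. Both groups share a logistic colonization
#' curve that brings the species group to dominance late in infancy;
#' cases add a transient bloom centred on the peak age.
#'
#' @param taxa Data frame as from [default_taxa()].
#' @param spike_taxon Taxon id of the species group carrying the
#'   case/control divergence.
#' @param spike_peak_age Age (days) of the peak divergence (231 d = 7.6 mo).
#' @param spike_width Gaussian width (days) of the case-only bloom; 35
#'   days concentrates the case/control divergence in a window a sliding
#'   scan can localize while keeping cases elevated over roughly 5-11
#'   months of age.
#' @param spike_case_level,spike_control_level Expected spike-taxon
#'   fraction at the peak age in cases / controls (fractions in \[0,1\]).
#' @param spike_baseline Pre-colonization spike-taxon fraction shared by
#'   both groups.
#' @param colonization_level Late-infancy plateau of the spike taxon's
#'   shared colonization curve (both groups reach it; it keeps the
#'   species group abundant enough to survive the 1% median cutoff, as
#'   the emulated dominant group does).
#' @param colonization_rate Logistic rate (days) of the shared
#'   colonization curve; its midpoint is derived so controls sit at
#'   `spike_control_level` at the peak age.
#' @param dorei_fraction Expected share of the merged group belonging to
#'   the first (dominant) species on the fine platform.
#' @param overdispersion Dirichlet-multinomial overdispersion; total
#'   concentration is `1 / overdispersion`. The default 0.075 reproduces a
#'   per-sample spike-fraction standard deviation of ~0.10 at the case
#'   peak level.
#' @param subject_effect_sd SD of per-subject log-normal perturbations of
#'   taxon concentrations (a subject-level random effect; this is what
#'   makes per-subject bootstrap balancing matter).
#' @param reads_per_sample Length-2 numeric `(mean, sdlog)`: sequencing
#'   depth is log-normal with this arithmetic mean and log-sd.
#' @param replicate_noise_scale Scale of abundance-dependent technical
#'   replicate noise; the log-scale noise sd for a taxon at fraction p is
#'   `scale * sqrt(1e-4 / p)`, so the default 3 drives the replicate CV
#'   above ~0.3 below 1% relative abundance.
#' @return An object of class `composition_spec`.
#' @export
composition_spec <- function(taxa = default_taxa(),
                             spike_taxon = "Bacteroides_dorei_vulgatus",
                             spike_peak_age = 231,
                             spike_width = 35,
                             spike_case_level = 0.173,
                             spike_control_level = 0.0018,
                             spike_baseline = 0.001,
                             colonization_level = 0.20,
                             colonization_rate = 40,
                             dorei_fraction = 0.75,
                             overdispersion = 0.075,
                             subject_effect_sd = 0.5,
                             reads_per_sample = c(357581, 0.5),
                             replicate_noise_scale = 3) {
  if (any(taxa$weight <= 0)) stop("taxon concentrations must be > 0")
  if (!spike_taxon %in% taxa$taxon_id) stop("spike taxon not in taxon list")
  lv <- c(spike_case_level, spike_control_level, dorei_fraction)
  if (any(lv < 0 | lv > 1)) stop("spike levels and dorei_fraction must be in [0,1]")
  if (!(spike_baseline < spike_control_level &&
          spike_control_level < colonization_level)) {
    stop("need spike_baseline < spike_control_level < colonization_level")
  }
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  if (replicate_noise_scale < 0) stop("replicate_noise_scale must be >= 0")
  structure(list(taxa = taxa, spike_taxon = spike_taxon,
                 spike_peak_age = spike_peak_age, spike_width = spike_width,
                 spike_case_level = spike_case_level,
                 spike_control_level = spike_control_level,
                 spike_baseline = spike_baseline,
                 colonization_level = colonization_level,
                 colonization_rate = colonization_rate,
                 dorei_fraction = dorei_fraction,
                 overdispersion = overdispersion,
                 subject_effect_sd = subject_effect_sd,
                 reads_per_sample = reads_per_sample,
                 replicate_noise_scale = replicate_noise_scale),
            class = "composition_spec")
}

#' Null-mode composition: no case/control difference
#'
#' Returns `spec` with the case spike level and floor set to the control
#' level, so the generated cohort satisfies the global null hypothesis.
#'
#' @param spec A `composition_spec`.
#' @return A `composition_spec` with no injected effect.
#' @export
null_composition <- function(spec = composition_spec()) {
  spec$spike_case_level <- spec$spike_control_level
  spec
}

# Expected spike-taxon fraction at one age for one group. Both groups
# share a logistic colonization curve rising from `spike_baseline` to
# `colonization_level`; its midpoint is placed so that controls sit at
# `spike_control_level` at the peak age. Cases add a transient Gaussian
# bloom on top, scaled so their expected level at the peak age equals
# `spike_case_level` — the case-control difference therefore peaks
# exactly at `spike_peak_age`.
spike_level_at_age <- function(comp, age_days, group) {
  lo <- comp$spike_baseline
  hi <- comp$colonization_level
  mid <- comp$spike_peak_age - comp$colonization_rate *
    stats::qlogis((comp$spike_control_level - lo) / (hi - lo))
  shared <- lo + (hi - lo) *
    stats::plogis((age_days - mid) / comp$colonization_rate)
  if (group == "case") {
    shared + (comp$spike_case_level - comp$spike_control_level) *
      exp(-0.5 * ((age_days - comp$spike_peak_age) / comp$spike_width)^2)
  } else {
    shared
  }
}

#' Generate subject metadata and covariates
#'
#' Draws a monotone sampling schedule per subject (first age ~5 months,
#' gaps ~36 days, follow-up ending uniformly between `dropout_earliest`
#' and `last_sample_age`), case seroconversion ages, and per-subject
#' covariates (delivery mode, breast-feeding durations, antibiotic
#' courses) identically distributed in both groups unless an imbalance
#' is injected.
#'
#' @param spec A [cohort_spec()].
#' @param covariate_imbalance Optional named list overriding case-group
#'   covariate distributions, e.g.
#'   `list(delivery_mode = c(vaginal = 0.5, cesarean = 0.5))`; used to
#'   exercise the chi-square balance check.
#' @return List with `metadata` (one row per sample: `sample_id`,
#'   `subject_id`, `age_days`, `group`, `platform`, `replicate_group`,
#'   `scheduled_depth`) and `covariates` (one row per subject, including
#'   `seroconversion_age_days`, `NA` for controls).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            covariate_imbalance = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$rng_seed, "cohort"), {
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(spec$n_cases + spec$n_controls)),
      group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
      stringsAsFactors = FALSE)

    rows <- lapply(seq_len(nrow(subjects)), function(i) {
      age <- min(max(stats::rnorm(1, spec$first_sample_age[1],
                                  spec$first_sample_age[2]), 122), 183)
      # follow-up ends uniformly between earliest dropout and the study
      # envelope, reproducing realistic attrition
      end <- stats::runif(1, spec$dropout_earliest, spec$last_sample_age)
      ages <- c()
      while (age <= end) {
        ages <- c(ages, age)
        age <- age + max(stats::rnorm(1, spec$sampling_interval[1],
                                      spec$sampling_interval[2]), 14)
      }
      if (!length(ages)) ages <- end  # at least one sample per subject
      data.frame(subject_id = subjects$subject_id[i],
                 group = subjects$group[i],
                 age_days = as.integer(round(ages)),
                 stringsAsFactors = FALSE)
    })
    md <- do.call(rbind, rows)
    md$sample_id <- sprintf("%s_d%04d", md$subject_id, md$age_days)
    # rounding can collide two close schedule points; nudge duplicates
    while (anyDuplicated(md$sample_id)) {
      d <- duplicated(md$sample_id)
      md$age_days[d] <- md$age_days[d] + 1L
      md$sample_id <- sprintf("%s_d%04d", md$subject_id, md$age_days)
    }
    md <- md[order(md$subject_id, md$age_days), ]
    md$platform <- "coarse"
    md$replicate_group <- NA_character_
    # scheduled sequencing depth; a fixed handful fall under 10,000 reads
    md$scheduled_depth <- NA_integer_
    if (spec$n_shallow > 0 && nrow(md) >= spec$n_shallow) {
      shallow <- sample.int(nrow(md), spec$n_shallow)
      md$scheduled_depth[shallow] <- as.integer(round(stats::runif(
        spec$n_shallow, spec$shallow_depth_range[1],
        spec$shallow_depth_range[2])))
    }
    md <- md[, c("sample_id", "subject_id", "age_days", "group",
                 "platform", "replicate_group", "scheduled_depth")]
    rownames(md) <- NULL

    cov <- subjects
    first_age <- tapply(md$age_days, md$subject_id, min)[cov$subject_id]
    draw_cat <- function(n, probs) {
      sample(names(probs), n, replace = TRUE, prob = probs)
    }
    probs <- list(delivery_mode = c(vaginal = 0.84, cesarean = 0.16),
                  excl_breastfeeding = c("0-2" = 0.3, "3-4" = 0.45,
                                         "5-6" = 0.25),
                  total_breastfeeding = c("0-5" = 0.25, "6-9" = 0.4,
                                          "10+" = 0.35))
    for (nm in names(probs)) {
      p_ctrl <- probs[[nm]]
      p_case <- covariate_imbalance[[nm]] %||% p_ctrl
      cov[[nm]] <- ifelse(cov$group == "case",
                          draw_cat(nrow(cov), p_case),
                          draw_cat(nrow(cov), p_ctrl))
    }
    lam <- (covariate_imbalance[["antibiotic_courses"]] %||% 1.5)
    cov$antibiotic_courses <- ifelse(
      cov$group == "case", stats::rpois(nrow(cov), lam),
      stats::rpois(nrow(cov), 1.5))
    # case seroconversion ages: truncated normal, > first sample age
    sero <- rep(NA_real_, nrow(cov))
    for (i in which(cov$group == "case")) {
      repeat {
        x <- stats::rnorm(1, months_to_days(spec$seroconversion_age[1]),
                          months_to_days(spec$seroconversion_age[2]))
        if (x > first_age[i]) break
      }
      sero[i] <- round(x)
    }
    cov$seroconversion_age_days <- sero
    list(metadata = md, covariates = cov)
  })
}

#' Generate Dirichlet-multinomial counts for a cohort
#'
#' Each sample's expected composition starts from the taxon weights,
#' multiplied by a per-subject log-normal random effect, with the spike
#' taxon's concentration share replaced by a group-specific Gaussian bump
#' in age centred on the spike peak. Counts are multinomial draws at a
#' log-normal sequencing depth (or the metadata's `scheduled_depth` where
#' set) from Dirichlet-distributed proportions.
#'
#' @param metadata Sample metadata as from [generate_cohort()].
#' @param comp A [composition_spec()].
#' @param seed Integer seed.
#' @return A [taxon_table()] with one column per metadata row.
#' @export
generate_counts <- function(metadata, comp = composition_spec(),
                            seed = 1L) {
  validate_metadata(metadata)
  if (nrow(metadata) == 0L) stop("metadata is empty")
  stopifnot(inherits(comp, "composition_spec"))
  taxa <- comp$taxa
  spike <- match(comp$spike_taxon, taxa$taxon_id)
  with_seed(derive_seed(seed, "counts"), {
    subjects <- unique(metadata$subject_id)
    eff <- matrix(
      exp(stats::rnorm(length(subjects) * nrow(taxa), 0,
                       comp$subject_effect_sd) -
            comp$subject_effect_sd^2 / 2),
      nrow = nrow(taxa),
      dimnames = list(taxa$taxon_id, subjects))
    mlog <- log(comp$reads_per_sample[1]) - comp$reads_per_sample[2]^2 / 2
    counts <- matrix(0L, nrow(taxa), nrow(metadata),
                     dimnames = list(taxa$taxon_id, metadata$sample_id))
    # the subject effect enters the spike fraction as f*e/(f*e + 1 - f),
    # which is concave in e; a second-order correction to the target
    # concentration keeps the marginal mean at the requested level
    jensen_v <- exp(comp$subject_effect_sd^2) - 1
    for (j in seq_len(nrow(metadata))) {
      f <- spike_level_at_age(comp, metadata$age_days[j], metadata$group[j])
      f <- min(f * (1 + jensen_v * f * (1 - f)), 0.999)
      w <- taxa$weight * eff[, metadata$subject_id[j]]
      w[spike] <- 0
      w <- w / sum(w) * (1 - f)
      w[spike] <- f * eff[spike, metadata$subject_id[j]]
      w <- w / sum(w)
      p <- if (comp$overdispersion <= 1e-12) w else {
        g <- stats::rgamma(length(w), shape = w / comp$overdispersion)
        if (sum(g) <= 0) w else g / sum(g)
      }
      depth <- metadata$scheduled_depth[j]
      if (is.na(depth %||% NA)) {
        depth <- max(1L, as.integer(round(stats::rlnorm(
          1, mlog, comp$reads_per_sample[2]))))
      }
      counts[, j] <- stats::rmultinom(1, depth, p)[, 1]
    }
    taxon_table(counts, taxa[, c("phylum", "genus", "species")])
  })
}

#' Generate technical replicate columns
#'
#' For each chosen sample, draws `k` replicate columns from the sample's
#' empirical composition perturbed by abundance-dependent log-normal noise
#' (sd `scale * sqrt(1e-4 / p)` on the log scale), then multinomial
#' resampling at the source sample's depth. With
#' `replicate_noise_scale = 0` replicates are plain multinomial resamples.
#' Within-group coefficient of variation therefore rises sharply as
#' abundance falls, mirroring measured technical-replicate behaviour.
#'
#' @param table A [taxon_table()].
#' @param comp A [composition_spec()]; supplies the noise scale.
#' @param k Replicates per chosen sample (>= 2).
#' @param sample_ids Samples to replicate; default all.
#' @param seed Integer seed.
#' @return List with `table` (taxon_table of replicate columns, named
#'   `<sample>__r<j>`) and `groups` (data frame `sample_id`,
#'   `replicate_group` mapping each replicate column to its source).
#' @export
generate_replicates <- function(table, comp = composition_spec(), k = 2L,
                                sample_ids = NULL, seed = 1L) {
  stopifnot(inherits(table, "taxon_table"))
  if (k < 2) stop("k must be >= 2")
  sample_ids <- sample_ids %||% colnames(table$counts)
  missing <- setdiff(sample_ids, colnames(table$counts))
  if (length(missing)) stop("unknown sample ids: ",
                            paste(missing, collapse = ", "))
  with_seed(derive_seed(seed, "replicates"), {
    out <- matrix(0L, nrow(table$counts), length(sample_ids) * k)
    cn <- character(ncol(out))
    grp <- character(ncol(out))
    col <- 0L
    for (sid in sample_ids) {
      x <- table$counts[, sid]
      depth <- sum(x)
      p <- if (depth > 0) x / depth else rep(1 / length(x), length(x))
      for (j in seq_len(k)) {
        col <- col + 1L
        w <- p
        if (comp$replicate_noise_scale > 0) {
          nz <- p > 0
          sdlog <- comp$replicate_noise_scale * sqrt(1e-4 / pmax(p[nz], 1e-6))
          w[nz] <- p[nz] * exp(stats::rnorm(sum(nz), 0, sdlog))
          w <- w / sum(w)
        }
        out[, col] <- if (depth > 0) {
          stats::rmultinom(1, depth, w)[, 1]
        } else x
        cn[col] <- sprintf("%s__r%d", sid, j)
        grp[col] <- sid
      }
    }
    dimnames(out) <- list(rownames(table$counts), cn)
    list(table = taxon_table(out, table$lineage),
         groups = data.frame(sample_id = cn, replicate_group = grp,
                             stringsAsFactors = FALSE))
  })
}

#' Generate a species-resolved fine-platform subset
#'
#' Emulates re-sequencing a subset of samples on a longer-read platform
#' that resolves the merged spike group into two species: the merged row
#' is replaced by `<spike>_sp1` and `<spike>_sp2`, with the sp1 count
#' binomial at `dorei_fraction` of the group count. Samples with the
#' highest group abundance are chosen, mirroring selection of
#' high-Bacteroides samples for deeper sequencing.
#'
#' @param table A [taxon_table()] containing the spike taxon.
#' @param comp A [composition_spec()].
#' @param n_samples Number of samples to resolve (<= available samples).
#' @param seed Integer seed.
#' @return A [taxon_table()] of the selected samples with two species rows
#'   replacing the merged group row.
#' @export
generate_fine_platform_subset <- function(table, comp = composition_spec(),
                                          n_samples = 93L, seed = 1L) {
  stopifnot(inherits(table, "taxon_table"))
  spike <- match(comp$spike_taxon, rownames(table$counts))
  if (is.na(spike)) stop("spike taxon not present in table")
  if (n_samples > ncol(table$counts)) {
    stop("n_samples exceeds available samples")
  }
  with_seed(derive_seed(seed, "fine_platform"), {
    frac <- table$counts[spike, ] / pmax(colSums(table$counts), 1)
    sel <- order(frac, decreasing = TRUE)[seq_len(n_samples)]
    sel <- sort(sel)
    cnt <- table$counts[, sel, drop = FALSE]
    g <- cnt[spike, ]
    sp1 <- stats::rbinom(length(g), g, comp$dorei_fraction)
    sp2 <- g - sp1
    out <- rbind(cnt[-spike, , drop = FALSE],
                 matrix(sp1, 1L), matrix(sp2, 1L))
    base <- table$lineage[-spike, , drop = FALSE]
    spl <- table$lineage[spike, , drop = FALSE]
    lin <- rbind(base, spl, spl)
    lin$species[(nrow(lin) - 1):nrow(lin)] <-
      paste0(spl$species, c("_sp1", "_sp2"))
    rownames(out) <- c(rownames(cnt)[-spike],
                       paste0(comp$spike_taxon, c("_sp1", "_sp2")))
    taxon_table(out, lin)
  })
}

#' Generate qPCR copy-number triplicates
#'
#' Emulates absolute-abundance measurement of one taxon: each sample's
#' expected copy number is its relative abundance times a log-normal total
#' bacterial load, and the three technical replicates carry independent
#' log-normal noise of the given sd. Expected log-copies are affine in log
#' relative abundance by construction.
#'
#' @param table A [taxon_table()].
#' @param taxon Taxon id to quantify (must be in the table).
#' @param noise Log-scale sd of replicate noise (>= 0).
#' @param total_load Length-2 numeric `(meanlog, sdlog)` of total
#'   16S copies per reaction.
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `rep1`, `rep2`, `rep3` (copies).
#' @export
generate_qpcr <- function(table, taxon = "Bacteroides_dorei_vulgatus",
                          noise = 0.3, total_load = c(log(1e8), 0.5),
                          seed = 1L) {
  stopifnot(inherits(table, "taxon_table"))
  if (noise < 0) stop("noise must be >= 0")
  if (ncol(table$counts) == 0L) stop("table has no samples")
  if (!length(taxon) || !all(taxon %in% rownames(table$counts))) {
    stop("taxon not present in table")
  }
  with_seed(derive_seed(seed, "qpcr"), {
    frac <- colSums(table$counts[taxon, , drop = FALSE]) /
      pmax(colSums(table$counts), 1)
    load <- stats::rlnorm(length(frac), total_load[1], total_load[2])
    mu <- pmax(frac, 1e-6) * load
    reps <- vapply(mu, function(m) {
      m * exp(stats::rnorm(3, 0, noise))
    }, numeric(3))
    data.frame(sample_id = colnames(table$counts),
               rep1 = reps[1, ], rep2 = reps[2, ], rep3 = reps[3, ],
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper running every generator with child seeds derived
#' from the cohort spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @param comp A [composition_spec()].
#' @param n_fine Fine-platform subset size (clipped to the cohort size).
#' @param n_qpcr qPCR sample count, drawn from samples aged 200-350 days.
#' @param replicate_samples Number of samples given technical replicates.
#' @return List with `metadata`, `covariates`, `counts`, `replicates`
#'   (list of `table`, `groups`), `fine` (species-resolved taxon_table),
#'   `qpcr` (triplicate data frame), and `comp`/`spec` echoes.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            comp = composition_spec(),
                            n_fine = 93L, n_qpcr = 28L,
                            replicate_samples = 40L) {
  ch <- generate_cohort(spec)
  counts <- generate_counts(ch$metadata, comp, seed = spec$rng_seed)
  reps <- generate_replicates(
    counts, comp, k = 2L,
    sample_ids = with_seed(derive_seed(spec$rng_seed, "repsel"),
                           sample(colnames(counts$counts),
                                  min(replicate_samples,
                                      ncol(counts$counts)))),
    seed = spec$rng_seed)
  fine <- generate_fine_platform_subset(
    counts, comp, n_samples = min(n_fine, ncol(counts$counts)),
    seed = spec$rng_seed)
  in_age <- ch$metadata$sample_id[ch$metadata$age_days >= 200 &
                                    ch$metadata$age_days <= 350]
  if (length(in_age) < 2) in_age <- ch$metadata$sample_id
  qsel <- with_seed(derive_seed(spec$rng_seed, "qpcrsel"),
                    sample(in_age, min(n_qpcr, length(in_age))))
  qpcr <- generate_qpcr(subset_samples(counts, qsel),
                        taxon = comp$spike_taxon, seed = spec$rng_seed)
  list(metadata = ch$metadata, covariates = ch$covariates, counts = counts,
       replicates = reps, fine = fine, qpcr = qpcr, spec = spec,
       comp = comp)
}

#' Write a simulated bundle to a directory of TSV files
#'
#' @param bundle Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param provenance Named character vector stamped into file headers.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(bundle$counts, file.path(dir, "counts.tsv"), provenance)
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"), provenance)
  write_tsv_prov(bundle$covariates, file.path(dir, "covariates.tsv"),
                 provenance)
  write_count_table(bundle$replicates$table,
                    file.path(dir, "replicates.tsv"), provenance)
  write_tsv_prov(bundle$replicates$groups,
                 file.path(dir, "replicate_groups.tsv"), provenance)
  write_count_table(bundle$fine, file.path(dir, "fine_platform.tsv"),
                    provenance)
  write_tsv_prov(bundle$qpcr, file.path(dir, "qpcr.tsv"), provenance)
  invisible(dir)
}
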