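# End-to-end orchestration: simulate -> preprocess -> differential ->
# windows -> calibrate -> predict, with provenance stamps, a resumable
# state file, and full determinism under one master seed. Each stage uses
# a named child seed, so toggling one stage never perturbs another's
# randomness.

#' Pipeline configuration
#'
#' @param counts,metadata,covariates,replicates,replicate_groups,fine,qpcr
#'   Input file paths; all `NULL` means "simulate the inputs" with the
#'   given cohort/composition specs.
#' @param cohort,composition Specs used when simulating (see
#'   [cohort_spec()], [composition_spec()]).
#' @param depth Rarefaction depth.
#' @param cutoff Relative-abundance cutoff; `"derive"` re-derives it from
#'   technical replicates.
#' @param ranks Ranks analyzed.
#' @param bootstrap_iterations,per_subject_k Differential-test bootstrap
#'   settings.
#' @param alpha Adjusted-p significance level.
#' @param window Window scan settings (a [window_config()]; its seed is
#'   overridden by the master seed).
#' @param scan_taxa Taxa scanned across windows; default the composition
#'   spec's spike taxon.
#' @param prediction_window Length-2 ages (days) for the fixed prediction
#'   window; default 186-368 days (6.1-12.1 months).
#' @param seed Master seed.
#' @return A `pipeline_config` list (with a stable content hash).
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL,
                            covariates = NULL, replicates = NULL,
                            replicate_groups = NULL, fine = NULL,
                            qpcr = NULL,
                            cohort = cohort_spec(),
                            composition = composition_spec(),
                            depth = 10000, cutoff = 0.01,
                            ranks = c("phylum", "genus", "species"),
                            bootstrap_iterations = 100L,
                            per_subject_k = 1L, alpha = 0.001,
                            window = window_config(),
                            scan_taxa = NULL,
                            prediction_window = c(186, 368),
                            seed = 1L) {
  cfg <- list(counts = counts, metadata = metadata,
              covariates = covariates, replicates = replicates,
              replicate_groups = replicate_groups, fine = fine,
              qpcr = qpcr, cohort = cohort, composition = composition,
              depth = depth, cutoff = cutoff, ranks = ranks,
              bootstrap_iterations = as.integer(bootstrap_iterations),
              per_subject_k = as.integer(per_subject_k), alpha = alpha,
              window = window, scan_taxa = scan_taxa,
              prediction_window = prediction_window,
              seed = as.integer(seed))
  cfg$hash <- hash_object(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults;
#' nested `cohort`, `composition` and `window` blocks override the
#' corresponding spec fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cohort", "composition", "window"))]
  if (!is.null(y$cohort)) {
    args$cohort <- do.call(cohort_spec, y$cohort)
  }
  if (!is.null(y$composition)) {
    args$composition <- do.call(composition_spec, y$composition)
  }
  if (!is.null(y$window)) args$window <- do.call(window_config, y$window)
  do.call(pipeline_config, args)
}

pipeline_provenance <- function(config) {
  c(tool = paste0("seroscan ",
                  as.character(utils::packageVersion("seroscan"))),
    config_hash = config$hash, seed = as.character(config$seed))
}

read_state <- function(out_dir) {
  p <- file.path(out_dir, "state.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else
    list(hash = NULL, completed = character(0))
}

write_state <- function(out_dir, state) {
  jsonlite::write_json(state, file.path(out_dir, "state.json"),
                       auto_unbox = TRUE, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order, writing each stage's TSV outputs
#' (stamped with tool version, config hash and seed) under `out_dir` and
#' recording completed stages in a state file so a partial failure can be
#' resumed without redoing finished stages. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param resume Reuse completed stages from a previous run of the same
#'   config (default TRUE).
#' @return Invisible result bundle (list of stage outputs).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c("counts", "metadata", "covariates", "replicates",
             "replicate_groups", "fine", "qpcr")
  for (p in paths) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("input file for '", p, "' not found: ", config[[p]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- read_state(out_dir)
  if (!resume || !identical(state$hash, config$hash)) {
    state <- list(hash = config$hash, completed = character(0))
  }
  prov <- pipeline_provenance(config)
  bundle <- list(config = config)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    state$completed <<- union(state$completed, name)
    write_state(out_dir, state)
    res
  }

  # -- inputs -------------------------------------------------------------
  bundle$data <- run_stage("simulate", function() {
    if (is.null(config$counts)) {
      cohort <- config$cohort
      cohort$rng_seed <- derive_seed(config$seed, "simulate")
      sim <- simulate_cohort(cohort, config$composition)
      write_cohort(sim, file.path(out_dir, "simulated"), prov)
      sim
    } else {
      rt <- read_tables(config$counts, config$metadata)
      list(metadata = rt$metadata, counts = rt$table,
           covariates = if (!is.null(config$covariates))
             utils::read.delim(config$covariates, comment.char = "#",
                               stringsAsFactors = FALSE) else NULL,
           replicates = if (!is.null(config$replicates))
             list(table = read_count_table(config$replicates),
                  groups = utils::read.delim(config$replicate_groups,
                                             comment.char = "#",
                                             stringsAsFactors = FALSE))
           else NULL,
           fine = if (!is.null(config$fine))
             read_count_table(config$fine) else NULL,
           qpcr = if (!is.null(config$qpcr))
             utils::read.delim(config$qpcr, comment.char = "#",
                               stringsAsFactors = FALSE) else NULL,
           comp = config$composition)
    }
  })
  data <- bundle$data

  # -- preprocess ---------------------------------------------------------
  bundle$prep <- run_stage("preprocess", function() {
    cutoff_report <- NULL
    cutoff <- config$cutoff
    if (identical(cutoff, "derive")) {
      if (is.null(data$replicates)) {
        stop("cutoff = 'derive' needs technical replicates")
      }
      rel_reps <- to_relative(data$replicates$table)
      cutoff_report <- derive_cutoff(rel_reps, data$replicates$groups)
      cutoff <- cutoff_report$cutoff
    }
    prep <- preprocess(data$counts, data$metadata, depth = config$depth,
                       cutoff = cutoff, ranks = config$ranks,
                       seed = derive_seed(config$seed, "preprocess"),
                       cutoff_report = cutoff_report)
    for (r in names(prep$ranks)) {
      tb <- prep$ranks[[r]]$table
      write_tsv_prov(data.frame(taxon = rownames(tb$fractions),
                                tb$fractions, check.names = FALSE),
                     file.path(out_dir, paste0("abundance_", r, ".tsv")),
                     prov)
    }
    prep
  })
  prep <- bundle$prep

  # -- differential abundance --------------------------------------------
  bundle$differential <- run_stage("diff", function() {
    out <- lapply(names(prep$ranks), function(r) {
      cfg <- bootstrap_config(
        iterations = config$bootstrap_iterations,
        per_subject_k = config$per_subject_k,
        seed = derive_seed(config$seed, paste0("diff/", r)))
      res <- test_all_taxa(prep$ranks[[r]]$table, prep$metadata, cfg,
                           m_total = prep$ranks[[r]]$m_total,
                           alpha = config$alpha)
      res$rank <- r
      write_tsv_prov(res, file.path(out_dir, paste0("diff_", r, ".tsv")),
                     prov)
      # LOESS trajectories for the significant taxa at this rank
      sig <- res$taxon[res$significant]
      if (length(sig)) {
        md <- prep$metadata[match(
          colnames(prep$ranks[[r]]$table$fractions),
          prep$metadata$sample_id), ]
        curves <- do.call(rbind, lapply(sig, function(tx) {
          tr <- loess_trajectory(
            md$age_days, prep$ranks[[r]]$table$fractions[tx, ],
            md$group)
          cbind(rank = r, taxon = tx, tr)
        }))
        write_tsv_prov(curves,
                       file.path(out_dir, paste0("loess_", r, ".tsv")),
                       prov)
      }
      res
    })
    names(out) <- names(prep$ranks)
    out
  })

  # -- covariate balance --------------------------------------------------
  if (!is.null(data$covariates)) {
    bundle$balance <- run_stage("balance", function() {
      bal <- covariate_balance(data$covariates)
      write_tsv_prov(bal, file.path(out_dir, "covariate_balance.tsv"),
                     prov)
      bal
    })
  }

  # -- window scan --------------------------------------------------------
  bundle$scan <- run_stage("windows", function() {
    wcfg <- config$window
    wcfg$seed <- derive_seed(config$seed, "windows")
    sp_rel <- prep$ranks$species$table
    taxa <- config$scan_taxa %||% intersect(
      rownames(sp_rel$fractions),
      rank_labels(data$counts$lineage, "species")[
        match(config$composition$spike_taxon,
              rownames(data$counts$counts))])
    sc <- scan_windows(sp_rel, prep$metadata, wcfg, taxa = taxa)
    merged <- merge(sc$tests, sc$windows, by = "window_index")
    write_tsv_prov(merged[order(merged$window_index), ],
                   file.path(out_dir, "window_scan.tsv"), prov)
    if (length(taxa)) {
      pk <- locate_peak(sc, taxa[1])
      jsonlite::write_json(
        c(pk, list(taxon = taxa[1],
                   median_age_months = days_to_months(pk$median_age))),
        file.path(out_dir, "peak.json"), auto_unbox = TRUE, digits = NA)
    }
    sc
  })

  # -- calibration --------------------------------------------------------
  if (!is.null(data$fine)) {
    bundle$calibration <- run_stage("calibrate", function() {
      fine_rel <- to_relative(data$fine)
      sp <- grep("_sp[12]$", rownames(fine_rel$fractions), value = TRUE)
      coarse_rel <- to_relative(data$counts)
      spike <- config$composition$spike_taxon
      paired <- colnames(fine_rel$fractions)
      model <- fit_calibration(
        coarse_rel$fractions[spike, paired],
        t(fine_rel$fractions[sp, paired, drop = FALSE]),
        depth = config$depth)
      rest <- setdiff(colnames(coarse_rel$fractions), paired)
      imputed <- impute_species(model, coarse_rel$fractions[spike, rest])
      write_tsv_prov(data.frame(sample_id = rest, imputed,
                                check.names = FALSE),
                     file.path(out_dir, "imputed_species.tsv"), prov)
      jsonlite::write_json(
        list(species = model$species, n = model$n,
             weighting = model$weighting),
        file.path(out_dir, "calibration.json"), auto_unbox = TRUE,
        digits = NA)
      model
    })
  }

  # -- qPCR concordance ---------------------------------------------------
  if (!is.null(data$qpcr)) {
    bundle$qpcr <- run_stage("qpcr", function() {
      rec <- qpcr_qc(data$qpcr)
      rel <- to_relative(data$counts)
      spike <- config$composition$spike_taxon
      conc <- qpcr_concordance(
        rel$fractions[spike, rec$sample_id], rec)
      write_tsv_prov(data.frame(slope = conc$slope, p = conc$p,
                                concordant = conc$concordant, n = conc$n),
                     file.path(out_dir, "qpcr_concordance.tsv"), prov)
      conc
    })
  }

  # -- prediction ---------------------------------------------------------
  bundle$prediction <- run_stage("predict", function() {
    spike_label <- rank_labels(data$counts$lineage, "species")[
      match(config$composition$spike_taxon, rownames(data$counts$counts))]
    sp_rel <- prep$ranks$species$table
    if (!spike_label %in% rownames(sp_rel$fractions)) return(NULL)
    sf <- subject_features(sp_rel, prep$metadata, spike_label,
                           config$prediction_window)
    cv <- loso_cv(sf$features)
    write_tsv_prov(cv$scores, file.path(out_dir, "subject_scores.tsv"),
                   prov)
    write_tsv_prov(
      data.frame(window_start = config$prediction_window[1],
                 window_end = config$prediction_window[2],
                 auc = cv$auc, auc_se = cv$auc_se, p = cv$p,
                 n_case = cv$n_case, n_control = cv$n_control),
      file.path(out_dir, "prediction.tsv"), prov)
    cv
  })

  invisible(bundle)
}

#' Summarize a pipeline result bundle
#'
#' @param bundle Result of [run_pipeline()].
#' @return Character vector of report lines (also printed); regeneration
#'   is idempotent and sections whose stages are absent are omitted.
#' @export
report <- function(bundle) {
  lines <- c("seroscan pipeline report",
             sprintf("config hash: %s, seed: %d", bundle$config$hash,
                     bundle$config$seed))
  if (!is.null(bundle$differential)) {
    for (r in names(bundle$differential)) {
      d <- bundle$differential[[r]]
      sig <- d[d$significant, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s: %d/%d taxa significant at adjusted p < %g", r, nrow(sig),
        nrow(d), bundle$config$alpha))
      if (nrow(sig)) {
        lines <- c(lines, sprintf(
          "  %s (%s, adjusted p = %.3g, case median %.3g vs control %.3g)",
          sig$taxon, sig$direction, sig$fdr_p, sig$case_median,
          sig$control_median))
      }
    }
  } else lines <- c(lines, "differential stage missing")
  if (!is.null(bundle$scan) && nrow(bundle$scan$tests)) {
    for (tx in unique(bundle$scan$tests$taxon)) {
      pk <- locate_peak(bundle$scan, tx)
      lines <- c(lines, sprintf(
        "window scan %s: %d/%d windows at p<0.05, min p %.3g at median age %.0f d (%.1f mo)",
        tx, sum(bundle$scan$tests$sig05[bundle$scan$tests$taxon == tx]),
        nrow(bundle$scan$windows), pk$p, pk$median_age,
        days_to_months(pk$median_age)))
    }
  }
  if (!is.null(bundle$calibration)) {
    m <- bundle$calibration
    lines <- c(lines, sprintf(
      "calibration: shares %s over %d paired samples",
      paste(sprintf("%s=%.3f", names(m$pooled_shares), m$pooled_shares),
            collapse = ", "), m$n))
  }
  if (!is.null(bundle$qpcr)) {
    lines <- c(lines, sprintf(
      "qPCR concordance: slope %.3g, p %.3g (%s)", bundle$qpcr$slope,
      bundle$qpcr$p,
      if (bundle$qpcr$concordant) "concordant" else "not concordant"))
  }
  if (!is.null(bundle$prediction)) {
    cv <- bundle$prediction
    lines <- c(lines, sprintf(
      "prediction: AUC %.3f (SE %.3f), p %.3g over %d cases / %d controls",
      cv$auc, cv$auc_se, cv$p, cv$n_case, cv$n_control))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
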