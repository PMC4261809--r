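# Sliding-window scan across age: contiguous runs of age-sorted samples,
# truncated to at most two samples per subject (nearest the window
# midpoint), collapsed to one median profile per subject, tested by
# bootstrap-averaged Mann-Whitney, flagged at 0.05 / 0.01.

#' Window scan configuration
#'
#' Defaults mirror the emulated study's realized windows: ~98 samples per
#' window after truncating each subject to at most two samples, windows
#' advanced by 10 age-sorted samples, and windows with fewer than 20 case
#' or 20 control subjects discarded.
#'
#' @param target_samples_per_window Post-truncation samples per window.
#' @param max_samples_per_subject Per-subject cap within a window; the
#'   samples nearest the window's age midpoint are kept.
#' @param min_cases,min_controls Minimum subjects per group to retain a
#'   window.
#' @param step Advance, in age-sorted samples, between window starts.
#' @param iterations Bootstrap iterations per window and taxon.
#' @param seed Integer seed.
#' @return A `window_config` list.
#' @export
window_config <- function(target_samples_per_window = 98L,
                          max_samples_per_subject = 2L,
                          min_cases = 20L, min_controls = 20L,
                          step = 10L, iterations = 100L, seed = 1L) {
  vals <- c(target_samples_per_window, max_samples_per_subject,
            min_cases, min_controls, step, iterations)
  if (any(vals < 1)) stop("all window config counts must be >= 1")
  structure(list(target_samples_per_window =
                   as.integer(target_samples_per_window),
                 max_samples_per_subject =
                   as.integer(max_samples_per_subject),
                 min_cases = as.integer(min_cases),
                 min_controls = as.integer(min_controls),
                 step = as.integer(step),
                 iterations = as.integer(iterations), seed = seed),
            class = "window_config")
}

# keep at most k samples per subject, nearest the midpoint of the run's
# age span (ties -> earlier sample)
truncate_window <- function(md_run, k) {
  mid <- (min(md_run$age_days) + max(md_run$age_days)) / 2
  keep <- unlist(lapply(split(seq_len(nrow(md_run)), md_run$subject_id),
                        function(i) {
    if (length(i) <= k) return(i)
    i[order(abs(md_run$age_days[i] - mid),
            md_run$age_days[i])][seq_len(k)]
  }), use.names = FALSE)
  md_run[sort(keep), , drop = FALSE]
}

#' Build sliding age windows
#'
#' Samples are sorted by age; from each start position the contiguous run
#' is extended until it holds `target_samples_per_window` samples after
#' per-subject truncation (or the cohort ends). Windows not meeting the
#' minimum case/control subject counts are discarded (their positions are
#' reported in `dropped`).
#'
#' @param metadata Sample metadata.
#' @param cfg A [window_config()].
#' @return List with `windows` (each: `sample_ids`, `start_day`,
#'   `end_day` — half-open `[start, end)` — `median_age`, `n_case`,
#'   `n_control`) and `dropped` (count of gated-out windows). Warns when
#'   no window passes the gate.
#' @export
build_windows <- function(metadata, cfg = window_config()) {
  validate_metadata(metadata)
  md <- metadata[order(metadata$age_days, metadata$sample_id), ]
  n <- nrow(md)
  subj_count <- function(run) {
    tab <- tapply(run$subject_id, run$subject_id, length)
    sum(pmin(tab, cfg$max_samples_per_subject))
  }
  windows <- list()
  dropped <- 0L
  seen <- character(0)
  for (i in seq(1L, n, by = cfg$step)) {
    j <- i
    cnt <- integer(0)
    # grow run until the truncated sample count reaches the target
    tabs <- new.env(parent = emptyenv())
    total <- 0L
    while (j <= n) {
      s <- md$subject_id[j]
      prev <- get0(s, envir = tabs, ifnotfound = 0L)
      assign(s, prev + 1L, envir = tabs)
      if (prev < cfg$max_samples_per_subject) total <- total + 1L
      if (total >= cfg$target_samples_per_window) break
      j <- j + 1L
    }
    j <- min(j, n)
    run <- md[i:j, , drop = FALSE]
    win <- truncate_window(run, cfg$max_samples_per_subject)
    key <- paste(win$sample_id, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    groups <- tapply(win$group, win$subject_id, function(g) g[1])
    n_case <- sum(groups == "case")
    n_control <- sum(groups == "control")
    if (n_case < cfg$min_cases || n_control < cfg$min_controls) {
      dropped <- dropped + 1L
      next
    }
    windows[[length(windows) + 1L]] <- list(
      sample_ids = win$sample_id,
      start_day = min(win$age_days),
      end_day = max(win$age_days) + 1L,
      median_age = stats::median(win$age_days),
      n_case = n_case, n_control = n_control)
    if (j >= n) break
  }
  if (!length(windows)) {
    warning("no window satisfies the minimum case/control subject counts")
  }
  list(windows = windows, dropped = dropped)
}

#' Collapse one subject's in-window samples to a median profile
#'
#' @param fractions Taxa-by-sample matrix of the subject's in-window
#'   samples (>= 1 column).
#' @return Named numeric vector: per-taxon median across the samples.
#' @export
subject_median_profile <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (!ncol(fractions)) stop("need at least one sample")
  apply(fractions, 1L, stats::median)
}

# taxa x subjects matrix of median profiles for one window
window_profiles <- function(rel_table, metadata, sample_ids, taxa) {
  md <- metadata[match(sample_ids, metadata$sample_id), ]
  fr <- rel_table$fractions[taxa, sample_ids, drop = FALSE]
  subj <- unique(md$subject_id)
  prof <- vapply(subj, function(s) {
    subject_median_profile(fr[, md$subject_id == s, drop = FALSE])
  }, numeric(length(taxa)))
  if (length(taxa) == 1L) prof <- matrix(prof, nrow = 1L)
  dimnames(prof) <- list(taxa, subj)
  label <- vapply(subj, function(s) md$group[md$subject_id == s][1],
                  character(1))
  list(profiles = prof, labels = label)
}

#' Sliding-window differential abundance scan
#'
#' Within each retained window, each subject's samples collapse to a
#' per-taxon median profile; per taxon, the case and control profile sets
#' are compared by a bootstrap-averaged Mann-Whitney test in which every
#' iteration draws `min(n_case, n_control)` subjects per group with
#' replacement, equalizing group sampling frequency. Flags mark windows
#' significant at 0.05 and 0.01 (unadjusted, as is conventional for this
#' display). Per-window/taxon seeds derive from the config seed, so the
#' scan is invariant to input row order.
#'
#' @param rel_table A `rel_abundance`.
#' @param metadata Matching sample metadata.
#' @param cfg A [window_config()].
#' @param taxa Taxa to test (default: all rows); may be empty, in which
#'   case windows are still reported without tests.
#' @return A `window_scan`: list with `windows` (data frame
#'   `window_index`, `start_day`, `end_day`, `median_age`, `n_case`,
#'   `n_control`) and `tests` (data frame `window_index`, `taxon`,
#'   `boot_p`, `sig05`, `sig01`).
#' @export
scan_windows <- function(rel_table, metadata, cfg = window_config(),
                         taxa = rownames(rel_table$fractions)) {
  stopifnot(inherits(rel_table, "rel_abundance"))
  md <- metadata[metadata$sample_id %in% colnames(rel_table$fractions), ]
  bw <- build_windows(md, cfg)
  wdf <- do.call(rbind, lapply(seq_along(bw$windows), function(i) {
    w <- bw$windows[[i]]
    data.frame(window_index = i, start_day = w$start_day,
               end_day = w$end_day, median_age = w$median_age,
               n_case = w$n_case, n_control = w$n_control)
  }))
  tests <- list()
  for (i in seq_along(bw$windows)) {
    w <- bw$windows[[i]]
    if (!length(taxa)) break
    wp <- window_profiles(rel_table, md, w$sample_ids, taxa)
    case_i <- which(wp$labels == "case")
    ctrl_i <- which(wp$labels == "control")
    m <- min(length(case_i), length(ctrl_i))
    for (tx in taxa) {
      seed <- derive_seed(cfg$seed %||% 0L,
                          sprintf("scan/%d-%d/%s", w$start_day,
                                  w$end_day, tx))
      p <- with_seed(seed, {
        mean(vapply(seq_len(cfg$iterations), function(it) {
          mw_p(wp$profiles[tx, sample(case_i, m, replace = TRUE)],
               wp$profiles[tx, sample(ctrl_i, m, replace = TRUE)])
        }, numeric(1)))
      })
      tests[[length(tests) + 1L]] <- data.frame(
        window_index = i, taxon = tx, boot_p = p,
        sig05 = p < 0.05, sig01 = p < 0.01, stringsAsFactors = FALSE)
    }
  }
  structure(list(windows = wdf %||%
                   data.frame(window_index = integer(0)),
                 tests = if (length(tests)) do.call(rbind, tests) else
                   data.frame(window_index = integer(0),
                              taxon = character(0), boot_p = numeric(0),
                              sig05 = logical(0), sig01 = logical(0)),
                 dropped = bw$dropped),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window_scan: %d windows (%d gated out), %d tests\n",
              nrow(x$windows) %||% 0L, x$dropped, nrow(x$tests)))
  invisible(x)
}

#' Locate the minimum-p window for a taxon
#'
#' @param scan A [scan_windows()] result.
#' @param taxon Taxon id present in the scan.
#' @return List `window_index`, `start_day`, `end_day`, `median_age`,
#'   `p`. Ties go to the earliest window.
#' @export
locate_peak <- function(scan, taxon) {
  stopifnot(inherits(scan, "window_scan"))
  tt <- scan$tests[scan$tests$taxon == taxon, ]
  if (!nrow(tt)) stop("taxon not present in scan: ", taxon)
  tt <- tt[order(tt$window_index), ]
  best <- tt$window_index[which.min(tt$boot_p)]
  w <- scan$windows[scan$windows$window_index == best, ]
  list(window_index = best, start_day = w$start_day,
       end_day = w$end_day, median_age = w$median_age,
       p = min(tt$boot_p))
}
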