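# Subject-aware prediction of case status from spike-taxon abundance:
# per-subject median features in an age window, leave-one-subject-out
# cross-validated logistic regression, AUC with Hanley-McNeil standard
# error, and a window scan of prediction accuracy.

#' Per-subject abundance features within an age window
#'
#' Each subject's feature is the median abundance of `taxon` over that
#' subject's samples with `start_day <= age < end_day`. Subjects without
#' in-window samples are excluded and counted.
#'
#' @param rel_table A `rel_abundance`.
#' @param metadata Matching sample metadata.
#' @param taxon Taxon id (row of `rel_table`).
#' @param window Length-2 numeric `[start_day, end_day)` in days.
#' @return List with `features` (data frame `subject_id`, `group`,
#'   `feature`) and `n_excluded`.
#' @export
subject_features <- function(rel_table, metadata, taxon, window) {
  stopifnot(inherits(rel_table, "rel_abundance"), length(window) == 2L)
  if (!taxon %in% rownames(rel_table$fractions)) {
    stop("taxon not in table: ", taxon)
  }
  md <- metadata[metadata$sample_id %in% colnames(rel_table$fractions), ]
  inw <- md$age_days >= window[1] & md$age_days < window[2]
  if (!any(inw)) stop("window contains no samples")
  a <- rel_table$fractions[taxon, md$sample_id]
  subj <- unique(md$subject_id)
  rows <- lapply(subj, function(s) {
    sel <- inw & md$subject_id == s
    if (!any(sel)) return(NULL)
    data.frame(subject_id = s, group = md$group[sel][1],
               feature = stats::median(a[sel]), stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  list(features = feats, n_excluded = length(subj) - nrow(feats))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, with ties counted one half (the Mann-Whitney identity).
#'
#' @param scores Numeric predicted scores.
#' @param labels `"case"`/`"control"` per score (both classes present).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  is_case <- labels == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (!n1 || !n0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-parameter logistic fit by IRLS; returns c(intercept, slope).
# Much faster than stats::glm for the thousands of small cross-validation
# fits; saturates cleanly under separation.
fit_logit2 <- function(x, y) {
  b0 <- stats::qlogis(min(max(mean(y), 0.01), 0.99))
  b1 <- 0
  for (it in 1:25) {
    eta <- pmin(pmax(b0 + b1 * x, -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    r <- y - mu
    sw <- sum(w)
    swx <- sum(w * x)
    swxx <- sum(w * x * x)
    det <- sw * swxx - swx^2
    if (!is.finite(det) || det < 1e-12) break
    g0 <- sum(r)
    g1 <- sum(r * x)
    d0 <- (swxx * g0 - swx * g1) / det
    d1 <- (-swx * g0 + sw * g1) / det
    b0 <- b0 + d0
    b1 <- b1 + d1
    if (abs(d0) + abs(d1) < 1e-9) break
  }
  c(b0, b1)
}

# Hanley-McNeil standard error of an AUC estimate
auc_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt(max(0, (a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                 (n0 - 1) * (q2 - a^2)) / (n1 * n0)))
}

#' Leave-one-subject-out cross-validated prediction
#'
#' A logistic regression of case status on the feature is cross-validated
#' at the subject level: no subject's data ever informs its own
#' prediction. Per-subject scores come from leave-one-subject-out folds
#' (predicted probability minus the training fold's case prevalence,
#' which removes the leave-one-out prevalence artifact). The AUC itself
#' is estimated by leave-pair-out cross-validation: for every
#' case-control subject pair, the model is refitted without both
#' subjects and the pair is scored by whether the held-out case outranks
#' the held-out control (ties one half). Pooled leave-one-out scores
#' carry a well-known pessimistic AUC bias — each fold's slope is
#' anticorrelated with its held-out label — whereas the pairwise
#' estimator is unbiased under the null, so its mean is 1/2 when the
#' feature carries no signal. The Hanley-McNeil formula supplies the
#' AUC standard error; significance is the 1-df likelihood-ratio
#' chi-square of the full-data logistic fit. Training folds that
#' degenerate (one class, or a constant feature) fall back to the prior
#' rate and are flagged.
#'
#' @param features Data frame from [subject_features()] (`subject_id`,
#'   `group`, `feature`), >= 5 subjects per group.
#' @param labels Optional explicit labels overriding `features$group`.
#' @param seed Unused (the procedure is deterministic); accepted for
#'   interface uniformity.
#' @param auc_method `"leave-pair-out"` (default) or `"pooled"`
#'   (AUC of the pooled leave-one-subject-out scores; pessimistically
#'   biased, retained for comparison).
#' @return A `prediction_result`: `auc`, `auc_se`, `p`, `scores` (data
#'   frame `subject_id`, `group`, `score` from the leave-one-out folds),
#'   `n_case`, `n_control`, `n_fallback_folds`.
#' @export
loso_cv <- function(features, labels = NULL, seed = NULL,
                    auc_method = c("leave-pair-out", "pooled")) {
  auc_method <- match.arg(auc_method)
  labels <- labels %||% features$group
  y <- as.integer(labels == "case")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 5L || n0 < 5L) stop("need >= 5 subjects per group")
  x <- features$feature
  scores <- numeric(length(y))
  fallback <- 0L
  for (i in seq_along(y)) {
    yi <- y[-i]
    xi <- x[-i]
    if (length(unique(yi)) < 2L || stats::var(xi) == 0) {
      scores[i] <- 0
      fallback <- fallback + 1L
      next
    }
    b <- fit_logit2(xi, yi)
    scores[i] <- stats::plogis(b[1] + b[2] * x[i]) - mean(yi)
  }
  a <- if (auc_method == "pooled") {
    auc(scores, labels)
  } else {
    cases <- which(y == 1L)
    ctrls <- which(y == 0L)
    tot <- 0
    const_x <- stats::var(x) == 0
    for (i in cases) {
      for (j in ctrls) {
        if (const_x) {
          tot <- tot + 0.5
          next
        }
        keep <- -c(i, j)
        b <- fit_logit2(x[keep], y[keep])
        si <- b[1] + b[2] * x[i]
        sj <- b[1] + b[2] * x[j]
        tot <- tot + (si > sj) + 0.5 * (si == sj)
      }
    }
    tot / (n1 * n0)
  }
  full <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  null <- stats::glm(y ~ 1, family = stats::binomial())
  stat <- max(null$deviance - full$deviance, 0)
  structure(list(auc = a, auc_se = auc_se(a, n1, n0),
                 p = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 scores = data.frame(subject_id = features$subject_id,
                                     group = labels, score = scores,
                                     stringsAsFactors = FALSE),
                 n_case = n1, n_control = n0,
                 n_fallback_folds = fallback),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "prediction_result: AUC %.3f (SE %.3f), p %.3g, %d cases / %d controls\n",
    x$auc, x$auc_se, x$p, x$n_case, x$n_control))
  invisible(x)
}

#' Scan prediction accuracy across age windows
#'
#' Runs [loso_cv()] on per-subject features from every retained sliding
#' window and reports the AUC-maximizing window; when case
#' seroconversion ages are supplied, flags whether that window's upper
#' age bound precedes the cohort's median seroconversion age.
#'
#' @param rel_table A `rel_abundance`.
#' @param metadata Matching sample metadata.
#' @param taxon Feature taxon id.
#' @param cfg A [window_config()] (minimum subject counts apply; windows
#'   whose feature sets fall under 5 subjects per group are skipped).
#' @param seroconversion_age_days Optional numeric vector of case
#'   seroconversion ages.
#' @return List with `windows` (data frame `window_index`, `start_day`,
#'   `end_day`, `median_age`, `auc`, `auc_se`, `p`, `n_case`,
#'   `n_control`), `best` (that row), and
#'   `best_precedes_seroconversion` (logical or `NA`).
#' @export
scan_prediction_windows <- function(rel_table, metadata, taxon,
                                    cfg = window_config(),
                                    seroconversion_age_days = NULL) {
  bw <- build_windows(
    metadata[metadata$sample_id %in% colnames(rel_table$fractions), ], cfg)
  rows <- list()
  for (i in seq_along(bw$windows)) {
    w <- bw$windows[[i]]
    sf <- subject_features(rel_table, metadata, taxon,
                           c(w$start_day, w$end_day))
    n1 <- sum(sf$features$group == "case")
    n0 <- sum(sf$features$group == "control")
    if (n1 < 5L || n0 < 5L) next
    cv <- loso_cv(sf$features)
    rows[[length(rows) + 1L]] <- data.frame(
      window_index = i, start_day = w$start_day, end_day = w$end_day,
      median_age = w$median_age, auc = cv$auc, auc_se = cv$auc_se,
      p = cv$p, n_case = n1, n_control = n0)
  }
  if (!length(rows)) stop("no window yields enough subjects to predict")
  windows <- do.call(rbind, rows)
  best <- windows[which.max(windows$auc), ]
  precedes <- if (is.null(seroconversion_age_days)) NA else
    best$end_day < stats::median(seroconversion_age_days, na.rm = TRUE)
  list(windows = windows, best = best,
       best_precedes_seroconversion = precedes)
}
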