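# Cross-platform species calibration: weighted Poisson regression of
# fine-platform species pseudo-counts on coarse-platform group abundance,
# cohort-wide imputation, and qPCR absolute-abundance concordance.

#' Fit the species calibration model
#'
#' For each species, regresses its fine-platform pseudo-counts
#' (`fraction x depth`, rounded) on the log of the coarse-platform group
#' fraction with a log-link Poisson GLM, weighting observations
#' proportionally to group abundance (normalized to mean 1) because
#' measurement variance falls as abundance rises. Reports per-species
#' coefficients, deviance and squared-correlation R², and the pooled
#' species share of the group.
#'
#' @param group_abund Coarse-platform group fractions, one per paired
#'   sample (>= 10 pairs, > 0 in at least 5).
#' @param species_abund Matrix or data frame of fine-platform species
#'   fractions (one column per species, same row order).
#' @param depth Pseudo-count depth (default 10,000, the rarefaction
#'   depth).
#' @param weight_by_abundance Use abundance-proportional weights
#'   (default TRUE); FALSE gives equal weights.
#' @return A `calibration_model`: per-species `intercept`, `slope`,
#'   `r2_deviance`, `r2_pearson`, `share`; plus `pooled_shares`, `n`,
#'   `depth`, `weighting`.
#' @export
fit_calibration <- function(group_abund, species_abund, depth = 10000,
                            weight_by_abundance = TRUE) {
  species_abund <- as.matrix(species_abund)
  if (is.null(colnames(species_abund))) {
    colnames(species_abund) <- paste0("species", seq_len(ncol(species_abund)))
  }
  if (length(group_abund) != nrow(species_abund)) {
    stop("group_abund and species_abund sizes differ")
  }
  if (length(group_abund) < 10L) stop("need >= 10 paired samples")
  pos <- group_abund > 0
  if (sum(pos) < 5L) stop("need group abundance > 0 in >= 5 samples")
  g <- group_abund[pos]
  w <- if (weight_by_abundance) g / mean(g) else rep(1, length(g))
  fits <- lapply(colnames(species_abund), function(sp) {
    y <- round(species_abund[pos, sp] * depth)
    if (all(y == 0)) {
      return(list(species = sp, intercept = -Inf, slope = 0,
                  r2_deviance = NA_real_, r2_pearson = NA_real_,
                  share = 0, degenerate = TRUE))
    }
    fit <- suppressWarnings(
      stats::glm(y ~ log(g), family = stats::poisson(), weights = w,
                 control = stats::glm.control(epsilon = 1e-12,
                                              maxit = 100L)))
    r2_dev <- 1 - fit$deviance / fit$null.deviance
    r2_pea <- stats::cor(y, fit$fitted.values)^2
    list(species = sp, intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]), r2_deviance = r2_dev,
         r2_pearson = r2_pea,
         share = sum(species_abund[pos, sp]) / sum(g),
         degenerate = FALSE)
  })
  names(fits) <- colnames(species_abund)
  structure(list(species = fits,
                 pooled_shares = vapply(fits, `[[`, numeric(1), "share"),
                 n = length(g), depth = depth,
                 weighting = if (weight_by_abundance) "abundance" else
                   "equal"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %d species, %d paired samples (%s weights)\n",
              length(x$species), x$n, x$weighting))
  for (f in x$species) {
    cat(sprintf("  %s: share %.3f, deviance R2 %.3f\n",
                f$species, f$share, f$r2_deviance))
  }
  invisible(x)
}

#' Impute species abundances from group abundance
#'
#' Applies the fitted calibration to coarse-platform group fractions.
#' Predictions are clipped to `[0, group]` per species and jointly
#' rescaled when their sum would exceed the group fraction.
#'
#' @param model A [fit_calibration()] result.
#' @param group_abund Group fractions to impute from.
#' @return Matrix of species fractions, one column per species.
#' @export
impute_species <- function(model, group_abund) {
  stopifnot(inherits(model, "calibration_model"))
  out <- vapply(model$species, function(f) {
    pred <- ifelse(group_abund > 0 & is.finite(f$intercept),
                   exp(f$intercept + f$slope * log(group_abund)) /
                     model$depth,
                   0)
    pmin(pmax(pred, 0), group_abund)
  }, numeric(length(group_abund)))
  if (length(group_abund) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- names(model$species)
  tot <- rowSums(out)
  over <- tot > group_abund & tot > 0
  if (any(over)) {
    out[over, ] <- out[over, , drop = FALSE] *
      (group_abund[over] / tot[over])
  }
  out
}

#' Quality-control a qPCR triplicate
#'
#' @param values Exactly three positive copy-number measurements.
#' @param cv_threshold Maximum tolerated coefficient of variation
#'   (default 0.3).
#' @return List `copies` (triplicate mean), `cv`, `retained`.
#' @export
triplicate_qc <- function(values, cv_threshold = 0.3) {
  if (length(values) != 3L) stop("a triplicate has exactly 3 values")
  if (any(!is.finite(values) | values <= 0)) {
    stop("copy numbers must be positive")
  }
  m <- mean(values)
  cv <- stats::sd(values) / m
  list(copies = m, cv = cv, retained = cv <= cv_threshold)
}

#' QC a table of qPCR triplicates
#'
#' @param qpcr Data frame `sample_id`, `rep1`, `rep2`, `rep3`.
#' @param cv_threshold Passed to [triplicate_qc()].
#' @return Data frame `sample_id`, `copies`, `cv`, `retained`.
#' @export
qpcr_qc <- function(qpcr, cv_threshold = 0.3) {
  res <- lapply(seq_len(nrow(qpcr)), function(i) {
    r <- triplicate_qc(as.numeric(qpcr[i, c("rep1", "rep2", "rep3")]),
                       cv_threshold)
    data.frame(sample_id = qpcr$sample_id[i], copies = r$copies,
               cv = r$cv, retained = r$retained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Concordance of relative and absolute abundance
#'
#' Regresses QC-retained qPCR copy numbers on relative abundance with a
#' log-link quasi-Poisson GLM (the quasi-likelihood dispersion absorbs
#' the technical overdispersion of copy-number data, keeping the test
#' calibrated) and declares concordance when the slope is positive with
#' p < 0.01.
#'
#' @param rel_abund Relative abundance per record (same order as
#'   `records`).
#' @param records Data frame as from [qpcr_qc()] (needs `copies`,
#'   `retained`); >= 5 retained records required.
#' @return List `slope`, `p`, `concordant`, `n`.
#' @export
qpcr_concordance <- function(rel_abund, records) {
  keep <- records$retained
  if (sum(keep) < 5L) stop("need >= 5 QC-retained qPCR records")
  y <- records$copies[keep]
  x <- rel_abund[keep]
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::quasipoisson()))
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  p <- sm["x", "Pr(>|t|)"]
  list(slope = slope, p = p, concordant = slope > 0 && p < 0.01,
       n = sum(keep))
}
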