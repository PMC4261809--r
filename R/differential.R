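# Case-vs-control testing: Mann-Whitney U with exact small-sample
# enumeration, per-subject balanced bootstrap averaging of p-values,
# Benjamini-Hochberg correction over the full (pre-cutoff) taxon count,
# logistic age x abundance interaction tests, LOESS trajectories, and
# chi-square covariate balance checks.

# fast two-sided Mann-Whitney p-value. Exact (via the null distribution of
# U) when both groups have <= `exact_max` observations and there are no
# ties; tie-corrected normal approximation with continuity correction
# otherwise.
mw_p <- function(x, y, exact_max = 8L) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  if (nx <= exact_max && ny <= exact_max && !any(ties > 1L)) {
    p <- if (u > nx * ny / 2) {
      stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE) +
        stats::pwilcox(nx * ny - u, nx, ny)
    } else {
      stats::pwilcox(u, nx, ny) +
        stats::pwilcox(nx * ny - u - 1, nx, ny, lower.tail = FALSE)
    }
    return(min(1, p))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of the U null distribution when both groups have at
#' most 8 observations and no ties occur; mid-rank, tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric vectors of abundances for the two groups (both
#'   non-empty).
#' @return List with `statistic` (U for `x`), `p.value`, and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p.value  # 1/3
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  exact <- nx <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  list(statistic = u, p.value = mw_p(x, y),
       method = if (exact) "exact" else "normal approximation")
}

#' Bootstrap configuration for balanced testing
#'
#' @param iterations Bootstrap iterations (default 100).
#' @param per_subject_k Samples drawn per subject per iteration (with
#'   replacement when a subject has fewer); default 1, which makes each
#'   iteration a one-sample-per-subject test.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @param balance_groups Unused placeholder kept for forward
#'   compatibility of stored configs.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(iterations = 100L, per_subject_k = 1L,
                             seed = NULL, balance_groups = TRUE) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (per_subject_k < 1) stop("per_subject_k must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 per_subject_k = as.integer(per_subject_k),
                 seed = seed, balance_groups = isTRUE(balance_groups)),
            class = "bootstrap_config")
}

#' Bootstrap-balanced Mann-Whitney p-value
#'
#' Counters unequal per-subject sampling frequency in repeated-measures
#' cohorts: each iteration draws `per_subject_k` samples from every
#' subject (with replacement if the subject has fewer), runs the
#' Mann-Whitney test on the resampled case and control values, and the
#' reported p-value is the arithmetic mean over iterations.
#'
#' @param abundance Numeric vector, one value per sample.
#' @param labels Character vector (`"case"`/`"control"`) per sample.
#' @param subjects Subject id per sample; each group needs >= 2 subjects.
#' @param cfg A [bootstrap_config()].
#' @return Averaged p-value (numeric scalar).
#' @export
bootstrap_balanced_p <- function(abundance, labels, subjects,
                                 cfg = bootstrap_config()) {
  stopifnot(length(abundance) == length(labels),
            length(abundance) == length(subjects))
  by_subj <- split(seq_along(abundance), subjects)
  subj_label <- vapply(by_subj, function(i) labels[i[1]], character(1))
  case_s <- which(subj_label == "case")
  ctrl_s <- which(subj_label == "control")
  if (length(case_s) < 2 || length(ctrl_s) < 2) {
    stop("need at least 2 subjects per group")
  }
  k <- cfg$per_subject_k
  with_seed(cfg$seed, {
    ps <- vapply(seq_len(cfg$iterations), function(it) {
      draw <- function(sidx) {
        unlist(lapply(by_subj[sidx], function(i) {
          ii <- if (length(i) == 1L && k == 1L) i else
            sample(i, k, replace = length(i) < k)
          abundance[ii]
        }), use.names = FALSE)
      }
      mw_p(draw(case_s), draw(ctrl_s))
    }, numeric(1))
    mean(ps)
  })
}

#' Benjamini-Hochberg adjustment over an inflated hypothesis count
#'
#' Step-up BH where the denominator ranks act as if `m_total` hypotheses
#' were tested, with the untested ones at p = 1. Use this when taxa below
#' the abundance-reliability cutoff were excluded from testing but must
#' still count toward the FDR correction.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m_total Total hypothesis count (>= `length(p)`).
#' @return Adjusted p-values, in the input order.
#' @export
fdr_adjust <- function(p, m_total = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m_total < m) stop("m_total must be >= length(p)")
  if (!m) return(numeric(0))
  o <- order(p)
  padj <- rev(cummin(rev(p[o] * m_total / seq_len(m))))
  pmin(1, padj)[order(o)]
}

#' Test every retained taxon for case/control abundance differences
#'
#' Runs both testing routes on each taxon at one rank: (1) across all
#' samples, the raw Mann-Whitney p and the bootstrap-balanced averaged p;
#' (2) across age, the logistic age-by-abundance interaction
#' likelihood-ratio p. Each route is BH-adjusted over `m_total`
#' hypotheses, and a taxon is significant when either adjusted p falls
#' below `alpha` — mirroring how such cohorts are analysed "across all
#' samples and across age". Per-taxon bootstrap seeds are derived from
#' the config seed and the taxon name so results do not depend on taxon
#' order.
#'
#' @param rel_table A `rel_abundance` (one rank, cutoff applied).
#' @param metadata Matching sample metadata.
#' @param cfg A [bootstrap_config()].
#' @param m_total Total taxon count at this rank before the cutoff.
#' @param alpha Significance level on the adjusted p (default 0.001).
#' @param include_age_test Also run the age-interaction route
#'   (default TRUE); taxa whose interaction is inestimable get `NA`
#'   there and are judged on the all-samples route alone.
#' @return Data frame, one row per taxon: `taxon`, `raw_p`, `boot_p`,
#'   `fdr_p`, `interaction_p`, `interaction_fdr_p`, `case_median`,
#'   `control_median`, `direction`, `significant`.
#' @export
test_all_taxa <- function(rel_table, metadata, cfg = bootstrap_config(),
                          m_total = nrow(rel_table$fractions),
                          alpha = 0.001, include_age_test = TRUE) {
  stopifnot(inherits(rel_table, "rel_abundance"))
  md <- metadata[match(colnames(rel_table$fractions), metadata$sample_id), ]
  is_case <- md$group == "case"
  taxa <- rownames(rel_table$fractions)
  res <- lapply(taxa, function(tx) {
    a <- rel_table$fractions[tx, ]
    tcfg <- cfg
    tcfg$seed <- derive_seed(cfg$seed %||% 0L, paste0("taxon/", tx))
    boot_p <- bootstrap_balanced_p(a, md$group, md$subject_id, tcfg)
    int_p <- NA_real_
    if (include_age_test) {
      int_p <- tryCatch(
        age_interaction_test(a, md$age_days, md$group)$p,
        error = function(e) NA_real_)
    }
    cm <- stats::median(a[is_case])
    km <- stats::median(a[!is_case])
    dir <- if (cm > km) "case-higher" else if (km > cm) "control-higher"
      else if (mean(a[is_case]) >= mean(a[!is_case])) "case-higher"
      else "control-higher"
    data.frame(taxon = tx, raw_p = mw_p(a[is_case], a[!is_case]),
               boot_p = boot_p, interaction_p = int_p, case_median = cm,
               control_median = km, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- fdr_adjust(out$boot_p, m_total)
  out$interaction_fdr_p <- fdr_adjust(
    ifelse(is.na(out$interaction_p), 1, out$interaction_p), m_total)
  out$interaction_fdr_p[is.na(out$interaction_p)] <- NA_real_
  out$significant <- out$fdr_p < alpha |
    (!is.na(out$interaction_fdr_p) & out$interaction_fdr_p < alpha)
  out[, c("taxon", "raw_p", "boot_p", "fdr_p", "interaction_p",
          "interaction_fdr_p", "case_median", "control_median",
          "direction", "significant")]
}

# Firth-penalized logistic regression (bias-reduced ML); used as the
# fallback when ordinary ML separates. Returns coefficients and the
# penalized log-likelihood.
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- solve(info, score)
    b <- b + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  pen <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  list(coef = b, loglik = ll + as.numeric(pen))
}

#' Logistic age-by-abundance interaction test
#'
#' Fits `case ~ abundance + age + abundance:age` with a logit link and
#' tests the interaction by a 1-df likelihood-ratio chi-square against
#' the no-interaction model. On (quasi-)separation the test falls back to
#' Firth-penalized fits of both models and the result is flagged.
#'
#' @param abundance Numeric vector per sample.
#' @param age_days Numeric age per sample (must vary).
#' @param labels `"case"`/`"control"` per sample (both present).
#' @param subjects Optional subject ids, carried through for provenance.
#' @return List with `p`, `statistic` (LR chi-square), `separated` flag,
#'   and the fitted `coefficients`.
#' @export
age_interaction_test <- function(abundance, age_days, labels,
                                 subjects = NULL) {
  y <- as.integer(labels == "case")
  if (!any(y == 1L) || !any(y == 0L)) stop("both labels must be present")
  if (stats::var(age_days) == 0) stop("age variation required")
  if (stats::var(abundance) == 0) {
    stop("interaction inestimable: abundance is constant")
  }
  a <- scale(abundance)[, 1]
  t <- scale(age_days)[, 1]
  separated <- FALSE
  full <- withCallingHandlers(
    stats::glm(y ~ a + t + a:t, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!separated) {
    red <- stats::glm(y ~ a + t, family = stats::binomial())
    stat <- red$deviance - full$deviance
    coefs <- stats::coef(full)
  } else {
    Xf <- cbind(1, a, t, a * t)
    Xr <- Xf[, 1:3]
    ff <- firth_logistic(Xf, y)
    fr <- firth_logistic(Xr, y)
    stat <- 2 * (ff$loglik - fr$loglik)
    coefs <- ff$coef
  }
  stat <- max(stat, 0)
  list(p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       statistic = stat, separated = separated, coefficients = coefs)
}

#' LOESS abundance trajectories by group
#'
#' Locally weighted degree-1 regression (tricube weights) of abundance on
#' age, fitted per group and evaluated with pointwise standard errors on
#' a common age grid spanning the full observed range.
#'
#' @param age_days Numeric ages per sample.
#' @param abundance Numeric abundances per sample.
#' @param labels Group labels per sample (>= 10 points per group).
#' @param span LOESS span in (0, 1\] (default 0.75).
#' @param grid_n Number of grid points (default 50).
#' @return Data frame `group`, `age_days`, `fit`, `se`; rows outside a
#'   group's own age range carry `NA` fits.
#' @export
loess_trajectory <- function(age_days, abundance, labels, span = 0.75,
                             grid_n = 50L) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  grid <- seq(min(age_days), max(age_days), length.out = grid_n)
  out <- lapply(unique(labels), function(g) {
    sel <- labels == g
    if (sum(sel) < 10L) stop("need >= 10 points per group")
    d <- data.frame(age = age_days[sel], ab = abundance[sel])
    fit <- stats::loess(ab ~ age, data = d, span = span, degree = 1L,
                        control = stats::loess.control(surface = "direct"))
    pr <- stats::predict(fit, newdata = data.frame(age = grid), se = TRUE)
    inside <- grid >= min(age_days[sel]) & grid <= max(age_days[sel])
    data.frame(group = g, age_days = grid,
               fit = ifelse(inside, pr$fit, NA_real_),
               se = ifelse(inside, pr$se.fit, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chi-square covariate balance check
#'
#' Tests each categorical covariate against case/control status with a
#' contingency chi-square (no continuity correction). Numeric covariates
#' with more than `max_levels` distinct values are binned at quantiles
#' first. Single-level covariates are undefined and reported as `NA`.
#'
#' @param covariates Data frame, one row per subject; a `group` column
#'   (or `labels`) gives case/control status.
#' @param labels Optional explicit label vector overriding
#'   `covariates$group`.
#' @param max_levels Bin numeric covariates above this many levels.
#' @return Data frame `covariate`, `statistic`, `df`, `p`,
#'   `low_expected_cells` (TRUE when any expected cell < 5).
#' @export
covariate_balance <- function(covariates, labels = NULL, max_levels = 6L) {
  labels <- labels %||% covariates$group
  if (is.null(labels)) stop("labels required (or a 'group' column)")
  vars <- setdiff(names(covariates),
                  c("group", "subject_id", "seroconversion_age_days"))
  res <- lapply(vars, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x) && length(unique(x)) > max_levels) {
      x <- cut(x, unique(stats::quantile(x, c(0, 1 / 3, 2 / 3, 1))),
               include.lowest = TRUE)
    }
    x <- factor(x)
    if (nlevels(x) < 2L) {
      return(data.frame(covariate = v, statistic = NA_real_,
                        df = NA_integer_, p = NA_real_,
                        low_expected_cells = NA))
    }
    tab <- table(x, labels)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(covariate = v, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               low_expected_cells = any(ct$expected < 5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
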