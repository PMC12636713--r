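# Donor-level association statistics relating imaging phenotypes to
# clinical and pathological traits.

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of `y` on `x` plus covariates (t-test within a
#' linear model); the canonical adjustment set for these cohorts is age,
#' sex, dichotomized background staining level and, where available,
#' post-mortem interval. Rows with missing values are dropped (listwise
#' deletion).
#'
#' @param data Data frame with one row per donor.
#' @param y,x Column names of the response and the predictor of interest.
#' @param covariates Character vector of covariate column names (may be
#'   empty; then this is simple regression).
#' @param conf_level Confidence level for the effect CI (default 0.95).
#' @return List: `effect` (coefficient of `x`), `ci` (length 2), `p`
#'   (two-sided), `n` (rows used), `fit` (the `lm` object).
#' @export
linear_association <- function(data, y, x, covariates = character(0),
                               conf_level = 0.95) {
  vars <- c(y, x, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  p_terms <- 1L + length(covariates)
  if (nrow(d) <= p_terms + 2L)
    stop("too few complete observations (n must exceed p + 2)")
  rhs <- paste(c(x, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(y, "~", rhs)), data = d)
  if (any(is.na(stats::coef(fit))))
    stop("collinearity error: rank-deficient design")
  sm <- summary(fit)$coefficients
  # coefficient row(s) belonging to x (factor predictors expand to dummies)
  xi <- which(attr(stats::terms(fit), "term.labels") == x)
  rows <- which(fit$assign == xi)
  if (length(rows) != 1L)
    stop("predictor '", x, "' must map to a single coefficient")
  ci <- stats::confint(fit, level = conf_level)[rows, ]
  list(effect = unname(sm[rows, "Estimate"]),
       ci = unname(ci),
       p = unname(sm[rows, "Pr(>|t|)"]),
       n = nrow(d), fit = fit)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the nonzero paired differences, tie-corrected; the
#' exact null distribution is used for up to 25 informative, untied pairs
#' and the normal approximation with continuity correction otherwise.
#'
#' @param a,b Equal-length paired numeric vectors with at least 5
#'   informative (nonzero-difference) pairs.
#' @return List: `statistic` (V), `p`, `n` (informative pairs), `exact`.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L)
    stop("degenerate input: all paired differences are zero")
  if (length(nz) < 5L)
    stop("need at least 5 informative pairs")
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(nz), exact = exact)
}

#' Pearson correlation with test
#'
#' @param x,y Numeric vectors.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-group cognitive slopes from longitudinal scores
#'
#' For each group, fits a linear mixed model of score on time with
#' subject-level random intercepts and slopes (REML) and reports the
#' fixed-effect slope. On non-convergence or a degenerate design the
#' estimate falls back to the two-stage procedure: per-subject OLS slopes
#' (subjects with >= 2 distinct time points) averaged within the group.
#'
#' @param scores Data frame with columns `subject`, `time`, `score`,
#'   `group`.
#' @return Data frame with one row per group: `group`, `slope`, `method`
#'   (`"lmm"` or `"two_stage"`), `n_subjects`.
#' @export
group_slopes <- function(scores) {
  need <- c("subject", "time", "score", "group")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(scores, scores$group), function(g) {
    slope <- NA_real_; method <- "two_stage"
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(score ~ time + (1 + time | subject), data = g,
                   REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    converged <- !is.null(fit) &&
      length(fit@optinfo$conv$lme4) == 0L
    if (converged) {
      slope <- unname(lme4::fixef(fit)["time"])
      method <- "lmm"
    } else {
      sl <- vapply(split(g, g$subject), function(s) {
        if (length(unique(s$time)) < 2L) return(NA_real_)
        unname(stats::coef(stats::lm(score ~ time, data = s))["time"])
      }, numeric(1))
      slope <- mean(sl, na.rm = TRUE)
      if (all(is.na(sl))) slope <- NA_real_
    }
    data.frame(group = g$group[1], slope = slope, method = method,
               n_subjects = length(unique(g$subject)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
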