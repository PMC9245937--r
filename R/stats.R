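# Cohort statistics: Spearman correlations, covariate-adjusted linear
# models, genotype-stratified correlation analysis, group contrasts.

stat_result <- function(kind, estimate, p_value, n, outcome, predictor,
                        covariates = character(0), stratum = "",
                        transform = "none") {
  structure(
    data.frame(kind = kind, estimate = estimate, p_value = p_value,
               n = n, outcome = outcome, predictor = predictor,
               covariates = paste(covariates, collapse = "+"),
               stratum = stratum, transform = transform,
               stringsAsFactors = FALSE),
    class = c("stat_result", "data.frame"))
}

#' Spearman rank correlation
#'
#' Computes the rank correlation on average ranks (ties averaged) with
#' pairwise-complete handling of missing values.  The two-sided p-value
#' uses the t approximation for n > 10 and the exact null distribution of
#' the rank statistic for n <= 10 (falling back to the t approximation in
#' the presence of ties, where the exact distribution does not apply).
#'
#' @param x,y numeric vectors of equal length.
#' @param outcome,predictor,stratum labels carried into the result.
#' @return a `stat_result` row with `kind = "spearman"`.
#' @export
spearman <- function(x, y, outcome = "y", predictor = "x", stratum = "") {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  r <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  stat_result("spearman", r, min(p, 1), n, outcome, predictor,
              stratum = stratum)
}

# "Transformed as required": log-transform when the raw outcome looks
# non-normal (Shapiro-Wilk W < 0.95) but its log looks no worse.
choose_transform <- function(v) {
  if (any(v <= 0, na.rm = TRUE)) return("none")
  w_raw <- tryCatch(stats::shapiro.test(v)$statistic, error = function(e) 1)
  if (w_raw >= 0.95) return("none")
  w_log <- tryCatch(stats::shapiro.test(log(v))$statistic,
                    error = function(e) 0)
  if (w_log > w_raw) "log" else "none"
}

#' Covariate-adjusted linear model for one predictor
#'
#' Ordinary least squares of the (optionally log-transformed) outcome on
#' the predictor plus covariates.  Outcome and predictor are z-scored so
#' the reported coefficient is a standardized beta; sex enters as a binary
#' indicator.  The transformation rule (`"auto"`: log the outcome when a
#' Shapiro-Wilk normality score below 0.95 on the raw but not the logged
#' values indicates skew) is recorded in the result.
#'
#' @param data cohort data.frame.
#' @param outcome,predictor column names.  A character/factor predictor
#'   with two levels enters as an indicator for its second level.
#' @param covariates character vector of column names (default: age at
#'   death, sex, post-mortem interval).
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @param stratum label carried into the result.
#' @return a `stat_result` row with `kind = "linear_model"`.
#' @export
fit_adjusted_model <- function(data, outcome, predictor,
                               covariates = c("age_death", "sex",
                                              "pm_interval"),
                               transform = c("auto", "none", "log"),
                               stratum = "") {
  transform <- match.arg(transform)
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  p_par <- length(cols) + 1
  if (nrow(d) <= p_par + 2)
    stop("too few complete cases (", nrow(d), ") for ", p_par,
         " parameters", call. = FALSE)
  y <- d[[outcome]]
  if (transform == "auto") transform <- choose_transform(y)
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform needs positive outcome",
                          call. = FALSE)
    y <- log(y)
  }
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  to_num <- function(v) {
    if (is.numeric(v)) return(v)
    lev <- sort(unique(as.character(v)))
    if (length(lev) > 2)
      stop("non-numeric predictor with > 2 levels", call. = FALSE)
    as.numeric(as.character(v) == lev[length(lev)])
  }
  df <- data.frame(.y = zscore(y), .x = zscore(to_num(d[[predictor]])))
  for (cv in covariates) df[[cv]] <- to_num(d[[cv]])
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  stat_result("linear_model", sm[".x", "Estimate"], sm[".x", "Pr(>|t|)"],
              nrow(d), outcome, predictor, covariates, stratum,
              transform)
}

#' Genotype-stratified marker-outcome correlations
#'
#' One Spearman correlation per (marker, stratum), with no pooling across
#' strata.  Strata with fewer than 3 complete pairs are skipped with a
#' warning.
#'
#' @param data cohort data.frame.
#' @param markers character vector of marker column names.
#' @param outcome outcome column (default neuronal density).
#' @param stratifier stratifying column (default genotype).
#' @return a `stat_result` data.frame, possibly empty.
#' @export
stratified_correlations <- function(data, markers,
                                    outcome = "neuron_density",
                                    stratifier = "genotype") {
  out <- list()
  for (lev in unique(data[[stratifier]])) {
    d <- data[data[[stratifier]] == lev, , drop = FALSE]
    for (m in markers) {
      n_ok <- sum(stats::complete.cases(d[[m]], d[[outcome]]))
      if (n_ok < 3) {
        warning("stratum '", lev, "' skipped for marker '", m,
                "': fewer than 3 complete pairs", call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <-
        spearman(d[[m]], d[[outcome]], outcome, m, stratum = lev)
    }
  }
  if (!length(out))
    return(stat_result("spearman", NA_real_, NA_real_, 0L, "", "")[0, ])
  do.call(rbind, out)
}

#' Adjusted contrast of an outcome between two groups
#'
#' Means and SEMs per group, the percent difference relative to
#' `group_a` (the reference, by convention the control/larger group), and
#' a p-value from the covariate-adjusted linear model with the group
#' indicator as predictor.
#'
#' @param data cohort data.frame.
#' @param outcome outcome column.
#' @param group_a,group_b level labels of `group_var`; `group_a` is the
#'   reference of the percent difference.
#' @param group_var grouping column.
#' @param covariates covariate columns for the adjusted model; `NULL` or
#'   empty for an unadjusted contrast (Welch t-test p).
#' @return a `group_contrast` list: `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `percent_difference`, `adjusted_p`, `n_a`,
#'   `n_b`.
#' @export
group_contrast <- function(data, outcome, group_a, group_b,
                           group_var = "group",
                           covariates = c("age_death", "sex",
                                          "pm_interval")) {
  va <- data[data[[group_var]] == group_a, outcome, drop = TRUE]
  vb <- data[data[[group_var]] == group_b, outcome, drop = TRUE]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (!length(va) || !length(vb))
    stop("outcome '", outcome, "' absent for a group", call. = FALSE)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  ma <- mean(va); mb <- mean(vb)
  p <- if (is.null(covariates) || !length(covariates)) {
    if (stats::sd(c(va, vb)) == 0) 1
    else stats::t.test(va, vb)$p.value
  } else {
    d <- data[data[[group_var]] %in% c(group_a, group_b), , drop = FALSE]
    d$.grp <- factor(d[[group_var]], levels = c(group_a, group_b))
    fit_adjusted_model(d, outcome, ".grp", covariates)$p_value
  }
  structure(
    list(group_a = group_a, group_b = group_b, mean_a = ma, mean_b = mb,
         sem_a = sem(va), sem_b = sem(vb),
         percent_difference = 100 * (ma - mb) / ma,
         adjusted_p = p, n_a = length(va), n_b = length(vb)),
    class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf(
    "<group_contrast> %s %.4g +/- %.3g vs %s %.4g +/- %.3g: %.1f%% (p = %.3g)\n",
    x$group_a, x$mean_a, x$sem_a, x$group_b, x$mean_b, x$sem_b,
    x$percent_difference, x$adjusted_p))
  invisible(x)
}
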