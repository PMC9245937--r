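# Synthetic cohort generator: per-case records with planted group means and
# genotype-dependent rank correlations via a Gaussian copula.

#' Cohort simulation configuration
#'
#' Describes the strata of a post-mortem cohort (MS cases split by
#' HLA-DRB1*15 carrier status, plus controls) and, per stratum, the
#' marginal distributions of each variable and the target Spearman
#' correlations between the microglial markers (and fibrinogen) and
#' neuronal density.
#'
#' Dependence model: within a stratum, neuronal density is the latent
#' factor; each correlated variable k loads on it with latent Pearson
#' correlation `rho_k = 2*sin(pi*r_k/6)` where `r_k` is the target
#' Spearman correlation (the exact Pearson-Spearman relation for a
#' bivariate Gaussian copula).  This one-factor structure is positive
#' definite whenever every `|rho_k| < 1`.  Marker expressions and
#' fibrinogen get log-normal marginals (non-negative, right-skewed);
#' neuronal density, age and post-mortem interval are Gaussian.
#'
#' Default means reproduce the printed cohort structure: 21 carrier and 26
#' non-carrier MS cases plus 10 controls; group marker means/SEMs and
#' neuron densities as published for the full cohort; ages and post-mortem
#' intervals per the cohort table (SDs back-computed from SEM x sqrt(n)
#' where printed, otherwise set to a quarter of the printed range).
#'
#' @param strata named list; each element is a list with fields `n`
#'   (cases), `group` (`"MS"` or `"control"`), `genotype` (`"DRB15_pos"`,
#'   `"DRB15_neg"` or `"not_applicable"`), `vars` (named list of marginal
#'   specs `list(mean=, sd=, dist="normal"|"lognormal")`), `p_female`,
#'   and `spearman` (named numeric, target rank correlation of that
#'   variable with `neuron_density`).
#' @param mean_coverage,mean_neuron_size optional named numerics (per
#'   stratum) planting per-case mean coverage / neuron size.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(strata = default_strata(),
                          mean_coverage = NULL, mean_neuron_size = NULL) {
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (s$n <= 0) stop("stratum '", nm, "' has non-positive n", call. = FALSE)
    bad <- names(s$spearman)[abs(s$spearman) >= 1]
    if (length(bad))
      stop("infeasible correlation target (|r| >= 1) for ",
           paste0(nm, ":", bad, collapse = ", "), call. = FALSE)
  }
  structure(list(strata = strata, mean_coverage = mean_coverage,
                 mean_neuron_size = mean_neuron_size),
            class = "cohort_config")
}

# Marginal specs shared by the MS strata; means in the units of the
# published tables (markers: millions of pixels/mm^2; lymphocytes:
# cells/mm^2; density: neurons/mm^2).
ms_vars <- function() list(
  age_death      = list(mean = 63,   sd = 12,   dist = "normal"),
  pm_interval    = list(mean = 18,   sd = 7,    dist = "normal"),
  disease_duration = list(mean = 31, sd = 11,   dist = "normal"),
  fibrinogen     = list(mean = 1.0,  sd = 0.6,  dist = "lognormal"),
  iba1           = list(mean = 6.18, sd = 3.77, dist = "lognormal"),
  cd68           = list(mean = 1.77, sd = 2.19, dist = "lognormal"),
  tmem119        = list(mean = 0.47, sd = 1.58, dist = "lognormal"),
  gfap           = list(mean = 0.85, sd = 2.67, dist = "lognormal"),
  cd3            = list(mean = 4.16, sd = 4.25, dist = "lognormal"),
  cd8            = list(mean = 1.77, sd = 2.13, dist = "lognormal"),
  neuron_density = list(mean = 414,  sd = 117,  dist = "normal"))

control_vars <- function() {
  v <- ms_vars()
  v$disease_duration <- NULL
  v$age_death   <- list(mean = 74,   sd = 8.5,  dist = "normal")
  v$pm_interval <- list(mean = 36.7, sd = 15.5, dist = "normal")
  v$iba1        <- list(mean = 6.16, sd = 2.21, dist = "lognormal")
  v$cd68        <- list(mean = 1.35, sd = 1.01, dist = "lognormal")
  v$tmem119     <- list(mean = 0.49, sd = 0.73, dist = "lognormal")
  v$gfap        <- list(mean = 0.84, sd = 1.36, dist = "lognormal")
  v$cd3         <- list(mean = 0.88, sd = 0.79, dist = "lognormal")
  v$cd8         <- list(mean = 0.10, sd = 0.22, dist = "lognormal")
  v$neuron_density <- list(mean = 431, sd = 85, dist = "normal")
  v
}

#' @rdname cohort_config
#' @export
default_strata <- function() list(
  DRB15_pos = list(
    n = 21, group = "MS", genotype = "DRB15_pos", p_female = 14 / 21,
    vars = ms_vars(),
    spearman = c(iba1 = 0.207, cd68 = 0.185, tmem119 = 0.355,
                 fibrinogen = -0.3)),
  DRB15_neg = list(
    n = 26, group = "MS", genotype = "DRB15_neg", p_female = 20 / 26,
    vars = ms_vars(),
    spearman = c(iba1 = 0.740, cd68 = 0.632, tmem119 = 0.522,
                 fibrinogen = -0.3)),
  control = list(
    n = 10, group = "control", genotype = "not_applicable",
    p_female = 3 / 10, vars = control_vars(),
    spearman = c(iba1 = 0.07, cd68 = 0.33, tmem119 = 0.26,
                 fibrinogen = 0)))

lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a cohort with planted rank correlations
#'
#' Draws each stratum from a Gaussian copula whose latent correlation
#' between a variable and neuronal density is `2*sin(pi*r_s/6)` for the
#' configured target Spearman `r_s`, then maps latent normals through the
#' configured marginals.  Rank correlations are invariant to the
#' (monotone) marginal transforms, so sample Spearman correlations
#' concentrate on their targets as n grows.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame of per-case records: `case_id`, `group`, `genotype`,
#'   `age_death`, `sex`, `pm_interval`, `disease_duration`, `fibrinogen`,
#'   `iba1`, `cd68`, `tmem119`, `gfap`, `cd3`, `cd8`, `neuron_density`,
#'   `mean_coverage`, `mean_neuron_size` (`NA` unless planted).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    out <- lapply(names(config$strata), function(nm) {
      s <- config$strata[[nm]]
      n <- s$n
      rho <- 2 * sin(pi * s$spearman / 6)
      z_fac <- stats::rnorm(n)   # latent factor = neuron-density score
      draw_var <- function(v, spec) {
        z <- if (v == "neuron_density") z_fac
             else if (v %in% names(rho))
               rho[[v]] * z_fac + sqrt(1 - rho[[v]]^2) * stats::rnorm(n)
             else stats::rnorm(n)
        if (spec$dist == "lognormal") {
          p <- lognormal_pars(spec$mean, spec$sd)
          stats::qlnorm(stats::pnorm(z), p["meanlog"], p["sdlog"])
        } else spec$mean + spec$sd * z
      }
      vals <- lapply(names(s$vars), function(v) draw_var(v, s$vars[[v]]))
      names(vals) <- names(s$vars)
      df <- data.frame(
        case_id = sprintf("%s_%02d", nm, seq_len(n)),
        group = s$group, genotype = s$genotype,
        age_death = vals$age_death,
        sex = ifelse(stats::runif(n) < s$p_female, "F", "M"),
        pm_interval = pmax(vals$pm_interval, 1),
        disease_duration = if (is.null(vals$disease_duration)) NA_real_
                           else pmax(vals$disease_duration, 1),
        fibrinogen = vals$fibrinogen,
        iba1 = vals$iba1, cd68 = vals$cd68, tmem119 = vals$tmem119,
        gfap = vals$gfap, cd3 = vals$cd3, cd8 = vals$cd8,
        neuron_density = pmax(vals$neuron_density, 10),
        mean_coverage = if (!is.null(config$mean_coverage[[nm]]))
          stats::rnorm(n, config$mean_coverage[[nm]],
                       0.1 * config$mean_coverage[[nm]]) else NA_real_,
        mean_neuron_size = if (!is.null(config$mean_neuron_size[[nm]]))
          stats::rnorm(n, config$mean_neuron_size[[nm]],
                       0.1 * config$mean_neuron_size[[nm]]) else NA_real_,
        stringsAsFactors = FALSE)
      df
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

cohort_column_dictionary <- c(
  case_id = "case identifier",
  group = "MS or control",
  genotype = "HLA-DRB1*15 carrier status (not_applicable for controls)",
  age_death = "age at death, years",
  sex = "M or F",
  pm_interval = "post-mortem interval, hours",
  disease_duration = "disease duration, years (empty for controls)",
  fibrinogen = "fibrinogen burden, arbitrary units",
  iba1 = "Iba1+ expression, millions of pixels/mm^2",
  cd68 = "CD68+ expression, millions of pixels/mm^2",
  tmem119 = "TMEM119+ expression, millions of pixels/mm^2",
  gfap = "GFAP+ coverage, millions of pixels/mm^2",
  cd3 = "CD3+ lymphocytes, cells/mm^2",
  cd8 = "CD8+ lymphocytes, cells/mm^2",
  neuron_density = "NeuN+ neurons/mm^2",
  mean_coverage = "mean inhibitory synaptic coverage, puncta/um^2",
  mean_neuron_size = "mean neuron size, um^2")

#' Write / read a cohort table as CSV
#'
#' The CSV carries a commented column dictionary in its header; missing
#' values are empty fields.  `read_cohort_csv(write_cohort_csv(x))`
#' round-trips exactly (up to numeric print precision of 15 significant
#' digits).
#'
#' @param records cohort data.frame from [simulate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: the
#'   cohort data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (col in names(records))
    writeLines(sprintf("# %s: %s", col,
                       cohort_column_dictionary[col] %||% ""), con)
  fmt <- records
  for (col in names(fmt))
    if (is.numeric(fmt[[col]]))
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA_character_,
                           format(fmt[[col]], digits = 15, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "")
  num <- setdiff(names(df), c("case_id", "group", "genotype", "sex"))
  df[num] <- lapply(df[num], as.numeric)
  df
}
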