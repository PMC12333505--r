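#' Read a coculture game-assay timecourse table
#'
#' Tab- or whitespace-delimited text with header columns `well_id`,
#' `initial_ancestor_fraction`, `time_h`, `count_ancestor`, `count_mutant`.
#' Each well is a coculture seeded at a known initial ancestor fraction and
#' imaged in two channels over time.
#'
#' @param path File path.
#' @return A validated tibble (see [validate_game_assay()]).
#' @export
read_game_assay <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  validate_game_assay(as_tibble(tab))
}

#' Validate a game-assay table
#'
#' Checks the schema and invariants: counts nonnegative, initial fractions
#' in `[0, 1]`, times strictly increasing within each well, at least three
#' timepoints per well.
#'
#' @param data A data frame of assay measurements.
#' @return The data as a tibble, invisibly validated.
#' @export
validate_game_assay <- function(data) {
  need <- c("well_id", "initial_ancestor_fraction", "time_h",
            "count_ancestor", "count_mutant")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing game-assay columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (any(data$count_ancestor < 0) || any(data$count_mutant < 0)) {
    abort("Counts must be nonnegative.")
  }
  p <- data$initial_ancestor_fraction
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`initial_ancestor_fraction` must lie in [0, 1].")
  }
  by_well <- split(data$time_h, data$well_id)
  if (any(vapply(by_well, function(t) any(diff(t) <= 0), logical(1)))) {
    abort("Times must be strictly increasing within each well.")
  }
  if (any(vapply(by_well, length, integer(1)) < 3L)) {
    abort("Each well needs at least 3 timepoints.")
  }
  data
}

#' Generate a synthetic game-assay dataset with known ground truth
#'
#' Emulates the coculture design: wells seeded at several initial ancestor
#' fractions, imaged every 4 h over 96 h, with replicate wells per fraction.
#' The ancestor grows exponentially at the reference rate; the mutant grows
#' at `ancestor_rate * mutant_fitness(truth, p)` using the well's *initial*
#' ancestor fraction `p`. Counts are perturbed by multiplicative lognormal
#' noise and left continuous (they stand for image-derived cell numbers).
#'
#' @param truth A [fitness_profile()]: the ground-truth `(fi, fe)` in units
#'   of the ancestor's growth rate.
#' @param fractions Initial ancestor fractions (>= 3 distinct values).
#' @param times Imaging times in hours.
#' @param replicates Wells per fraction.
#' @param n0 Total cells seeded per well.
#' @param ancestor_rate Ancestor growth rate per hour (reference rate;
#'   default 0.03/h, a ~23 h doubling time).
#' @param noise_sd Standard deviation of the log-counts noise (0 = exact).
#' @param seed Optional RNG seed for reproducibility.
#' @return A game-assay tibble (see [read_game_assay()] for the schema).
#' @examples
#' d <- generate_synthetic_assay(fitness_profile(0.8, 1.0), seed = 1)
#' fit <- game_fit(d)
#' glance(fit)
#' @export
generate_synthetic_assay <- function(truth,
                                     fractions = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                     times = seq(0, 96, by = 4),
                                     replicates = 3L,
                                     n0 = 1500,
                                     ancestor_rate = 0.03,
                                     noise_sd = 0.05,
                                     seed = NULL) {
  stopifnot(inherits(truth, "fitness_profile") || (is.list(truth) &&
              all(c("fi", "fe") %in% names(truth))))
  if (!is.null(seed)) set.seed(seed)
  wells <- tidyr::expand_grid(
    initial_ancestor_fraction = fractions,
    rep = seq_len(replicates)
  ) %>%
    mutate(well_id = sprintf("p%03d_r%d",
                             round(100 * .data$initial_ancestor_fraction),
                             .data$rep))
  prof <- if (inherits(truth, "fitness_profile")) truth else
    fitness_profile(truth$fi, truth$fe)
  out <- tidyr::expand_grid(wells, time_h = times) %>%
    mutate(
      mut_rate = ancestor_rate *
        (prof$fi + (prof$fe - prof$fi) * .data$initial_ancestor_fraction),
      count_ancestor = n0 * .data$initial_ancestor_fraction *
        exp(ancestor_rate * .data$time_h),
      count_mutant = n0 * (1 - .data$initial_ancestor_fraction) *
        exp(.data$mut_rate * .data$time_h)
    )
  if (noise_sd > 0) {
    k <- nrow(out)
    out$count_ancestor <- out$count_ancestor * exp(rnorm(k, 0, noise_sd))
    out$count_mutant <- out$count_mutant * exp(rnorm(k, 0, noise_sd))
  }
  out %>%
    select("well_id", "initial_ancestor_fraction", "time_h",
           "count_ancestor", "count_mutant")
}

# slope/intercept/R^2 of a least-squares line y ~ x, without lm() overhead
ls_line <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  fit <- mean(y) + slope * xc
  ssr <- sum((y - fit)^2)
  sst <- sum(yc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = if (sst > 0) 1 - ssr / sst else 1)
}

#' Per-well exponential growth rates
#'
#' Fits `log(count) ~ time` by least squares within the window for each
#' well and channel; the slope is the growth rate per hour. Wells with any
#' nonpositive count inside the window are flagged and excluded from the
#' fit rather than silently imputed.
#'
#' @param data A game-assay tibble (see [read_game_assay()]).
#' @param window Time interval `c(lo, hi)` in hours used for the fit
#'   (default the full timecourse).
#' @return A tibble with one row per well and channel: `well_id`,
#'   `initial_ancestor_fraction`, `channel` (`"ancestor"`/`"mutant"`),
#'   `rate` (per hour), `r_squared`, `n_points`, `excluded`.
#' @export
estimate_growth_rates <- function(data, window = NULL) {
  data <- validate_game_assay(data)
  if (is.null(window)) window <- range(data$time_h)
  data <- filter(data, .data$time_h >= window[1], .data$time_h <= window[2])
  long <- tidyr::pivot_longer(
    data, c("count_ancestor", "count_mutant"),
    names_to = "channel", names_prefix = "count_", values_to = "count"
  )
  long %>%
    group_by(.data$well_id, .data$initial_ancestor_fraction, .data$channel) %>%
    dplyr::group_modify(function(d, key) {
      if (any(d$count <= 0) || nrow(d) < 3L) {
        return(tibble(n_points = nrow(d), excluded = TRUE,
                      rate = NA_real_, r_squared = NA_real_))
      }
      f <- ls_line(d$time_h, log(d$count))
      tibble(n_points = nrow(d), excluded = FALSE,
             rate = f$slope, r_squared = f$r_squared)
    }) %>%
    dplyr::ungroup()
}

#' Fit frequency-dependent fitness from per-well growth rates
#'
#' Normalises each well's mutant growth rate by the mean ancestor rate
#' across wells (the model fixes the ancestor's fitness at 1) and regresses
#' the relative rate linearly on the well's *initial* ancestor fraction
#' `p`. The fitted line evaluated at `p = 0` estimates the intrinsic
#' fitness `fi` and at `p = 1` the ecological fitness `fe`. A positive
#' ecological interaction is declared when the one-sided test of slope > 0
#' rejects at `alpha`. Confidence intervals are bootstrap-t intervals:
#' wells are resampled with replacement (ancestor normalisation recomputed
#' per resample), and the interval is the estimate plus/minus
#' `qt(1 - (1-conf)/2, n - 2)` times the bootstrap standard error inflated
#' by `sqrt(n / (n - 2))` — the small-sample degrees-of-freedom correction
#' for the two fitted regression parameters, without which case-resampling
#' intervals undercover at this design size (15 wells).
#'
#' @param rates Output of [estimate_growth_rates()].
#' @param bootstrap Number of bootstrap resamples (0 to skip CIs).
#' @param conf Confidence level.
#' @param alpha Level of the one-sided slope test.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `game_fit`; see [tidy.game_fit()] and
#'   [glance.game_fit()].
#' @export
fit_frequency_dependence <- function(rates, bootstrap = 1000L, conf = 0.95,
                                     alpha = 0.05, seed = NULL) {
  stopifnot(all(c("well_id", "initial_ancestor_fraction", "channel", "rate")
                %in% names(rates)))
  wide <- rates %>%
    filter(!.data$excluded) %>%
    tidyr::pivot_wider(id_cols = c("well_id", "initial_ancestor_fraction"),
                       names_from = "channel", values_from = "rate") %>%
    filter(is.finite(.data$ancestor), is.finite(.data$mutant))
  if (length(unique(wide$initial_ancestor_fraction)) < 3L) {
    abort("Need at least 3 distinct initial ancestor fractions to fit frequency dependence.")
  }
  point <- function(d) {
    ref <- mean(d$ancestor)
    rel <- d$mutant / ref
    f <- ls_line(d$initial_ancestor_fraction, rel)
    c(fi = f$intercept, fe = f$intercept + f$slope, slope = f$slope,
      ref_rate = ref, r_squared = f$r_squared)
  }
  est <- point(wide)
  # one-sided slope > 0 test from the classical t statistic
  m <- lm(I(mutant / mean(ancestor)) ~ initial_ancestor_fraction, data = wide)
  sm <- summary(m)$coefficients
  tval <- sm["initial_ancestor_fraction", "t value"]
  p_one_sided <- pt(tval, df = nrow(wide) - 2L, lower.tail = FALSE)

  ci <- NULL
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    nb <- nrow(wide)
    boots <- matrix(NA_real_, bootstrap, 3L,
                    dimnames = list(NULL, c("fi", "fe", "slope")))
    for (b in seq_len(bootstrap)) {
      d <- wide[sample.int(nb, nb, replace = TRUE), ]
      if (length(unique(d$initial_ancestor_fraction)) < 2L) next
      pb <- point(d)
      boots[b, ] <- pb[c("fi", "fe", "slope")]
    }
    se_boot <- apply(boots, 2, sd, na.rm = TRUE) * sqrt(nb / (nb - 2))
    half <- qt(1 - (1 - conf) / 2, df = nb - 2L) * se_boot
    mid <- est[c("fi", "fe", "slope")]
    ci <- rbind(lower = mid - half, upper = mid + half)
    colnames(ci) <- c("fi", "fe", "slope")
  }
  out <- list(
    rates = rates, wells = wide,
    fi_hat = unname(est["fi"]), fe_hat = unname(est["fe"]),
    slope = unname(est["slope"]), ref_rate = unname(est["ref_rate"]),
    r_squared = unname(est["r_squared"]),
    p_value_slope = unname(p_one_sided), alpha = alpha,
    positive_interaction = p_one_sided < alpha,
    conf = conf, ci = ci, bootstrap = if (bootstrap > 0L) bootstrap else 0L,
    n_wells = nrow(wide)
  )
  class(out) <- "game_fit"
  out
}

#' Estimate frequency-dependent fitness from a coculture timecourse
#'
#' Convenience wrapper: [estimate_growth_rates()] then
#' [fit_frequency_dependence()].
#'
#' @param data A game-assay tibble.
#' @param window Fitting window in hours (default full timecourse).
#' @param ... Passed to [fit_frequency_dependence()].
#' @return A `game_fit` object.
#' @export
game_fit <- function(data, window = NULL, ...) {
  fit_frequency_dependence(estimate_growth_rates(data, window), ...)
}

#' @export
print.game_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<game_fit> %d wells; ancestor reference rate %.4g /h\n",
      "  fi_hat = %.4g, fe_hat = %.4g (slope %.4g, one-sided p = %.3g)\n",
      "  %s ecological interaction at alpha = %.2g\n"
    ),
    x$n_wells, x$ref_rate, x$fi_hat, x$fe_hat, x$slope, x$p_value_slope,
    if (x$positive_interaction) "POSITIVE" else "no significant", x$alpha
  ))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CI: fi [%.4g, %.4g], fe [%.4g, %.4g]\n",
                100 * x$conf, x$ci[1, "fi"], x$ci[2, "fi"],
                x$ci[1, "fe"], x$ci[2, "fe"]))
  }
  invisible(x)
}

#' Tidy a game-assay fit
#'
#' @param x A `game_fit`.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`fi`, `fe`, `slope`):
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.game_fit <- function(x, ...) {
  est <- c(fi = x$fi_hat, fe = x$fe_hat, slope = x$slope)
  tibble(
    term = names(est),
    estimate = unname(est),
    conf.low = if (!is.null(x$ci)) x$ci[1, names(est)] else NA_real_,
    conf.high = if (!is.null(x$ci)) x$ci[2, names(est)] else NA_real_
  )
}

#' @export
glance.game_fit <- function(x, ...) {
  tibble(
    fi_hat = x$fi_hat, fe_hat = x$fe_hat, slope = x$slope,
    r_squared = x$r_squared, p_value_slope = x$p_value_slope,
    positive_interaction = x$positive_interaction,
    ref_rate = x$ref_rate, n_wells = x$n_wells, bootstrap = x$bootstrap
  )
}
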