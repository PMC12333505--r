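#' Wright-Fisher run configuration
#'
#' Parameters of the lineage-tracking Wright-Fisher simulator. The
#' population has constant size `N`; each generation every ancestor mutates
#' with probability `mu` (new mutants found their own lineage of size 1 with
#' fresh fitness draws), then the whole population is resampled
#' multinomially with weights proportional to fitness. Mutant fitness is
#' evaluated at the ancestor fraction after mutation; the ancestor's fitness
#' is the constant 1.
#'
#' @param N Population size.
#' @param mu Per-individual, per-generation mutation probability in `[0, 1)`.
#' @param generations Number of generations to simulate.
#' @param fc Minimum fitness cost; sets the default DFE to uniform on
#'   `[0, 1 - fc]`.
#' @param dee [effect_dist] for ecological fitness (DEE). The default,
#'   uniform on `[0, 0.999]`, keeps `fmax` strictly below 1 as required by
#'   the closed-form results; supports extending above 1 are allowed and
#'   produce stable mutant-ancestor coexistence.
#' @param dfe [effect_dist] for intrinsic fitness (DFE); support must lie in
#'   `[0, 1)`.
#' @param burn_in Generations excluded from stationary summaries.
#' @param replicates Default number of replicates for [wf_replicates()].
#' @param seed Default RNG seed.
#' @return An object of class `wf_params`.
#' @export
wf_params <- function(N, mu, generations, fc = 0,
                      dee = effect_dist_uniform(0, 0.999),
                      dfe = dfe_uniform(fc),
                      burn_in = 0L, replicates = 1L, seed = 1L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) abort("`N` must be a positive integer.")
  if (!is.finite(mu) || mu < 0 || mu >= 1) abort("`mu` must lie in [0, 1).")
  generations <- as.integer(generations)
  burn_in <- as.integer(burn_in)
  if (burn_in >= generations) abort("`burn_in` must be smaller than `generations`.")
  if (!is.finite(fc) || fc < 0 || fc >= 1) abort("`fc` must lie in [0, 1).")
  stopifnot(inherits(dee, "effect_dist"), inherits(dfe, "effect_dist"))
  if (dfe$hi > 1 || dfe$lo < 0) abort("DFE support must lie within [0, 1].")
  if (dee$lo < 0) abort("DEE support must be nonnegative.")
  structure(
    list(N = N, mu = mu, generations = generations, fc = fc,
         dee = dee, dfe = dfe, burn_in = burn_in,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "wf_params"
  )
}

#' @export
print.wf_params <- function(x, ...) {
  cat(sprintf(
    "<wf_params> N = %d, mu = %.3g, %d generations (burn-in %d), fc = %.3g\n",
    x$N, x$mu, x$generations, x$burn_in, x$fc
  ))
  cat("  DFE: "); print(x$dfe)
  cat("  DEE: "); print(x$dee)
  invisible(x)
}

#' Run the lineage-tracking Wright-Fisher simulator
#'
#' @param params A [wf_params()].
#' @param seed RNG seed (defaults to `params$seed`). Identical parameters and
#'   seed give identical results.
#' @param record_lineages Record every emerged lineage (id, fitness values,
#'   birth generation, extinction time)? Turn off for long stationary runs
#'   where only the accumulated summaries are needed.
#' @param totals_every Record per-generation totals every this many
#'   generations (0 = never).
#' @param fe_breaks,fi_breaks Bin edges for the stationary fitness
#'   histograms accumulated over post-burn-in generations (mutant
#'   individuals per bin, averaged over generations). Defaults to 50 equal
#'   bins over the corresponding support.
#' @param init Optional initial mutant clone, a list
#'   `list(count =, fi =, fe =)`, seeded at generation 0 (used e.g. to study
#'   coexistence fixed points with `mu = 0`).
#' @param stop_on_absorption With `mu = 0`, stop as soon as mutants are
#'   extinct or fixed.
#' @return An object of class `wf_result`: list with `lineages` (tibble:
#'   `lineage_id`, `fi`, `fe`, `cost`, `birth_generation`, `tau`,
#'   `censored`), `totals` (tibble: `generation`, `ancestor`, `mutants`),
#'   `stationary` (accumulated histograms and moments), `params`, `seed`.
#'   A mutant that leaves no offspring in its first selection step has
#'   `tau = 0`; lineages alive at the end are `censored` with `tau = NA`.
#' @export
wf_run <- function(params, seed = params$seed, record_lineages = TRUE,
                   totals_every = 1L, fe_breaks = NULL, fi_breaks = NULL,
                   init = NULL, stop_on_absorption = FALSE) {
  stopifnot(inherits(params, "wf_params"))
  if (is.null(fe_breaks)) {
    fe_breaks <- seq(params$dee$lo, params$dee$hi, length.out = 51L)
  }
  if (is.null(fi_breaks)) {
    fi_breaks <- seq(params$dfe$lo, params$dfe$hi, length.out = 51L)
  }
  init_count <- 0L; init_fi <- 0; init_fe <- 0
  if (!is.null(init)) {
    init_count <- as.integer(init$count)
    init_fi <- init$fi; init_fe <- init$fe
  }
  set.seed(seed)
  raw <- wf_sim_cpp(
    params$N, params$mu, params$generations, params$burn_in,
    dist_to_cpp(params$dfe), dist_to_cpp(params$dee),
    fe_breaks, fi_breaks,
    record_lineages, as.integer(totals_every),
    init_count, init_fi, init_fe, stop_on_absorption
  )
  lineages <- tibble(
    lineage_id = raw$lineage_id,
    fi = raw$fi, fe = raw$fe, cost = 1 - raw$fi,
    birth_generation = raw$birth,
    tau = raw$tau,
    censored = is.na(raw$tau)
  ) %>% arrange(.data$lineage_id)
  n_post <- raw$n_post
  mean_mut <- if (n_post > 0) raw$sum_mut / n_post else NA_real_
  var_mut <- if (n_post > 1) {
    (raw$sumsq_mut - n_post * mean_mut^2) / (n_post - 1)
  } else NA_real_
  out <- list(
    lineages = lineages,
    totals = tibble(
      generation = raw$totals_gen,
      ancestor = raw$totals_anc,
      mutants = raw$totals_mut
    ),
    stationary = list(
      fe_breaks = fe_breaks, fe_hist = raw$fe_hist,
      fi_breaks = fi_breaks, fi_hist = raw$fi_hist,
      n_post = n_post, mean_mutants = mean_mut, var_mutants = var_mut,
      half_means = c(raw$h1_mean, raw$h2_mean),
      half_n = c(raw$h1_n, raw$h2_n)
    ),
    n_lineages_total = raw$n_lineages_total,
    n_censored = raw$n_censored,
    final_ancestor = raw$final_ancestor,
    gens_run = raw$gens_run,
    params = params, seed = seed
  )
  class(out) <- "wf_result"
  out
}

#' @export
print.wf_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<wf_result> N = %d, mu = %.3g, %d generations run (seed %d)\n",
      "  %d lineages emerged, %d censored at run end\n"
    ),
    x$params$N, x$params$mu, x$gens_run, x$seed,
    x$n_lineages_total, x$n_censored
  ))
  if (x$stationary$n_post > 0) {
    cat(sprintf("  post-burn-in mean mutant count: %.4g (%g generations)\n",
                x$stationary$mean_mutants, x$stationary$n_post))
  }
  invisible(x)
}

#' @export
tidy.wf_result <- function(x, ...) x$lineages

#' @export
glance.wf_result <- function(x, ...) {
  tibble(
    N = x$params$N, mu = x$params$mu, generations = x$gens_run,
    burn_in = x$params$burn_in, seed = x$seed,
    n_lineages = x$n_lineages_total, n_censored = x$n_censored,
    mean_mutants = x$stationary$mean_mutants
  )
}

#' Mean extinction time binned by ecological fitness
#'
#' Censored lineages (still alive at the end of the run) are excluded from
#' the means and reported per bin; empty bins are reported as missing.
#'
#' @param x A `wf_result` or a lineage tibble with columns `fe`, `tau`,
#'   `censored`.
#' @param breaks Bin edges over `fe` (half-open bins `[lo, hi)`).
#' @return A tibble with `bin_lo`, `bin_hi`, `fe_mid`, `mean_tau`, `se_tau`,
#'   `n`, `n_censored`.
#' @export
wf_extinction_curve <- function(x, breaks = seq(0, 1, length.out = 51L)) {
  lin <- if (inherits(x, "wf_result")) x$lineages else as_tibble(x)
  stopifnot(all(c("fe", "tau", "censored") %in% names(lin)))
  nb <- length(breaks) - 1L
  bin <- findInterval(lin$fe, breaks, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= nb & lin$fe < breaks[nb + 1L]
  lin <- lin[keep, ]; bin <- bin[keep]
  per <- tibble(bin = bin, tau = lin$tau, censored = lin$censored) %>%
    group_by(.data$bin) %>%
    summarise(
      mean_tau = mean(.data$tau[!.data$censored]),
      se_tau = sd(.data$tau[!.data$censored]) /
        sqrt(max(1L, sum(!.data$censored))),
      n = sum(!.data$censored),
      n_censored = sum(.data$censored),
      .groups = "drop"
    )
  tibble(bin = seq_len(nb),
         bin_lo = breaks[-(nb + 1L)], bin_hi = breaks[-1L],
         fe_mid = (breaks[-(nb + 1L)] + breaks[-1L]) / 2) %>%
    left_join(per, by = "bin") %>%
    select(-"bin")
}

#' Stationary distribution of mutant fitness
#'
#' Average number of mutant individuals per fitness bin over post-burn-in
#' generations, from the histogram accumulated during the run, with a
#' normalised density for comparison against the closed-form stationary
#' distribution. A stationarity sanity check compares the first- and
#' second-half post-burn-in mean mutant counts: they should differ by less
#' than 3 standard errors (batch-means SE over 20 batches of the recorded
#' totals when available); failure attaches a warning flag, not an error.
#'
#' @param x A `wf_result`.
#' @param which `"fe"` (default) or `"fi"`.
#' @param weight `"individuals"` (default): average number of mutant
#'   individuals per generation in each bin, the weighting under which the
#'   closed-form stationary density is derived. `"lineages"`: each emerged
#'   lineage counts once regardless of size or lifespan (requires
#'   `record_lineages = TRUE`).
#' @return A tibble with `bin_lo`, `bin_hi`, `mid`, `mean_count` (mutant
#'   individuals per generation in the bin) and `density` (normalised per
#'   unit fitness); attributes `stationary_ok` and `mean_mutants`.
#' @export
wf_stationary_fe <- function(x, which = c("fe", "fi"),
                             weight = c("individuals", "lineages")) {
  stopifnot(inherits(x, "wf_result"))
  which <- match.arg(which)
  weight <- match.arg(weight)
  st <- x$stationary
  if (st$n_post <= 0) abort("No post-burn-in generations were accumulated.")
  breaks <- if (which == "fe") st$fe_breaks else st$fi_breaks
  hist <- if (which == "fe") st$fe_hist else st$fi_hist
  if (weight == "lineages") {
    if (!nrow(x$lineages)) {
      abort("By-lineage weighting needs a run with `record_lineages = TRUE`.")
    }
    vals <- x$lineages[[which]]
    vals <- vals[x$lineages$birth_generation > x$params$burn_in]
    hist <- vapply(seq_len(length(breaks) - 1L), function(i) {
      sum(vals >= breaks[i] & vals < breaks[i + 1L])
    }, numeric(1))
  }
  nb <- length(breaks) - 1L
  mean_count <- hist / st$n_post
  width <- diff(breaks)
  dens <- mean_count / sum(mean_count) / width
  ok <- TRUE
  tot <- x$totals
  post <- tot[tot$generation > x$params$burn_in, ]
  if (nrow(post) >= 40L) {
    # batch means absorb autocorrelation; each half holds nb_batch/2 batches
    nb_batch <- 20L
    bm <- tapply(post$mutants, cut(seq_len(nrow(post)), nb_batch, labels = FALSE), mean)
    se_diff <- sd(bm) * sqrt(2 / (nb_batch / 2))
    ok <- abs(st$half_means[1] - st$half_means[2]) < 3 * se_diff
  } else if (all(is.finite(st$half_means))) {
    se_diff <- sqrt(2 * st$var_mutants / (st$n_post / 2))
    ok <- abs(st$half_means[1] - st$half_means[2]) < 3 * se_diff
  }
  if (!isTRUE(ok)) {
    warn("Stationarity check failed: first/second half mutant means differ by > 3 SE.")
  }
  out <- tibble(
    bin_lo = breaks[-(nb + 1L)], bin_hi = breaks[-1L],
    mid = (breaks[-(nb + 1L)] + breaks[-1L]) / 2,
    mean_count = mean_count, density = dens
  )
  attr(out, "stationary_ok") <- isTRUE(ok)
  attr(out, "mean_mutants") <- st$mean_mutants
  out
}

#' Replicated Wright-Fisher runs
#'
#' Runs `replicates` independent simulations with per-replicate child seeds
#' derived from `seed` (see [child_seeds()]) and pools the stationary
#' summaries.
#'
#' @param params A [wf_params()].
#' @param replicates Number of replicates (default `params$replicates`).
#' @param seed Master seed (default `params$seed`).
#' @param record_lineages,totals_every,fe_breaks Passed to [wf_run()].
#' @return An object of class `wf_replicates`: `runs` (one-row-per-replicate
#'   tibble with the post-burn-in mean mutant count), `fe_hist` (per-bin
#'   mean counts: pooled mean and across-replicate SE), `lineages` (bound
#'   lineage tibble with a `replicate` column, if recorded), `params`.
#' @export
wf_replicates <- function(params, replicates = params$replicates,
                          seed = params$seed, record_lineages = FALSE,
                          totals_every = 0L, fe_breaks = NULL) {
  stopifnot(inherits(params, "wf_params"))
  seeds <- child_seeds(seed, replicates)
  runs <- vector("list", replicates)
  hists <- NULL
  lineages <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    res <- wf_run(params, seed = seeds[r], record_lineages = record_lineages,
                  totals_every = totals_every, fe_breaks = fe_breaks)
    runs[[r]] <- tibble(
      replicate = r, seed = seeds[r],
      mean_mutants = res$stationary$mean_mutants,
      n_post = res$stationary$n_post,
      n_lineages = res$n_lineages_total,
      n_censored = res$n_censored
    )
    h <- res$stationary$fe_hist / res$stationary$n_post
    if (is.null(hists)) {
      hists <- matrix(NA_real_, replicates, length(h))
      breaks_used <- res$stationary$fe_breaks
    }
    hists[r, ] <- h
    if (record_lineages) {
      lineages[[r]] <- mutate(res$lineages, replicate = r)
    }
  }
  nb <- ncol(hists)
  out <- list(
    runs = bind_rows(runs),
    fe_hist = tibble(
      bin_lo = breaks_used[-(nb + 1L)], bin_hi = breaks_used[-1L],
      mid = (breaks_used[-(nb + 1L)] + breaks_used[-1L]) / 2,
      mean_count = colMeans(hists),
      se_count = apply(hists, 2, sd) / sqrt(replicates)
    ),
    lineages = if (record_lineages) bind_rows(lineages) else NULL,
    params = params, seed = seed, replicates = replicates
  )
  class(out) <- "wf_replicates"
  out
}

#' @export
print.wf_replicates <- function(x, ...) {
  cat(sprintf(
    "<wf_replicates> %d replicates of N = %d, mu = %.3g\n  mean mutant count %.4g (SE %.3g)\n",
    x$replicates, x$params$N, x$params$mu,
    mean(x$runs$mean_mutants), sd(x$runs$mean_mutants) / sqrt(x$replicates)
  ))
  invisible(x)
}

#' Fixation probability of a single mutant clone under Wright-Fisher
#'
#' Replicated two-type runs (no mutation) until absorption; used to check
#' the simulator against the Moran/diffusion fixation probabilities (e.g.
#' `s0 / N` in the neutral case).
#'
#' @param N Population size.
#' @param profile A [fitness_profile()].
#' @param s0 Initial mutant count.
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @param max_gen Per-replicate cap on generations (censored if reached).
#' @return One-row tibble with `p_fix`, `se`, `n_fix`, `n_ext`, `n_censored`.
#' @export
wf_fixation_prob <- function(N, profile, s0 = 1L, reps = 10000L, seed = 1L,
                             max_gen = 50L * N) {
  stopifnot(inherits(profile, "fitness_profile"))
  set.seed(seed)
  raw <- wf_two_type_cpp(as.integer(N), profile$fi, profile$fe,
                         as.integer(s0), as.integer(reps),
                         as.integer(max_gen))
  p <- raw$n_fix / reps
  tibble(
    p_fix = p, se = sqrt(p * (1 - p) / reps),
    n_fix = raw$n_fix, n_ext = raw$n_ext, n_censored = raw$n_censored
  )
}
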