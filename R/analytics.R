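#' Closed-form mean extinction time of a mutant lineage
#'
#' Approximate mean extinction time (in generations) of a newly emerged
#' mutant lineage under Wright-Fisher dynamics, as a function of its
#' ecological fitness only:
#' \deqn{\tau(f_e) \approx \frac{3\ln(1-f_e)}{f_e^2 - 3}.}
#' The approximation is independent of population size, mutation rate and
#' fitness cost (for small mutant fractions), is `~ fe` as `fe -> 0`, and
#' diverges as `fe -> 1`. It is invalid for `fe >= 1`, where a mutant can
#' coexist stably with the ancestor instead of going extinct.
#'
#' @param fe Ecological fitness, in `[0, 1)`. Vectorised.
#' @return Mean extinction time in generations.
#' @examples
#' tau_approx(c(0, 0.5, 0.99))
#' @export
tau_approx <- function(fe) {
  if (any(!is.finite(fe)) || any(fe < 0 | fe >= 1)) {
    abort("`fe` must lie in [0, 1); the approximation is invalid at or above 1.")
  }
  3 * log(1 - fe) / (fe^2 - 3)
}

#' Expected number of mutants without ecological interactions
#'
#' Mean number of resistance-conferring mutants maintained at
#' mutation-selection balance when a mutant's growth rate is its intrinsic
#' fitness alone (`fi` drawn uniformly on `[0, 1 - fc]`):
#' \deqn{N_{mut}^{noeco} = N\mu\left(\frac{-\ln f_c}{1-f_c} - 1\right).}
#'
#' @param N Population size.
#' @param mu Mutation probability per individual per generation, in `(0, 1)`.
#' @param fc Minimum fitness cost, in `(0, 1]`; the expression diverges as
#'   `fc -> 0` and tends to 0 as `fc -> 1`.
#' @return Expected mutant count. Vectorised elementwise.
#' @export
n_mut_noeco <- function(N, mu, fc) {
  if (any(!is.finite(fc)) || any(fc <= 0 | fc > 1)) {
    abort("`fc` must lie in (0, 1]: the mutant number diverges as fc -> 0.")
  }
  if (any(mu <= 0 | mu >= 1)) abort("`mu` must lie in (0, 1).")
  ratio <- ifelse(fc == 1, 1, -log(fc) / (1 - fc)) # L'Hopital limit at fc = 1
  N * mu * (ratio - 1)
}

#' Expected number of mutants with ecological interactions, small-mu form
#'
#' For small mutation rate, the expected mutant count with
#' frequency-dependent ecology and a uniform DEE on `[0, fmax]`:
#' \deqn{N_{mut}^{eco} \approx N\mu\left(\frac{-\ln(1-f_{max})}{f_{max}} - 1\right).}
#' Substituting `fmax = 1 - fc` recovers [n_mut_noeco()] exactly. The ratio
#' of the two is independent of `N mu`. This form breaks down as `mu` grows;
#' see [n_mut_eco()].
#'
#' @param N Population size.
#' @param mu Mutation probability; a warning is issued above `1e-3`.
#' @param fmax Upper DEE support, in `(0, 1)`; it can approach but never
#'   equal 1 for a well-defined normalisation.
#' @return Expected mutant count. Vectorised elementwise.
#' @export
n_mut_eco_small_mu <- function(N, mu, fmax) {
  if (any(!is.finite(fmax)) || any(fmax <= 0 | fmax >= 1)) {
    abort("`fmax` must lie in (0, 1).")
  }
  if (any(mu <= 0 | mu >= 1)) abort("`mu` must lie in (0, 1).")
  if (any(mu > 1e-3)) {
    warn("`n_mut_eco_small_mu()` assumes mu << 1; use n_mut_eco() for mu > 1e-3.")
  }
  N * mu * (-log(1 - fmax) / fmax - 1)
}

# Principal-branch Lambert W given the *logarithm* of its argument: solves
# w * exp(w) = exp(rho) for w > 0, working throughout in u = log(w) so that
# arguments far beyond double range (rho ~ 1e6 arises at small mu) are fine.
# In u the equation is exp(u) + u = rho, whose left side is convex and
# strictly increasing, so Newton converges globally: after one step the
# iterate is an upper bound of the root and decreases monotonically.
# (pracma::lambertWp implements the same branch but its Halley loop can
# oscillate forever for some arguments, e.g. x ~ 1.256e8; it is used as an
# independent cross-check in the tests, not here.)
lambert_w0_log <- function(rho) {
  vapply(rho, function(r) {
    u <- if (r > 1) log(r) else r - 1 # start below/near the root
    for (i in 1:200) {
      eu <- exp(u)
      delta <- (eu + u - r) / (eu + 1)
      u <- u - delta
      if (abs(delta) < 1e-15 * max(1, abs(u))) break
    }
    exp(u)
  }, numeric(1))
}

#' Expected number of mutants with ecological interactions
#'
#' Mutation-selection balance for the expected number of mutant individuals
#' with frequency-dependent ecology (uniform DEE on `[0, fmax]`, intrinsic
#' fitness uniform on `[0, 1 - fc]`), valid across several decades of `mu`.
#' The mean mutant fraction `m` solves the balance
#' \deqn{\frac{f_{max}}{\mu} m + f_{max} = -\ln(1 - f_{max} + m g),}
#' where `g = fc^{fc/(fc-1)}/e` is the geometric mean of `1 - fi`; the
#' right-hand side is the lifetime factor of the surviving mutants and the
#' `m g` term the crowding/mean-fitness feedback through the ancestor
#' fraction. The solution in closed form uses the principal Lambert W
#' branch: with `b = fmax/(mu g)`,
#' \deqn{m = \frac{W\!\big(b\, e^{b(1-f_{max})-f_{max}}\big)/b - (1-f_{max})}{g}.}
#' As `mu -> 0` this reduces to [n_mut_eco_small_mu()]; by
#' default the small-mu form is used below `mu = 1e-6`, where the two agree
#' to well under 1%.
#'
#' @param N Population size.
#' @param mu Mutation probability, in `(0, 0.1]`.
#' @param fc Minimum fitness cost, in `(0, 1)`.
#' @param fmax Upper DEE support, in `(0, 1)`.
#' @param method `"auto"` (Lambert-W form, small-mu form below `mu = 1e-6`),
#'   `"lambert"`, or `"small_mu"`.
#' @return Expected mutant count. Vectorised elementwise.
#' @export
n_mut_eco <- function(N, mu, fc, fmax, method = c("auto", "lambert", "small_mu")) {
  method <- match.arg(method)
  if (any(!is.finite(fc)) || any(fc <= 0 | fc >= 1)) abort("`fc` must lie in (0, 1).")
  if (any(!is.finite(fmax)) || any(fmax <= 0 | fmax >= 1)) abort("`fmax` must lie in (0, 1).")
  if (any(!is.finite(mu)) || any(mu <= 0 | mu > 0.1)) abort("`mu` must lie in (0, 0.1].")
  n <- max(length(N), length(mu), length(fc), length(fmax))
  N <- rep_len(N, n); mu <- rep_len(mu, n)
  fc <- rep_len(fc, n); fmax <- rep_len(fmax, n)
  use_small <- switch(method,
    auto = mu < 1e-6,
    lambert = rep(FALSE, n),
    small_mu = rep(TRUE, n)
  )
  out <- numeric(n)
  if (any(use_small)) {
    out[use_small] <- N[use_small] * mu[use_small] *
      (-log(1 - fmax[use_small]) / fmax[use_small] - 1)
  }
  if (any(!use_small)) {
    i <- !use_small
    g <- fc[i]^(fc[i] / (fc[i] - 1)) / exp(1)
    b <- fmax[i] / (mu[i] * g)
    rho <- log(b) + b * (1 - fmax[i]) - fmax[i]
    W <- lambert_w0_log(rho)
    if (any(!is.finite(W) | W <= 0)) {
      abort("Lambert W evaluation failed: argument outside the principal-branch domain.")
    }
    m <- (W / b - (1 - fmax[i])) / g
    out[i] <- N[i] * m
  }
  out
}

#' Stationary density of mutant ecological fitness
#'
#' Expected mutant-individual fraction density at ecological fitness `fe`
#' under mutation-selection balance with DEE density `rho0`:
#' \deqn{P(f_e) \approx \frac{f_e\,\mu}{1-f_e}\,\rho_0(f_e),}
#' the balance of the rate `fe mu rho0(fe)` at which mutants with fitness
#' `fe` arise and survive against the rate `(1 - fe)` at which existing ones
#' are lost. For a uniform DEE on `[0, fmax]` this is
#' `mu fe / (fmax (1 - fe))`, and its integral over `[0, fmax]` equals
#' [n_mut_eco_small_mu()] divided by `N`.
#'
#' @param fe Ecological fitness values in `[0, 1)`. Vectorised.
#' @param mu Mutation probability.
#' @param dee [effect_dist] giving `rho0` (default uniform on `[0, 0.999]`).
#' @return Density of expected mutant fraction per unit `fe`.
#' @export
stationary_density <- function(fe, mu, dee = effect_dist_uniform(0, 0.999)) {
  stopifnot(inherits(dee, "effect_dist"))
  if (any(!is.finite(fe)) || any(fe < 0 | fe >= 1)) {
    abort("`fe` must lie in [0, 1).")
  }
  fe * mu / (1 - fe) * dist_density(dee, fe)
}

#' Classify the preexisting-resistance regime
#'
#' Compares the expected mutant numbers with and without ecological
#' interactions against 1 (the threshold above which resistance is expected
#' to preexist at the start of treatment):
#' * `small-Nmu` - both below 1: mutational supply too small either way;
#' * `rare-mutant` - only the ecological count exceeds 1: preexistence is
#'   driven by rare mutants with strong positive ecological interactions;
#' * `many-mutant` - both exceed 1: mutants are common regardless, but
#'   ecology still reshapes their fitness distribution.
#'
#' For `fmax >= 1 - fc` the ecological count is never the smaller one, so
#' the fourth combination cannot occur (asserted).
#'
#' @param N Population size.
#' @param mu Mutation probability.
#' @param fc Minimum fitness cost.
#' @param fmax Upper DEE support.
#' @return A one-row tibble: `N`, `mu`, `fc`, `fmax`, `n_mut_noeco`,
#'   `n_mut_eco`, `regime`.
#' @export
classify_regime <- function(N, mu, fc, fmax) {
  n <- max(length(N), length(mu), length(fc), length(fmax))
  N <- rep_len(N, n); mu <- rep_len(mu, n)
  fc <- rep_len(fc, n); fmax <- rep_len(fmax, n)
  noeco <- n_mut_noeco(N, mu, fc)
  eco <- n_mut_eco(N, mu, fc, fmax)
  bad <- noeco > 1 & eco <= 1
  if (any(bad & fmax >= 1 - fc)) {
    abort("Internal inconsistency: n_mut_noeco > 1 > n_mut_eco with fmax >= 1 - fc.")
  }
  if (any(bad)) {
    warn("fmax < 1 - fc: ecology suppresses the mutant count below 1; labelled small-Nmu.")
  }
  regime <- dplyr::case_when(
    eco > 1 & noeco > 1 ~ "many-mutant",
    eco > 1 ~ "rare-mutant",
    .default = "small-Nmu"
  )
  tibble(N = N, mu = mu, fc = fc, fmax = fmax,
         n_mut_noeco = noeco, n_mut_eco = eco, regime = regime)
}

#' Phase diagram of preexistence regimes
#'
#' Evaluates [classify_regime()] over a grid of `N mu` against either `fc`
#' or `fmax`, reproducing the structure of the three-regime phase diagram.
#'
#' @param Nmu Vector of `N * mu` values.
#' @param fc Vector of fitness costs (held at `fc[1]` when varying `fmax`).
#' @param fmax Vector of upper DEE supports (held at `fmax[1]` when varying
#'   `fc`).
#' @param vary Which axis varies: `"fc"` or `"fmax"`.
#' @param N Population size used to factor `Nmu` into `N` and `mu` (the
#'   classification depends on `mu` itself only weakly through the
#'   Lambert-W form).
#' @return A tibble over the grid with counts and regime labels.
#' @export
regime_map <- function(Nmu, fc = 0.25, fmax = 0.99, vary = c("fc", "fmax"),
                       N = 1e7) {
  vary <- match.arg(vary)
  grid <- if (vary == "fc") {
    tidyr::expand_grid(Nmu = Nmu, fc = fc, fmax = fmax[1])
  } else {
    tidyr::expand_grid(Nmu = Nmu, fc = fc[1], fmax = fmax)
  }
  res <- classify_regime(N, grid$Nmu / N, grid$fc, grid$fmax)
  mutate(res, Nmu = grid$Nmu, .before = 1)
}

#' Coexistence fixed point between mutant and ancestor
#'
#' A mutant with `fe > 1 > fi` outgrows the ancestor when rare but is
#' outgrown when common, giving a stable mixed equilibrium at the ancestor
#' fraction where the mutant's growth rate equals the ancestor's:
#' \deqn{x^* = \frac{1 - f_i}{f_e - f_i} \in (0, 1).}
#' Stability follows from the positive slope `fe - fi > 0`: the mutant
#' grows (fitness > 1) whenever the ancestor fraction exceeds `x*` and
#' shrinks below it. For `fe <= 1` the ancestor wins at every frequency and
#' there is no interior fixed point (extinction is a matter of when, not
#' if); `NA` is returned.
#'
#' @param profile A [fitness_profile()].
#' @return The equilibrium ancestor fraction, or `NA_real_` when `fe <= 1`.
#' @examples
#' coexistence_fixed_point(fitness_profile(0.8, 1.1)) # 2/3
#' @export
coexistence_fixed_point <- function(profile) {
  stopifnot(inherits(profile, "fitness_profile"))
  if (profile$fe <= 1) return(NA_real_)
  (1 - profile$fi) / (profile$fe - profile$fi)
}
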