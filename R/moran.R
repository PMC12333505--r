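#' Specification of the generalized Moran birth-death process
#'
#' A two-type Moran process on states `s = 0, ..., N` (mutant count), with
#' no mutation, so `s = 0` (extinction) and `s = N` (fixation) are
#' absorbing. The mutant's payoff against the ancestor is frequency
#' dependent through the 2x2 game with entries
#' (mutant vs mutant) = `1 - fc`, (mutant vs ancestor) = `fe`, and ancestor
#' payoff 1 against both.
#'
#' @param N Total population size (integer, `>= 2`).
#' @param fc Mutant fitness cost, in `[0, 1)`.
#' @param fe Mutant ecological fitness, `>= 0`.
#' @param s0 Initial mutant count, `0 <= s0 <= N`.
#' @return An object of class `moran_spec`.
#' @examples
#' spec <- moran_spec(N = 100, fc = 0.25, fe = 1.0)
#' moran_absorption(spec)
#' @export
moran_spec <- function(N, fc, fe, s0 = 1L) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) abort("`N` must be an integer >= 2.")
  if (!is.finite(fc) || fc < 0 || fc >= 1) abort("`fc` must lie in [0, 1).")
  if (!is.finite(fe) || fe < 0) abort("`fe` must be nonnegative.")
  s0 <- as.integer(s0)
  if (is.na(s0) || s0 < 0L || s0 > N) abort("`s0` must satisfy 0 <= s0 <= N.")
  structure(list(N = N, fc = fc, fe = fe, s0 = s0), class = "moran_spec")
}

#' @export
print.moran_spec <- function(x, ...) {
  cat(sprintf("<moran_spec> N = %d, fc = %.4g, fe = %.4g, s0 = %d\n",
              x$N, x$fc, x$fe, x$s0))
  invisible(x)
}

#' Expected payoffs in a population with s mutants
#'
#' Self-interaction is excluded: a focal mutant among `s` mutants meets one
#' of the other `s - 1` mutants (payoff `1 - fc`) or one of the `N - s`
#' ancestors (payoff `fe`), so
#' \deqn{P_R(s) = \frac{s-1}{N-1}(1-f_c) + \frac{N-s}{N-1} f_e, \qquad P_A = 1.}
#'
#' @param spec A [moran_spec()].
#' @param s Integer vector of mutant counts, each in `1, ..., N - 1`.
#' @return A tibble with columns `s`, `P_R`, `P_A`.
#' @export
moran_payoffs <- function(spec, s) {
  stopifnot(inherits(spec, "moran_spec"))
  if (any(s < 1 | s > spec$N - 1)) {
    abort("`s` must lie in 1, ..., N - 1 (payoffs are undefined at the absorbing states).")
  }
  N <- spec$N
  tibble(
    s = as.integer(s),
    P_R = ((s - 1) / (N - 1)) * (1 - spec$fc) + ((N - s) / (N - 1)) * spec$fe,
    P_A = 1
  )
}

# birth/death/stay probabilities for all states 0..N (vectors of length N+1)
moran_rates <- function(spec) {
  N <- spec$N
  s <- 0:N
  b <- d <- numeric(N + 1)
  idx <- 2:N # s = 1 .. N-1
  si <- s[idx]
  PR <- ((si - 1) / (N - 1)) * (1 - spec$fc) + ((N - si) / (N - 1)) * spec$fe
  tot <- si * PR + (N - si)
  b[idx] <- (si * PR / tot) * ((N - si) / N)
  d[idx] <- ((N - si) / tot) * (si / N)
  list(s = s, b = b, d = d, stay = 1 - b - d)
}

#' Per-event transition probabilities of the Moran chain
#'
#' One event is one birth-death step: an individual is chosen to reproduce
#' with probability proportional to its expected payoff, and an individual
#' chosen uniformly at random dies. `N` events correspond to one generation.
#'
#' @param spec A [moran_spec()].
#' @param s Integer vector of states (default all of `0:N`).
#' @return A tibble with columns `s`, `birth`, `death`, `stay`.
#' @export
moran_transitions <- function(spec, s = 0:spec$N) {
  stopifnot(inherits(spec, "moran_spec"))
  if (any(s < 0 | s > spec$N)) abort("`s` must lie in 0, ..., N.")
  r <- moran_rates(spec)
  i <- s + 1L
  tibble(s = as.integer(s), birth = r$b[i], death = r$d[i], stay = r$stay[i])
}

#' Absorption probabilities of the Moran chain
#'
#' Extinction (`s = 0`) and fixation (`s = N`) probabilities from `s0`, via
#' the standard birth-death ratio formula with
#' `gamma_j = d_j / b_j = 1 / P_R(j)`, evaluated in log space for numerical
#' stability. States `j` with `b_j = 0` (possible when `fe = 0`) are handled
#' as reflecting-from-below limits rather than division errors.
#'
#' @param spec A [moran_spec()].
#' @return A one-row tibble with `p_ext` and `p_fix` (`p_ext + p_fix = 1`).
#' @export
moran_absorption <- function(spec) {
  stopifnot(inherits(spec, "moran_spec"))
  N <- spec$N; s0 <- spec$s0
  if (s0 == 0L) return(tibble(p_ext = 1, p_fix = 0))
  if (s0 == N) return(tibble(p_ext = 0, p_fix = 1))
  r <- moran_rates(spec)
  j <- 1:(N - 1)
  gam <- r$d[j + 1L] / r$b[j + 1L] # = 1 / P_R(j)
  blocked <- !is.finite(gam)
  if (any(blocked)) {
    j0 <- max(j[blocked])
    if (j0 >= s0) return(tibble(p_ext = 1, p_fix = 0))
    # common infinite prefix cancels: restart the products above j0
    gam <- gam[j > j0]
    cl <- cumsum(log(gam))
    lognum <- c(0, cl[seq_len(s0 - j0 - 1)])
    logden <- c(0, cl)
  } else {
    cl <- cumsum(log(gam))
    lognum <- c(0, cl[seq_len(s0 - 1)])
    logden <- c(0, cl)
  }
  m <- max(logden)
  p_fix <- sum(exp(lognum - m)) / sum(exp(logden - m))
  tibble(p_ext = 1 - p_fix, p_fix = p_fix)
}

#' Extinction-time distribution of the Moran chain
#'
#' First-passage probability mass to the extinct state `s = 0`, computed by
#' iterating the transient (tridiagonal) transition structure of the
#' embedded discrete-time chain: a phase-type recursion in which
#' `pmf[t] = P(absorption at 0 exactly at event step t)`. The conditional
#' mean extinction time is also computed exactly from the linear system
#' `(I - Q) u = h` (with `h` the extinction probabilities), and the two are
#' cross-checked.
#'
#' @param spec A [moran_spec()].
#' @param horizon Number of event steps to iterate. `NULL` (default) extends
#'   automatically until at least `1 - 1e-10` of the conditional mass is
#'   captured (capped at 5e6 steps).
#' @param conditioned If `TRUE` (default) the reported `pmf` is conditioned
#'   on extinction (sums to 1 up to truncation); the unconditioned mass is
#'   kept alongside.
#' @return An object of class `moran_extinction`: a list with the pmf tibble
#'   (`step`, `probability`, `unconditioned`), `p_ext`, `p_fix`,
#'   `mean_steps` and `mean_generations` (conditional on extinction, from
#'   the exact linear system), `mean_steps_pmf` (from the truncated pmf),
#'   `captured` (fraction of conditional mass captured) and `truncated`
#'   (TRUE with a warning flag when `captured < 0.999`).
#' @export
moran_extinction <- function(spec, horizon = NULL, conditioned = TRUE) {
  stopifnot(inherits(spec, "moran_spec"))
  N <- spec$N; s0 <- spec$s0
  if (s0 == 0L || s0 == N) {
    abort("`s0` must be a transient state (1 <= s0 <= N - 1).")
  }
  r <- moran_rates(spec)
  idx <- 2:N # transient states s = 1..N-1
  b <- r$b[idx]; d <- r$d[idx]; stay <- r$stay[idx]
  K <- N - 1L

  ab <- moran_absorption(spec)
  # exact conditional mean: (I - Q) u = h, h = extinction prob by state
  h <- vapply(1:K, function(s) {
    moran_absorption(moran_spec(N, spec$fc, spec$fe, s))$p_ext
  }, numeric(1))
  IQ <- diag(1 - stay, K, K)
  for (i in seq_len(K - 1L)) {
    IQ[i, i + 1L] <- -b[i]
    IQ[i + 1L, i] <- -d[i + 1L]
  }
  u <- solve(IQ, h)
  mean_steps <- u[s0] / h[s0]

  auto <- is.null(horizon)
  cap <- if (auto) 5e6 else horizon
  block <- if (auto) max(1000L, as.integer(20 * mean_steps)) else horizon
  v <- numeric(K); v[s0] <- 1
  pmf <- numeric(0)
  target <- ab$p_ext * (1 - 1e-10)
  repeat {
    nsteps <- min(block, cap - length(pmf))
    if (nsteps <= 0L) break
    chunk <- numeric(nsteps)
    for (t in seq_len(nsteps)) {
      chunk[t] <- v[1L] * d[1L]
      v <- v * stay +
        c(0, v[-K] * b[-K]) + # arrivals from below via birth
        c(v[-1L] * d[-1L], 0) # arrivals from above via death
    }
    pmf <- c(pmf, chunk)
    if (!auto || sum(pmf) >= target || length(pmf) >= cap) break
  }
  captured <- sum(pmf) / ab$p_ext
  truncated <- captured < 0.999
  if (truncated) {
    warn(sprintf(
      "Horizon of %d steps captures only %.4f of the conditional extinction mass.",
      length(pmf), captured
    ))
  }
  steps <- seq_along(pmf)
  mean_steps_pmf <- sum(steps * pmf) / sum(pmf)
  out <- list(
    spec = spec,
    pmf = tibble(
      step = steps,
      probability = if (conditioned) pmf / ab$p_ext else pmf,
      unconditioned = pmf
    ),
    conditioned = conditioned,
    p_ext = ab$p_ext, p_fix = ab$p_fix,
    mean_steps = mean_steps,
    mean_generations = mean_steps / N,
    mean_steps_pmf = mean_steps_pmf,
    captured = captured,
    truncated = truncated
  )
  class(out) <- "moran_extinction"
  out
}

#' @export
print.moran_extinction <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<moran_extinction> N = %d, fc = %.3g, fe = %.3g, s0 = %d\n",
      "  p_ext = %.6g, p_fix = %.6g\n",
      "  conditional mean extinction: %.6g events = %.6g generations\n",
      "  pmf: %d steps capturing %.4f%% of conditional mass%s\n"
    ),
    x$spec$N, x$spec$fc, x$spec$fe, x$spec$s0,
    x$p_ext, x$p_fix, x$mean_steps, x$mean_generations,
    nrow(x$pmf), 100 * x$captured,
    if (x$truncated) " [TRUNCATED]" else ""
  ))
  invisible(x)
}

#' @export
tidy.moran_extinction <- function(x, ...) {
  mutate(x$pmf, generations = .data$step / x$spec$N)
}

#' @export
glance.moran_extinction <- function(x, ...) {
  tibble(
    N = x$spec$N, fc = x$spec$fc, fe = x$spec$fe, s0 = x$spec$s0,
    p_ext = x$p_ext, p_fix = x$p_fix,
    mean_steps = x$mean_steps, mean_generations = x$mean_generations,
    captured = x$captured, truncated = x$truncated
  )
}

# standardized third moment of the conditional extinction-time pmf
moran_skewness <- function(x) {
  stopifnot(inherits(x, "moran_extinction"))
  p <- x$pmf$unconditioned / sum(x$pmf$unconditioned)
  t <- x$pmf$step
  m <- sum(t * p)
  v <- sum((t - m)^2 * p)
  sum((t - m)^3 * p) / v^1.5
}
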