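#' Fitness profile of a single mutant
#'
#' A mutant is fully characterised by two dimensionless growth rates measured
#' relative to the ancestor (whose growth rate is the constant 1): the
#' *intrinsic fitness* `fi`, its growth rate in monoculture (ancestor
#' fraction 0), and the *ecological fitness* `fe`, its growth rate in an
#' almost-all-ancestor population (ancestor fraction 1). The *fitness cost*
#' is `1 - fi`. Between the two endpoints the growth rate varies linearly
#' with the ancestor fraction (see [mutant_fitness()]).
#'
#' @param fi Intrinsic fitness, in `[0, 1)`.
#' @param fe Ecological fitness, `>= 0`. Values above 1 describe mutants that
#'   outgrow the ancestor when rare (negative frequency-dependent selection
#'   strong enough to produce a coexistence fixed point).
#' @return An object of class `fitness_profile` with fields `fi`, `fe`, and
#'   the derived `cost = 1 - fi`.
#' @examples
#' p <- fitness_profile(fi = 0.8, fe = 1.0)
#' mutant_fitness(p, ancestor_fraction = c(0, 0.5, 1))
#' @export
fitness_profile <- function(fi, fe) {
  stopifnot(length(fi) == 1L, length(fe) == 1L)
  if (!is.finite(fi) || fi < 0 || fi >= 1) {
    abort("`fi` must lie in [0, 1): the ancestor's growth rate is the reference 1.")
  }
  if (!is.finite(fe) || fe < 0) {
    abort("`fe` must be a finite nonnegative growth rate.")
  }
  structure(list(fi = fi, fe = fe, cost = 1 - fi), class = "fitness_profile")
}

#' @export
print.fitness_profile <- function(x, ...) {
  cat(sprintf(
    "<fitness_profile> fi = %.4g, fe = %.4g (cost = %.4g)\n",
    x$fi, x$fe, x$cost
  ))
  invisible(x)
}

#' Frequency-dependent mutant growth rate
#'
#' The mutant's growth rate interpolates linearly between its intrinsic
#' fitness `fi` (ancestor fraction 0) and its ecological fitness `fe`
#' (ancestor fraction 1):
#' \deqn{f(x) = f_i + (f_e - f_i)\,x,}
#' where `x` is the fraction of the population that is ancestral.
#'
#' @param profile A [fitness_profile()].
#' @param ancestor_fraction Numeric vector of ancestor fractions in `[0, 1]`.
#' @return Numeric vector of growth rates, same length as `ancestor_fraction`.
#' @export
mutant_fitness <- function(profile, ancestor_fraction) {
  stopifnot(inherits(profile, "fitness_profile"))
  x <- ancestor_fraction
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort("`ancestor_fraction` must lie in [0, 1].")
  }
  profile$fi + (profile$fe - profile$fi) * x
}

# ---- Effect distributions (DFE over fi, DEE over fe) ------------------------

new_effect_dist <- function(kind, lo, hi, mean = NA_real_, sd = NA_real_,
                            xs = NULL, ys = NULL) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo || lo < 0) {
    abort("Effect-distribution support must satisfy 0 <= lo < hi.")
  }
  d <- structure(
    list(kind = kind, lo = lo, hi = hi, mean = mean, sd = sd,
         xs = xs, ys = ys),
    class = "effect_dist"
  )
  d$cells <- dist_cells(d)
  d
}

#' Effect distributions for mutant fitness draws
#'
#' Distributions from which newly arising mutants draw their intrinsic
#' fitness (the distribution of fitness effects, DFE) or their ecological
#' fitness (the distribution of ecological effects, DEE). Three kinds are
#' supported: uniform on `[lo, hi]`; Gaussian truncated to `[lo, hi]` and
#' renormalised; and a custom tabulated density, linearly interpolated
#' between the supplied points and renormalised to integrate to 1.
#'
#' The upper support limit of the DEE is `fmax`, the largest ecological
#' fitness a mutant can draw. For the closed-form results `fmax` must be
#' strictly below 1; the simulators also accept supports extending above 1,
#' where mutants can coexist stably with the ancestor.
#'
#' @param lo,hi Support interval (`0 <= lo < hi`).
#' @param mean,sd Location and scale of the untruncated Gaussian.
#' @param x,density Numeric vectors tabulating a density on `[min(x), max(x)]`;
#'   `density` must be nonnegative and not identically zero.
#' @return An object of class `effect_dist`.
#' @examples
#' dee <- effect_dist_gaussian(mean = 0.5, sd = 0.15, lo = 0, hi = 1)
#' integrate(function(z) dist_density(dee, z), 0, 1)$value # 1
#' @name effect_dist
NULL

#' @rdname effect_dist
#' @export
effect_dist_uniform <- function(lo = 0, hi = 0.999) {
  new_effect_dist("uniform", lo, hi)
}

#' @rdname effect_dist
#' @export
effect_dist_gaussian <- function(mean = 0.5, sd = 0.15, lo = 0, hi = 1) {
  if (!is.finite(sd) || sd <= 0) abort("`sd` must be positive.")
  new_effect_dist("gaussian", lo, hi, mean = mean, sd = sd)
}

#' @rdname effect_dist
#' @export
effect_dist_custom <- function(x, density) {
  stopifnot(is.numeric(x), is.numeric(density), length(x) == length(density))
  if (length(x) < 2L) abort("A tabulated density needs at least two points.")
  o <- order(x)
  x <- x[o]; density <- density[o]
  if (any(duplicated(x))) abort("Tabulated `x` values must be distinct.")
  if (any(density < 0) || all(density == 0)) {
    abort("Tabulated density must be nonnegative and not identically zero.")
  }
  # renormalise by the trapezoid rule
  z <- sum(diff(x) * (head(density, -1) + density[-1]) / 2)
  new_effect_dist("custom", min(x), max(x), xs = x, ys = density / z)
}

#' Read a tabulated effect distribution from delimited text
#'
#' Expects two columns (value, density) with a header, tab- or
#' whitespace-delimited; the density is interpolated linearly and
#' renormalised.
#'
#' @param path Path to the file.
#' @return An `effect_dist` of kind `"custom"`.
#' @export
read_effect_dist <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  if (ncol(tab) < 2L) abort("Expected two columns: value and density.")
  effect_dist_custom(tab[[1L]], tab[[2L]])
}

#' @export
print.effect_dist <- function(x, ...) {
  extra <- switch(x$kind,
    gaussian = sprintf(" mean %.3g, sd %.3g (truncated, renormalised)", x$mean, x$sd),
    custom = sprintf(" tabulated at %d points", length(x$xs)),
    ""
  )
  cat(sprintf("<effect_dist> %s on [%.4g, %.4g]%s\n", x$kind, x$lo, x$hi, extra))
  invisible(x)
}

#' Density of an effect distribution
#'
#' @param dist An [effect_dist].
#' @param x Numeric vector of fitness values.
#' @return The density at `x` (0 outside the support).
#' @export
dist_density <- function(dist, x) {
  stopifnot(inherits(dist, "effect_dist"))
  inside <- x >= dist$lo & x <= dist$hi
  out <- numeric(length(x))
  if (!any(inside)) return(out)
  xi <- x[inside]
  out[inside] <- switch(dist$kind,
    uniform = rep(1 / (dist$hi - dist$lo), length(xi)),
    gaussian = dnorm(xi, dist$mean, dist$sd) /
      (pnorm(dist$hi, dist$mean, dist$sd) - pnorm(dist$lo, dist$mean, dist$sd)),
    custom = approx(dist$xs, dist$ys, xout = xi, rule = 2)$y
  )
  out
}

#' Sample from an effect distribution
#'
#' Uses the current R random number generator state, so draws are
#' reproducible under [set.seed()]. The truncated Gaussian is sampled by
#' rejection (exact); custom densities by the cell discretisation described
#' in `dist_cells`.
#'
#' @param dist An [effect_dist].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, all values within the support.
#' @export
dist_sample <- function(dist, n) {
  stopifnot(inherits(dist, "effect_dist"), n >= 0)
  if (n == 0L) return(numeric(0))
  switch(dist$kind,
    uniform = runif(n, dist$lo, dist$hi),
    gaussian = {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- rnorm(2L * (n - length(out)) + 8L, dist$mean, dist$sd)
        out <- c(out, cand[cand >= dist$lo & cand <= dist$hi])
      }
      out[seq_len(n)]
    },
    custom = {
      cells <- dist$cells
      k <- findInterval(runif(n), cells$cum, rightmost.closed = TRUE) + 1L
      lo <- cells$edges[k]
      lo + runif(n) * (cells$edges[k + 1L] - cells$edges[k])
    }
  )
}

# Piecewise-constant discretisation used to sample custom densities (both in
# R and inside the C++ simulator): 4096 equal-width cells, cell mass from the
# trapezoid rule on the interpolated density, uniform within a cell.
dist_cells <- function(dist, n_cells = 4096L) {
  if (dist$kind != "custom") return(NULL)
  edges <- seq(dist$lo, dist$hi, length.out = n_cells + 1L)
  dens <- approx(dist$xs, dist$ys, xout = edges, rule = 2)$y
  mass <- diff(edges) * (head(dens, -1) + dens[-1]) / 2
  mass <- mass / sum(mass)
  list(edges = edges, cum = cumsum(mass)[-n_cells])
}

# Flattened representation handed to the C++ simulator.
dist_to_cpp <- function(dist) {
  kind <- match(dist$kind, c("uniform", "gaussian", "custom")) - 1L
  cells <- dist$cells
  list(
    kind = kind, lo = dist$lo, hi = dist$hi,
    mean = if (is.na(dist$mean)) 0 else dist$mean,
    sd = if (is.na(dist$sd)) 1 else dist$sd,
    edges = if (is.null(cells)) numeric(0) else cells$edges,
    cum = if (is.null(cells)) numeric(0) else c(cells$cum, 1)
  )
}

#' Uniform DFE implied by a minimum fitness cost
#'
#' In the simulators `fc` is the *minimum* fitness cost: each mutant's
#' intrinsic fitness is drawn uniformly on `[0, 1 - fc]`, so its own cost
#' `1 - fi` is at least `fc`.
#'
#' @param fc Minimum fitness cost, in `[0, 1)`.
#' @return A uniform `effect_dist` on `[0, 1 - fc]`.
#' @export
dfe_uniform <- function(fc = 0) {
  if (!is.finite(fc) || fc < 0 || fc >= 1) abort("`fc` must lie in [0, 1).")
  effect_dist_uniform(0, 1 - fc)
}

#' Draw mutant fitness profiles
#'
#' Intrinsic and ecological fitness are drawn independently from the DFE and
#' DEE respectively; nothing in the model couples them at birth.
#'
#' @param n Number of mutants.
#' @param dfe [effect_dist] for intrinsic fitness; support must lie in `[0, 1)`.
#' @param dee [effect_dist] for ecological fitness; support must be nonnegative.
#' @return A tibble with columns `fi`, `fe`, `cost`.
#' @export
draw_mutants <- function(n, dfe = dfe_uniform(0), dee = effect_dist_uniform(0, 1)) {
  stopifnot(inherits(dfe, "effect_dist"), inherits(dee, "effect_dist"))
  if (dfe$hi > 1 || dfe$lo < 0) {
    abort("DFE support must lie within [0, 1]: intrinsic fitness cannot exceed the ancestor's.")
  }
  if (dee$lo < 0) abort("DEE support must be nonnegative.")
  fi <- dist_sample(dfe, n)
  fe <- dist_sample(dee, n)
  tibble(fi = fi, fe = fe, cost = 1 - fi)
}

#' @rdname draw_mutants
#' @export
draw_mutant <- function(dfe = dfe_uniform(0), dee = effect_dist_uniform(0, 1)) {
  d <- draw_mutants(1L, dfe, dee)
  fitness_profile(d$fi, d$fe)
}
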