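#' Deterministic child seeds
#'
#' Expands one master seed into a reproducible stream of per-component
#' seeds: `child_k = (seed * 69069 + k) mod (2^31 - 1)`, so adding
#' replicates never perturbs the seeds of existing ones.
#'
#' @param seed Master seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  base <- (as.numeric(seed) %% 2147483647) * 69069
  as.integer((base + seq_len(n)) %% 2147483647)
}

# ---- run configuration ------------------------------------------------------

# one row per parameter: type ("int", "num", "chr", "lgl"), default (NULL =
# required), and whether it is forwarded to the compute function
config_schemas <- function() {
  list(
    moran = list(
      N = list("int", NULL), fc = list("num", 0.25), fe = list("num", 0.75),
      s0 = list("int", 1L), horizon = list("int", NA_integer_),
      conditioned = list("lgl", TRUE)
    ),
    wf = list(
      N = list("int", NULL), mu = list("num", NULL),
      generations = list("int", NULL), fc = list("num", 0),
      burn_in = list("int", 0L), replicates = list("int", 1L),
      dee_kind = list("chr", "uniform"), dee_lo = list("num", 0),
      dee_hi = list("num", 0.999), dee_mean = list("num", 0.5),
      dee_sd = list("num", 0.15), dee_file = list("chr", NA_character_),
      record_lineages = list("lgl", TRUE), totals_every = list("int", 1L)
    ),
    analytics = list(
      formula = list("chr", NULL), fe = list("num", NA_real_),
      N = list("num", NA_real_), mu = list("num", NA_real_),
      fc = list("num", NA_real_), fmax = list("num", NA_real_),
      fi = list("num", NA_real_)
    ),
    `regime-map` = list(
      Nmu = list("num", NULL), fc = list("num", 0.25),
      fmax = list("num", 0.99), vary = list("chr", "fc")
    ),
    `game-fit` = list(
      data = list("chr", NULL), window_lo = list("num", NA_real_),
      window_hi = list("num", NA_real_), bootstrap = list("int", 1000L)
    ),
    `assay-sim` = list(
      fi = list("num", NULL), fe = list("num", NULL),
      replicates = list("int", 3L), noise_sd = list("num", 0.05),
      n0 = list("num", 1500), ancestor_rate = list("num", 0.03)
    )
  )
}

coerce_param <- function(value, type, key) {
  out <- switch(type,
    int = suppressWarnings(as.integer(value)),
    num = suppressWarnings(as.numeric(value)),
    chr = as.character(value),
    lgl = suppressWarnings(as.logical(value))
  )
  if (length(out) == 0L || (length(out) == length(value) && any(is.na(out) & !is.na(value)))) {
    abort(sprintf("Configuration key `%s` must be of type %s.", key, type))
  }
  out
}

#' Resolve a run configuration
#'
#' Validates a flat key-value parameter set for one subcommand against its
#' schema: unknown keys are rejected by name, missing required keys raise
#' an error, defaults are filled in, and types are coerced with checks.
#'
#' @param subcommand One of `moran`, `wf`, `analytics`, `regime-map`,
#'   `game-fit`, `assay-sim`.
#' @param params Named list of raw parameter values.
#' @param seed Integer seed recorded in the manifest and used for all
#'   randomness.
#' @param outdir Output directory.
#' @return An object of class `run_config`.
#' @export
resolve_config <- function(subcommand, params = list(), seed = 1L,
                           outdir = ".") {
  schemas <- config_schemas()
  if (!subcommand %in% names(schemas)) {
    abort(sprintf("Unknown subcommand `%s`. Known: %s.", subcommand,
                  paste(names(schemas), collapse = ", ")))
  }
  schema <- schemas[[subcommand]]
  unknown <- setdiff(names(params), names(schema))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key%s for `%s`: %s",
                  if (length(unknown) > 1) "s" else "", subcommand,
                  paste0("`", unknown, "`", collapse = ", ")))
  }
  resolved <- list()
  for (key in names(schema)) {
    spec <- schema[[key]]
    if (!is.null(params[[key]])) {
      resolved[[key]] <- coerce_param(params[[key]], spec[[1]], key)
    } else if (!is.null(spec[[2]])) {
      resolved[[key]] <- spec[[2]]
    } else {
      abort(sprintf("Missing required configuration key `%s` for `%s`.",
                    key, subcommand))
    }
  }
  structure(
    list(subcommand = subcommand, params = resolved,
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file must contain a `subcommand` key; all other top-level keys are
#' the flat parameter set (`seed` and `outdir` are honoured as well).
#'
#' @param path YAML file path.
#' @return A `run_config` (see [resolve_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$subcommand)) abort("Config file must name a `subcommand`.")
  sub <- raw$subcommand
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  outdir <- if (!is.null(raw$outdir)) raw$outdir else "."
  raw$subcommand <- NULL; raw$seed <- NULL; raw$outdir <- NULL
  resolve_config(sub, raw, seed = seed, outdir = outdir)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s (seed %d) -> %s\n", x$subcommand, x$seed, x$outdir))
  for (key in names(x$params)) {
    cat(sprintf("  %s: %s\n", key, paste(format(x$params[[key]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write the run manifest
#'
#' Echoes the fully resolved configuration, seed and package version to
#' `manifest.yaml` in the output directory; re-running a manifest
#' reproduces the outputs (bit-for-bit for deterministic paths, exactly for
#' seeded stochastic ones).
#'
#' @param config A `run_config`.
#' @param outdir Output directory (default `config$outdir`).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, outdir = config$outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, "manifest.yaml")
  params <- lapply(config$params, function(v) if (is.na(v[1]) && length(v) == 1L) NULL else v)
  yaml::write_yaml(
    list(
      package = "ecoresist",
      version = as.character(packageVersion("ecoresist")),
      subcommand = config$subcommand,
      seed = config$seed,
      outdir = config$outdir,
      params = params
    ),
    path
  )
  invisible(path)
}

#' Write result files
#'
#' Writes tables as tab-separated text with a header row ("." decimal, no
#' thousands separators; doubles in shortest round-trip notation, which
#' preserves more than 12 significant digits) and summaries as YAML
#' key-value documents.
#'
#' @param x A result object (`moran_extinction`, `wf_result`, `game_fit`,
#'   or a data frame).
#' @param outdir Output directory, created if needed.
#' @param ... Unused.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(x, outdir, ...) UseMethod("write_results")

write_summary_yaml <- function(lst, path) {
  yaml::write_yaml(lapply(lst, function(v) if (is.numeric(v)) unclass(v) else v), path)
  path
}

#' @export
write_results.data.frame <- function(x, outdir, name = "table", ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, paste0(name, ".tsv"))
  readr::write_tsv(x, path)
  invisible(path)
}

#' @export
write_results.moran_extinction <- function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pmf_path <- file.path(outdir, "pmf.tsv")
  readr::write_tsv(x$pmf[, c("step", "probability")], pmf_path)
  sum_path <- write_summary_yaml(as.list(glance(x)), file.path(outdir, "summary.yaml"))
  invisible(c(pmf_path, sum_path))
}

#' @export
write_results.wf_result <- function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  lin_path <- file.path(outdir, "lineages.tsv")
  readr::write_tsv(x$lineages, lin_path)
  paths <- c(paths, lin_path)
  if (nrow(x$totals)) {
    tot_path <- file.path(outdir, "totals.tsv")
    readr::write_tsv(x$totals, tot_path)
    paths <- c(paths, tot_path)
  }
  hist_path <- file.path(outdir, "stationary_fe.tsv")
  readr::write_tsv(wf_stationary_fe(x), hist_path)
  sum_path <- write_summary_yaml(as.list(glance(x)), file.path(outdir, "summary.yaml"))
  invisible(c(paths, hist_path, sum_path))
}

#' @export
write_results.game_fit <- function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rates_path <- file.path(outdir, "rates.tsv")
  readr::write_tsv(x$rates, rates_path)
  fit_path <- file.path(outdir, "fit.tsv")
  readr::write_tsv(tidy(x), fit_path)
  sum_path <- write_summary_yaml(as.list(glance(x)), file.path(outdir, "summary.yaml"))
  invisible(c(rates_path, fit_path, sum_path))
}
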