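#' Default run configuration
#'
#' The full experimental design: twelve patch sizes from 0.04 to 100 m^2,
#' refuge availabilities 5--75% in 5% steps, five replicate trials per
#' prey density, 3600 one-second steps per trial, 100 mg predator and
#' 1 mg prey, 50 maximum-feeding replicates. `scale = "desk"` selects the
#' reduced factorial (five smallest patch sizes, refuge in 10% steps)
#' that reproduces the headline estimates in minutes rather than days.
#'
#' @param scale `"paper"` or `"desk"`.
#' @param seed master seed.
#' @return A named list of class `"run_config"`.
#' @export
default_config <- function(scale = c("desk", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    areas = if (scale == "paper")
      c(0.04, 0.16, 0.64, 1.44, 2.56, 4, 16, 36, 49, 64, 81, 100)
    else c(0.04, 0.16, 0.64, 1.44, 2.56),
    refuge_fractions = if (scale == "paper") seq(0.05, 0.75, by = 0.05)
    else seq(0.05, 0.75, by = 0.10),
    reps = 5L, n_steps = 3600L, step_seconds = 1,
    predator_mass = 100, prey_mass = 1,
    max_feeding_reps = 50L, satiation_frac = 0.9, max_exponent = 24L,
    digestion_model = "proportional",
    e = 0.85, omega = 0.5, temperature = 282.65,
    seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("patchfr run configuration (", x$scale, " scale):\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Write / read a run configuration as a plain key-value file
#'
#' Vectors are comma-separated; the file round-trips losslessly through
#' [read_config()].
#'
#' @param config a [default_config()] list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration list.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    paste0(nm, ": ", paste(config[[nm]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  cfg <- default_config()
  for (p in kv) {
    val <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    template <- cfg[[p[1]]]
    cfg[[p[1]]] <- if (is.character(template) || is.null(template)) val
    else if (is.integer(template)) as.integer(val)
    else as.numeric(val)
  }
  cfg
}

#' Run the complete pipeline: simulate, fit, select, map
#'
#' Executes the three layers in order: (1) replicate non-spatial
#' maximum-feeding trials and the Poisson GLM for `ln(fmax)`; (2) the
#' factorial feeding experiment and the 25-model BIC selection for the
#' habitat scaling of `N0` and `h`; (3) the Rosenzweig-MacArthur
#' coexistence map over the same design. All stage outputs are returned
#' and, if `outdir` is given, also written as CSV files
#' (`trials.csv`, `model_selection.csv`, `coexistence.csv`) plus a
#' `summary.txt` with the fitted coefficients, the seed and the
#' configuration.
#'
#' @param config a [default_config()] list.
#' @param outdir optional output directory (created if missing).
#' @param verbose print stage progress.
#' @return A list of class `"patchfr_run"`: `config`, `max_feeding`
#'   (counts and GLM fit), `trials`, `selection`, `best_fit`,
#'   `hill`, `map`.
#' @export
run_all <- function(config = default_config(), outdir = NULL,
                    verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)

  say("stage 1/3: maximum feeding rate (%d replicates)",
      config$max_feeding_reps)
  cnt <- max_feeding_counts(config$max_feeding_reps, config$n_steps,
                            config$step_seconds, config$predator_mass,
                            config$prey_mass,
                            digestion_model = config$digestion_model)
  mf <- fit_max_feeding(cnt)
  say("  ln(fmax) = %.3f (se %.3f), mean %.2f prey/h",
      mf$ln_fmax, mf$se, mean(cnt))

  say("stage 2/3: factorial feeding experiment (%d areas x %d refuges)",
      length(config$areas), length(config$refuge_fractions))
  trials <- run_experiment(config$areas, config$refuge_fractions,
                           config$reps, fmax_mean = mean(cnt),
                           n_steps = config$n_steps,
                           step_seconds = config$step_seconds,
                           predator_mass = config$predator_mass,
                           prey_mass = config$prey_mass,
                           digestion_model = config$digestion_model,
                           satiation_frac = config$satiation_frac,
                           max_exponent = config$max_exponent,
                           verbose = verbose)
  say("  %d trials; fitting 25 candidate scaling models", nrow(trials))
  sel <- select_scaling_model(trials, mf$ln_fmax)
  best <- sel$best
  ht <- hill_test(best)
  say("  best: %s | Hill %.3f (p vs 1: %.2g)",
      sel$table$model[sel$table$rank == 1], ht$h, ht$p_value)

  say("stage 3/3: coexistence map")
  env <- environment_spec(prey_mass_mg = config$prey_mass,
                          predator_mass_mg = config$predator_mass,
                          temperature = config$temperature)
  map <- coexistence_map(best, config$areas, config$refuge_fractions,
                         e = config$e, omega = config$omega, env = env)

  out <- structure(list(config = config,
                        max_feeding = list(counts = cnt, fit = mf),
                        trials = trials, selection = sel, best_fit = best,
                        hill = ht, map = map), class = "patchfr_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(trials, file.path(outdir, "trials.csv"), row.names = FALSE)
    write.csv(sel$table, file.path(outdir, "model_selection.csv"),
              row.names = FALSE)
    write.csv(map, file.path(outdir, "coexistence.csv"), row.names = FALSE)
    write_config(config, file.path(outdir, "config.txt"))
    sink(file.path(outdir, "summary.txt"))
    on.exit(sink())
    print(out)
  }
  out
}

#' @export
print.patchfr_run <- function(x, ...) {
  cat("patchfr pipeline run (seed ", x$config$seed, ", ",
      x$config$scale, " scale)\n\n", sep = "")
  cat(sprintf("Maximum feeding: mean %.2f prey/h, ln(fmax) = %.3f (se %.3f)\n",
              mean(x$max_feeding$counts), x$max_feeding$fit$ln_fmax,
              x$max_feeding$fit$se))
  cat(sprintf("Feeding trials: %d\n\n", nrow(x$trials)))
  print(summary(x$best_fit))
  cat(sprintf("\nHill exponent: %.3f (p vs 1: %.3g)\n",
              x$hill$h, x$hill$p_value))
  surv <- table(x$map$status)
  cat("\nCoexistence map: ",
      paste(names(surv), surv, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
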