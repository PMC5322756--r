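#' Build a gridded arena with prey refuges
#'
#' The arena is a square grid of 1 cm x 1 cm cells with impenetrable walls.
#' A fixed number of cells, `round(refuge_fraction * n_cells)`, is drawn
#' uniformly without replacement and marked as refuge: individuals move
#' through refuge cells freely but no feeding can take place in them.
#' A fresh refuge mask is drawn on every call.
#'
#' @param area_m2 patch area in m^2; `sqrt(area_m2) * 100` must be a whole
#'   number of cells (all standard patch sizes 0.04--100 m^2 qualify).
#' @param refuge_fraction fraction of cells that are refuges, in `[0, 1]`.
#' @return A list of class `"arena"` with `width_cells`, `height_cells`,
#'   `refuge` (logical vector in row-major cell order), `area_m2`,
#'   `refuge_fraction`.
#' @examples
#' a <- build_arena(0.04, 0.05)
#' sum(a$refuge)  # 20 of 400 cells
#' @export
build_arena <- function(area_m2, refuge_fraction) {
  stopifnot(area_m2 > 0, refuge_fraction >= 0, refuge_fraction <= 1)
  side <- sqrt(area_m2) * 100
  if (abs(side - round(side)) > 1e-8)
    stop("'area_m2' does not resolve to a whole number of 1 cm cells per side")
  side <- as.integer(round(side))
  n_cells <- side * side
  n_ref <- as.integer(round(refuge_fraction * n_cells))
  refuge <- logical(n_cells)
  if (n_ref > 0)
    refuge[sample.int(n_cells, n_ref)] <- TRUE
  structure(list(width_cells = side, height_cells = side, refuge = refuge,
                 area_m2 = area_m2, refuge_fraction = refuge_fraction),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("Arena: %d x %d cells (%.2f m^2), %d refuge cells (%.0f%%)\n",
              x$width_cells, x$height_cells, x$area_m2, sum(x$refuge),
              100 * x$refuge_fraction))
  invisible(x)
}

resolve_digestion <- function(digestion_model) {
  digestion_model <- match.arg(digestion_model, c("proportional", "absolute"))
  if (digestion_model == "proportional") 1L else 0L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Run one spatial feeding trial
#'
#' Simulates a single predator foraging on `prey_count` prey for `n_steps`
#' one-second steps. Each step, all prey take a random-walk step (uniform
#' direction, allometric step length, walls truncate the move); then the
#' predator digests, and -- unless it is handling a previous capture or its
#' gut is at least 60% full -- moves and attacks one prey sharing its cell
#' (refuge cells support no feeding) with the allometric capture
#' probability. Captured prey are replaced at uniform random positions, so
#' the prey density is exactly constant throughout the trial.
#'
#' @param area_m2,refuge_fraction arena design; see [build_arena()].
#' @param prey_count number of prey individuals (>= 1).
#' @param n_steps number of time steps; the default 3600 x 1 s = 1 h.
#' @param step_seconds seconds per step.
#' @param predator_mass,prey_mass body masses in mg.
#' @param constants an [allometric_constants()] object.
#' @param digestion_model `"proportional"` (exponential gut evacuation at
#'   maximum rate D when full; the default) or `"absolute"` (D mg per
#'   second regardless of gut content).
#' @param seed optional integer seed making the trial independently
#'   reproducible; `NULL` uses (and advances) the current RNG stream.
#' @param diagnostics if `TRUE`, attach gut and prey-count bookkeeping.
#' @return A one-row `data.frame` with `area_m2`, `refuge_fraction`,
#'   `prey_count`, `density_per_m2`, `eaten`, and (with
#'   `diagnostics = TRUE`) `final_gut`, `max_gut`, `prey_alive_min`,
#'   `prey_alive_max`.
#' @export
run_feeding_trial <- function(area_m2, refuge_fraction, prey_count,
                              n_steps = 3600L, step_seconds = 1,
                              predator_mass = 100, prey_mass = 1,
                              constants = allometric_constants(),
                              digestion_model = c("proportional", "absolute"),
                              seed = NULL, diagnostics = FALSE) {
  stopifnot(prey_count >= 1, n_steps >= 1)
  dm <- resolve_digestion(digestion_model)
  tr <- compute_traits(predator_mass, prey_mass, constants)
  res <- with_seed(seed, {
    arena <- build_arena(area_m2, refuge_fraction)
    run_trial_cpp(arena$width_cells, arena$height_cells, arena$refuge,
                  as.integer(prey_count), as.integer(n_steps),
                  tr$velocity_pred, tr$velocity_prey,
                  tr$gut_capacity, tr$digestion_rate,
                  as.integer(round(tr$handling_time / step_seconds)),
                  tr$attack_success, prey_mass, step_seconds, dm)
  })
  out <- data.frame(area_m2 = area_m2, refuge_fraction = refuge_fraction,
                    prey_count = prey_count,
                    density_per_m2 = prey_count / area_m2,
                    eaten = res$eaten)
  if (diagnostics) {
    out$final_gut <- res$final_gut
    out$max_gut <- res$max_gut
    out$prey_alive_min <- res$prey_alive_min
    out$prey_alive_max <- res$prey_alive_max
  }
  out
}

#' Run one non-spatial maximum-feeding trial
#'
#' The physiological ceiling on feeding: every step the predator is neither
#' handling nor satiated it encounters a prey with certainty and attacks
#' with the allometric capture probability. Gut, digestion and handling
#' rules are identical to the spatial trial, so the outcome is limited by
#' attack success, handling time and digestion only.
#'
#' @inheritParams run_feeding_trial
#' @return Integer number of prey eaten.
#' @export
run_max_feeding_trial <- function(n_steps = 3600L, step_seconds = 1,
                                  predator_mass = 100, prey_mass = 1,
                                  constants = allometric_constants(),
                                  digestion_model = c("proportional", "absolute"),
                                  seed = NULL) {
  dm <- resolve_digestion(digestion_model)
  tr <- compute_traits(predator_mass, prey_mass, constants)
  with_seed(seed,
    run_max_trial_cpp(as.integer(n_steps), tr$gut_capacity, tr$digestion_rate,
                      as.integer(round(tr$handling_time / step_seconds)),
                      tr$attack_success, prey_mass, step_seconds, dm))
}

#' Estimate the maximum feeding rate by replicate non-spatial trials
#'
#' @param reps number of replicate trials (50 by default).
#' @inheritParams run_feeding_trial
#' @return Integer vector of eaten counts, one per replicate.
#' @export
max_feeding_counts <- function(reps = 50L, n_steps = 3600L, step_seconds = 1,
                               predator_mass = 100, prey_mass = 1,
                               constants = allometric_constants(),
                               digestion_model = c("proportional", "absolute"),
                               seed = NULL) {
  digestion_model <- match.arg(digestion_model)
  with_seed(seed,
    vapply(seq_len(reps), function(i)
      run_max_feeding_trial(n_steps, step_seconds, predator_mass, prey_mass,
                            constants, digestion_model), integer(1)))
}

#' Prey-density ladder for one design point
#'
#' Prey densities are doubled from one prey upward, `2^0, 2^1, ...`, until
#' the predator is satiated: the smallest exponent whose pilot mean feeding
#' (over `pilot_reps` trials) reaches `satiation_frac` of the non-spatial
#' maximum-feeding estimate ends the ladder.
#'
#' @param area_m2,refuge_fraction design point.
#' @param fmax_mean non-spatial maximum feeding estimate (prey per trial);
#'   computed from 50 fresh [run_max_feeding_trial()] replicates if `NULL`.
#' @param pilot_reps replicate trials per pilot density.
#' @param satiation_frac fraction of `fmax_mean` taken as satiation.
#' @param max_exponent safety cap on the ladder exponent.
#' @inheritParams run_feeding_trial
#' @return Integer vector of prey counts `2^0 .. 2^n`.
#' @export
density_ladder <- function(area_m2, refuge_fraction, fmax_mean = NULL,
                           pilot_reps = 5L, satiation_frac = 0.9,
                           max_exponent = 24L, n_steps = 3600L,
                           step_seconds = 1, predator_mass = 100,
                           prey_mass = 1,
                           constants = allometric_constants(),
                           digestion_model = c("proportional", "absolute"),
                           seed = NULL) {
  digestion_model <- match.arg(digestion_model)
  with_seed(seed, {
    if (is.null(fmax_mean))
      fmax_mean <- mean(max_feeding_counts(
        50L, n_steps, step_seconds, predator_mass, prey_mass, constants,
        digestion_model))
    target <- satiation_frac * fmax_mean
    n <- 0L
    repeat {
      eaten <- vapply(seq_len(pilot_reps), function(i)
        run_feeding_trial(area_m2, refuge_fraction, 2^n, n_steps,
                          step_seconds, predator_mass, prey_mass, constants,
                          digestion_model)$eaten, numeric(1))
      if (mean(eaten) >= target || n >= max_exponent) break
      n <- n + 1L
    }
    if (n >= max_exponent)
      warning("density ladder hit the exponent cap before satiation")
    as.integer(2^(0:n))
  })
}

#' Run the full factorial feeding experiment
#'
#' Crosses patch sizes and refuge availabilities; at each design point prey
#' densities are doubled from one prey upward with `reps` replicate trials
#' per density, stopping at satiation (see [density_ladder()]; the
#' replicate trials at each rung are themselves the pilot, so the recorded
#' data and the ladder rule coincide). Every trial draws a fresh refuge
#' mask and gets its own derived seed, recorded in the output.
#'
#' @param areas patch areas in m^2.
#' @param refuge_fractions refuge availabilities (proportions).
#' @param reps replicate trials per density.
#' @param fmax_mean non-spatial maximum-feeding estimate used by the
#'   satiation rule; estimated from 50 fresh trials if `NULL`.
#' @param seed master seed; per-trial seeds are drawn from it and recorded.
#' @param satiation_frac,max_exponent see [density_ladder()].
#' @param verbose print per-design-point progress.
#' @inheritParams run_feeding_trial
#' @return A `data.frame` with one row per trial: `area_m2`,
#'   `refuge_fraction`, `prey_count`, `density_per_m2`, `rep`, `seed`,
#'   `eaten`.
#' @examples
#' \donttest{
#' trials <- run_experiment(c(0.04, 0.16), c(0.05, 0.35), reps = 2,
#'                          seed = 1, verbose = FALSE)
#' }
#' @export
run_experiment <- function(areas, refuge_fractions, reps = 5L,
                           fmax_mean = NULL, n_steps = 3600L,
                           step_seconds = 1, predator_mass = 100,
                           prey_mass = 1,
                           constants = allometric_constants(),
                           digestion_model = c("proportional", "absolute"),
                           satiation_frac = 0.9, max_exponent = 24L,
                           seed = NULL, verbose = FALSE) {
  stopifnot(length(areas) >= 1, length(refuge_fractions) >= 1, reps >= 0)
  digestion_model <- match.arg(digestion_model)
  empty <- data.frame(area_m2 = numeric(), refuge_fraction = numeric(),
                      prey_count = numeric(), density_per_m2 = numeric(),
                      rep = integer(), seed = integer(), eaten = integer())
  if (reps == 0L) return(empty)
  with_seed(seed, {
    if (is.null(fmax_mean))
      fmax_mean <- mean(max_feeding_counts(
        50L, n_steps, step_seconds, predator_mass, prey_mass, constants,
        digestion_model))
    target <- satiation_frac * fmax_mean
    rows <- list()
    for (A in areas) for (R in refuge_fractions) {
      t0 <- proc.time()[["elapsed"]]
      n <- 0L
      repeat {
        for (r in seq_len(reps)) {
          trial_seed <- sample.int(.Machine$integer.max, 1L)
          rec <- run_feeding_trial(A, R, 2^n, n_steps, step_seconds,
                                   predator_mass, prey_mass, constants,
                                   digestion_model, seed = trial_seed)
          rec$rep <- r
          rec$seed <- trial_seed
          rows[[length(rows) + 1L]] <- rec
        }
        last <- do.call(rbind, rows[seq(length(rows) - reps + 1L,
                                        length(rows))])
        if (mean(last$eaten) >= target || n >= max_exponent) break
        n <- n + 1L
      }
      if (verbose)
        message(sprintf(
          "area %.2f m^2, refuge %.0f%%: densities 2^0..2^%d, %.1f s",
          A, 100 * R, n, proc.time()[["elapsed"]] - t0))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("area_m2", "refuge_fraction", "prey_count", "density_per_m2",
            "rep", "seed", "eaten")]
  })
}
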