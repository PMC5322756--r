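#' Environmental and allometric constants for the population model
#'
#' Constants of the empirically derived equations for prey carrying
#' capacity, prey intrinsic growth rate and predator metabolic rate.
#' Defaults describe an invertebrate detritivore prey / invertebrate
#' predator pair under temperate (German) climate and productivity.
#' Note the unit adapters: the carrying-capacity equation takes the prey
#' mass in gram, the growth-rate equation in microgram, the metabolic
#' equation the predator mass in gram -- `prey_mass_mg` and
#' `predator_mass_mg` are converted internally.
#'
#' @param prey_mass_mg,predator_mass_mg body masses in mg.
#' @param temperature environmental temperature T in Kelvin.
#' @param ln_K0,b_K,E_K carrying-capacity intercept (on the log scale),
#'   mass exponent and activation energy (eV).
#' @param sigma0,E_sigma,T0,z net-primary-production constants.
#' @param tl0,tl trophic-level intercept and prey trophic level.
#' @param ln_r0,b_r,E_r growth-rate constants (mass in microgram).
#' @param ln_x0,b_x,E_x metabolic-rate constants (mass in gram).
#' @param sigma_field field-to-basal metabolic multiplier.
#' @param cx_intercept intercept of the J s^-1 to d^-1 metabolic
#'   normalization `c_x = cx_intercept / M_p` (predator mass in mg).
#' @param boltzmann Boltzmann constant in eV K^-1.
#' @return An object of class `"environment_spec"`.
#' @export
environment_spec <- function(prey_mass_mg = 1, predator_mass_mg = 100,
                             temperature = 282.65,
                             ln_K0 = -31.15, b_K = -0.72, E_K = 0.71,
                             sigma0 = 600, E_sigma = -0.35, T0 = 293.15,
                             z = 1.03, tl0 = -2.68, tl = 1.5,
                             ln_r0 = 32.39, b_r = -0.25, E_r = -0.84,
                             ln_x0 = 27.68, b_x = 0.72, E_x = 0.87,
                             sigma_field = 3, cx_intercept = 12342.86,
                             boltzmann = 8.62e-5) {
  stopifnot(temperature > 0, prey_mass_mg > 0, predator_mass_mg > 0)
  structure(as.list(environment()), class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf(
    "Population-model environment: %g mg prey, %g mg predator, T = %g K\n",
    x$prey_mass_mg, x$predator_mass_mg, x$temperature))
  invisible(x)
}

#' Allometric prey carrying capacity
#'
#' \deqn{K = K_0 M_n^{b_K} e^{E_K/(kT)}
#'   \left(\sigma_0 e^{E_\sigma (T_0 - T)/(k T T_0)}\right)^{z}
#'   e^{tl_0 (tl - 1)}}
#' with the prey mass \eqn{M_n} in gram. Units: individuals m^-2.
#'
#' @param env an [environment_spec()].
#' @return Carrying capacity K (prey m^-2).
#' @export
carrying_capacity <- function(env = environment_spec()) {
  Mn_g <- env$prey_mass_mg / 1000
  kT <- env$boltzmann * env$temperature
  npp <- env$sigma0 * exp(env$E_sigma * (env$T0 - env$temperature) /
                            (kT * env$T0))
  exp(env$ln_K0) * Mn_g^env$b_K * exp(env$E_K / kT) * npp^env$z *
    exp(env$tl0 * (env$tl - 1))
}

#' Allometric prey intrinsic growth rate
#'
#' \deqn{r = r_0 M_n^{b_r} e^{E_r/(kT)}} with the prey mass \eqn{M_n} in
#' microgram. Units: d^-1.
#'
#' @param env an [environment_spec()].
#' @return Intrinsic growth rate r (d^-1).
#' @export
growth_rate <- function(env = environment_spec()) {
  Mn_ug <- env$prey_mass_mg * 1000
  exp(env$ln_r0) * Mn_ug^env$b_r *
    exp(env$E_r / (env$boltzmann * env$temperature))
}

#' Allometric predator metabolic rate
#'
#' \deqn{x = \sigma c_x x_0 M_p^{b_x} e^{-E_x/(kT)}} with the predator
#' mass \eqn{M_p} in gram inside the power law and in mg inside the
#' normalization \eqn{c_x = 12342.86/M_p} that converts J s^-1 to d^-1,
#' and \eqn{\sigma} the field-to-basal multiplier. Units: d^-1.
#'
#' @param env an [environment_spec()].
#' @return Metabolic rate x (d^-1).
#' @export
metabolic_rate <- function(env = environment_spec()) {
  Mp_g <- env$predator_mass_mg / 1000
  c_x <- env$cx_intercept / env$predator_mass_mg
  env$sigma_field * c_x * exp(env$ln_x0) * Mp_g^env$b_x *
    exp(-env$E_x / (env$boltzmann * env$temperature))
}

#' Rosenzweig-MacArthur rates for one habitat
#'
#' Combines the allometric rates (K, r, x) with the fitted
#' functional-response parameters into the parameter set of the
#' predator-prey model
#' \deqn{dN/dt = r N (1 - N/K) - \omega \frac{f_{max} N^h}{N_0^h + N^h} P}
#' \deqn{dP/dt = e \omega \frac{f_{max} N^h}{N_0^h + N^h} P - x P.}
#' The maximum feeding rate measured per hour in the feeding trials is
#' converted to d^-1 (x 24); the foraging-time proportion
#' \eqn{\omega = 1/2} (about 12 h foraging per day) then discounts it.
#'
#' @param N0 half-saturation density (prey m^-2).
#' @param h Hill exponent.
#' @param fmax_per_h maximum feeding rate in prey h^-1.
#' @param e assimilation efficiency in (0, 1].
#' @param omega effective foraging-time proportion in (0, 1].
#' @param env an [environment_spec()].
#' @return A list of class `"population_params"` with `r`, `K`, `x`, `e`,
#'   `omega`, `fmax` (d^-1), `N0`, `h`.
#' @export
population_params <- function(N0, h, fmax_per_h, e = 0.85, omega = 0.5,
                              env = environment_spec()) {
  stopifnot(N0 > 0, h > 0, fmax_per_h > 0, e > 0, e <= 1,
            omega > 0, omega <= 1)
  structure(list(r = growth_rate(env), K = carrying_capacity(env),
                 x = metabolic_rate(env), e = e, omega = omega,
                 fmax = 24 * fmax_per_h, N0 = N0, h = h),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Rosenzweig-MacArthur parameters (densities # m^-2, rates d^-1):\n")
  print(unlist(x))
  invisible(x)
}

#' Prey density on the predator isocline
#'
#' The prey density at which predator growth balances metabolism:
#' \deqn{N^* = \left(\frac{x N_0^h}{e \omega f_{max} - x}\right)^{1/h}.}
#' Requires energetic feasibility \eqn{e \omega f_{max} > x}.
#'
#' @param params a [population_params()] object.
#' @return `N_star`, or `NA_real_` (with attribute `infeasible = TRUE`)
#'   when the predator cannot energetically persist at any prey density.
#' @export
predator_isocline <- function(params) {
  surplus <- params$e * params$omega * params$fmax - params$x
  if (surplus <= 0)
    return(structure(NA_real_, infeasible = TRUE))
  (params$x * params$N0^params$h / surplus)^(1 / params$h)
}

#' Predator density on the prey isocline
#'
#' \deqn{P(N) = r N^{1-h} (K - N) \frac{N_0^h + N^h}{K \omega f_{max}}.}
#'
#' @param params a [population_params()] object.
#' @param N prey density (vectorized), > 0.
#' @return Predator density on the prey isocline.
#' @export
prey_isocline <- function(params, N) {
  stopifnot(all(N > 0))
  with(params,
       r * N^(1 - h) * (K - N) * (N0^h + N^h) / (K * omega * fmax))
}

#' Equilibrium and extinction classification for one patch
#'
#' Intersects the isoclines and compares the equilibrium densities with
#' the patch-scaled extinction boundary of two individuals per patch
#' (`2/area` individuals m^-2). The predator goes extinct when it is
#' energetically infeasible, when its required prey density reaches the
#' carrying capacity, or when its equilibrium density falls below the
#' boundary; the prey then grows to `K` (and is itself checked against
#' the boundary).
#'
#' @param params a [population_params()] object.
#' @param area_m2 patch area (m^2) setting the extinction boundary.
#' @return A list of class `"equilibrium_result"`: `status`
#'   (`"coexistence"`, `"predator_extinct"` or `"prey_extinct"`),
#'   `N_star`, `P_star`, `extinction_boundary`.
#' @export
classify_equilibrium <- function(params, area_m2) {
  stopifnot(area_m2 > 0)
  boundary <- 2 / area_m2
  N_star <- predator_isocline(params)
  predator_ok <- is.finite(N_star) && N_star < params$K
  P_star <- if (predator_ok) prey_isocline(params, N_star) else NA_real_
  if (predator_ok && P_star >= boundary) {
    status <- "coexistence"
  } else {
    N_star <- params$K
    P_star <- 0
    status <- if (params$K < boundary) "prey_extinct" else "predator_extinct"
  }
  structure(list(status = status, N_star = N_star, P_star = P_star,
                 extinction_boundary = boundary),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("%s: N* = %.4g, P* = %.4g (boundary %.4g # m^-2)\n",
              x$status, x$N_star, x$P_star, x$extinction_boundary))
  invisible(x)
}

#' Coexistence map over patch size and refuge availability
#'
#' Evaluates the habitat-dependent functional response of a fitted model
#' at every patch-size x refuge combination, builds the population
#' parameters and classifies each cell against its extinction boundary.
#'
#' @param fit an [fr_fit()] (or [fr_params()]) object supplying `N0`,
#'   `h` and `ln_fmax` per habitat.
#' @param areas patch areas (m^2).
#' @param refuge_fractions refuge availabilities.
#' @param e,omega,env see [population_params()].
#' @param drop_area_term if `TRUE`, evaluate `N0` (and `h`) at a
#'   reference area of 1 m^2 instead of each patch's own area, removing
#'   the (marginal) patch-size dependence of the feeding interaction.
#' @return A `data.frame` with one row per grid cell: `area_m2`,
#'   `refuge_fraction`, `N0`, `h`, `status`, `N_star`, `P_star`,
#'   `extinction_boundary`.
#' @export
coexistence_map <- function(fit, areas, refuge_fractions, e = 0.85,
                            omega = 0.5, env = environment_spec(),
                            drop_area_term = FALSE) {
  grid <- expand.grid(area_m2 = areas, refuge_fraction = refuge_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  pr <- predict_n0_h(fit, if (drop_area_term) 1 else grid$area_m2,
                     grid$refuge_fraction)
  fmax_per_h <- exp(fit$ln_fmax)
  out <- cbind(grid, N0 = pr$N0, h = pr$h, status = NA_character_,
               N_star = NA_real_, P_star = NA_real_,
               extinction_boundary = NA_real_)
  for (i in seq_len(nrow(out))) {
    pp <- population_params(out$N0[i], out$h[i], fmax_per_h, e, omega, env)
    eq <- classify_equilibrium(pp, out$area_m2[i])
    out$status[i] <- eq$status
    out$N_star[i] <- eq$N_star
    out$P_star[i] <- eq$P_star
    out$extinction_boundary[i] <- eq$extinction_boundary
  }
  out
}

#' Numerical integration of the predator-prey dynamics
#'
#' Integrates the Rosenzweig-MacArthur system (used to cross-validate the
#' analytical isoclines and inspect transients or limit cycles).
#'
#' @param params a [population_params()] object.
#' @param N_init,P_init initial densities (# m^-2), > 0.
#' @param t_end end time in days.
#' @param n_out number of output time points.
#' @return A `data.frame` with columns `time`, `N`, `P`.
#' @export
simulate_dynamics <- function(params, N_init, P_init, t_end = 1000,
                              n_out = 501) {
  stopifnot(N_init > 0, P_init >= 0, t_end > 0)
  rhs <- function(t, y, p) {
    feeding <- p$omega * real_fr(max(y[1], 0), p$fmax, p$N0, p$h) * y[2]
    list(c(p$r * y[1] * (1 - y[1] / p$K) - feeding,
           p$e * feeding - p$x * y[2]))
  }
  sol <- deSolve::ode(c(N = N_init, P = P_init),
                      seq(0, t_end, length.out = n_out), rhs, params)
  if (attr(sol, "istate")[1] < 0)
    stop("integration of the population dynamics failed")
  out <- as.data.frame(sol)
  names(out) <- c("time", "N", "P")
  out
}
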