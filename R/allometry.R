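#' Allometric trait constants
#'
#' Constants of the power-law trait equations (movement velocity, gut
#' capacity, digestion rate, handling time) and of the generalized Ricker
#' attack-success curve. Defaults are the empirically derived values used
#' throughout the package. Body masses are in milligram everywhere in the
#' individual-based layer; the population layer converts units itself.
#'
#' The traits are
#' \deqn{V = v_0 M^{a_v} \quad [cm\,s^{-1}]}
#' \deqn{G = g_0 M^{a_g} \quad [mg]}
#' \deqn{D = d_0 M^{a_d} \quad [mg\,s^{-1}]}
#' \deqn{T_h = h_0 M_p^{a_{h,p}} M_n^{a_{h,n}} \quad [s]}
#' \deqn{S_a = a_0 \left(\frac{R}{R_{opt}} e^{1 - R/R_{opt}}\right)^\lambda}
#' with \eqn{M} the body mass of the individual concerned, subscripts
#' \eqn{p}/\eqn{n} predator/prey, and \eqn{R = M_p/M_n} the predator:prey
#' body-mass ratio.
#'
#' @param v0,a_v velocity intercept (cm s^-1 mg^-a_v) and exponent.
#' @param g0,a_g gut-capacity intercept (mg mg^-a_g) and exponent.
#' @param d0,a_d digestion-rate intercept (mg s^-1 mg^-a_d) and exponent.
#' @param h0,a_h_p,a_h_n handling-time intercept (s) and its predator- and
#'   prey-mass exponents.
#' @param a0 maximum attack success (probability, in (0, 1]).
#' @param R_opt optimal predator:prey body-mass ratio (unitless).
#' @param lambda shape parameter of the Ricker attack-success curve.
#' @return An object of class `"allometric_constants"` (a named list).
#' @seealso [compute_traits()], [attack_success()]
#' @examples
#' ac <- allometric_constants()
#' compute_traits(100, 1, ac)
#' @export
allometric_constants <- function(v0 = 0.546, a_v = 0.29,
                                 g0 = 0.50, a_g = 0.434,
                                 d0 = 5e-5, a_d = 0.75,
                                 h0 = 37.504, a_h_p = -0.330, a_h_n = 0.173,
                                 a0 = 0.10, R_opt = 100, lambda = 1) {
  stopifnot(v0 > 0, g0 > 0, d0 > 0, h0 > 0, a0 > 0, a0 <= 1,
            R_opt > 0, lambda >= 0)
  structure(list(v0 = v0, a_v = a_v, g0 = g0, a_g = a_g,
                 d0 = d0, a_d = a_d, h0 = h0, a_h_p = a_h_p, a_h_n = a_h_n,
                 a0 = a0, R_opt = R_opt, lambda = lambda),
            class = "allometric_constants")
}

#' @export
print.allometric_constants <- function(x, ...) {
  cat("Allometric trait constants (masses in mg):\n")
  print(unlist(x))
  invisible(x)
}

#' Attack success as a function of the body-mass ratio
#'
#' Generalized Ricker curve
#' \eqn{S_a = a_0 ((R/R_{opt}) e^{1 - R/R_{opt}})^\lambda}, unimodal in the
#' predator:prey mass ratio \eqn{R} with maximum \eqn{a_0} at
#' \eqn{R = R_{opt}}.
#'
#' @param mass_ratio predator:prey body-mass ratio(s), > 0.
#' @param constants an [allometric_constants()] object.
#' @return Capture probability per encounter, in `[0, a0]`.
#' @export
attack_success <- function(mass_ratio, constants = allometric_constants()) {
  if (any(!is.finite(mass_ratio)) || any(mass_ratio <= 0))
    stop("'mass_ratio' must be positive and finite")
  rel <- mass_ratio / constants$R_opt
  constants$a0 * (rel * exp(1 - rel))^constants$lambda
}

#' Body-mass-dependent traits of a predator-prey pair
#'
#' Evaluates the allometric trait equations for a fixed predator and prey
#' body mass (mg). Traits are constant within a feeding trial; there is no
#' ontogeny.
#'
#' @param predator_mass,prey_mass body masses in mg, > 0.
#' @param constants an [allometric_constants()] object.
#' @return A list of class `"trait_set"` with elements `velocity_pred`,
#'   `velocity_prey` (cm s^-1), `gut_capacity` (mg), `digestion_rate`
#'   (mg s^-1, the evacuation rate at a full gut), `handling_time` (s) and
#'   `attack_success` (probability).
#' @export
compute_traits <- function(predator_mass, prey_mass,
                           constants = allometric_constants()) {
  if (!is.finite(predator_mass) || predator_mass <= 0 ||
      !is.finite(prey_mass) || prey_mass <= 0)
    stop("body masses must be positive and finite")
  cc <- constants
  structure(list(
    velocity_pred = cc$v0 * predator_mass^cc$a_v,
    velocity_prey = cc$v0 * prey_mass^cc$a_v,
    gut_capacity  = cc$g0 * predator_mass^cc$a_g,
    digestion_rate = cc$d0 * predator_mass^cc$a_d,
    handling_time = cc$h0 * predator_mass^cc$a_h_p * prey_mass^cc$a_h_n,
    attack_success = attack_success(predator_mass / prey_mass, cc)
  ), class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat("Individual traits:\n")
  print(unlist(x))
  invisible(x)
}
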