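#' Synthetic negative-binomial feeding table
#'
#' Draws feeding counts from the habitat-scaled functional-response model
#' at a given design, for testing the fitting layer in isolation from the
#' individual-based simulator: means follow Real's functional response
#' with `N0` and `h` from the supplied parameter object, counts are
#' negative binomial with dispersion `k` (variance `mu + mu^2/k`).
#'
#' @param params an [fr_params()] (or fitted [fr_fit()]) object providing
#'   `ln_fmax` and the scaling coefficients.
#' @param design `data.frame` with columns `area_m2`, `refuge_fraction`,
#'   `density_per_m2`; or `NULL` to build a factorial from `areas`,
#'   `refuge_fractions` and `ladder_max`.
#' @param k negative-binomial dispersion (larger is closer to Poisson).
#' @param reps replicate rows per design point.
#' @param areas,refuge_fractions,ladder_max used when `design` is `NULL`:
#'   densities are `2^(0:ladder_max)` prey per patch at each area x refuge
#'   combination.
#' @param seed optional integer seed.
#' @return A `data.frame` with `area_m2`, `refuge_fraction`,
#'   `density_per_m2`, `eaten`.
#' @examples
#' truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.8, ln_c_h = 0.25,
#'                    ln_fmax = log(6.7))
#' d <- make_synthetic_feeding_table(truth, k = 4, reps = 2, seed = 1)
#' @export
make_synthetic_feeding_table <- function(params, design = NULL, k = 4,
                                         reps = 1L,
                                         areas = c(0.04, 0.16, 0.64, 1.44,
                                                   2.56),
                                         refuge_fractions = seq(0.05, 0.75,
                                                                by = 0.1),
                                         ladder_max = 12L, seed = NULL) {
  stopifnot(inherits(params, "fr_fit"), k > 0, reps >= 1)
  if (is.null(design)) {
    grid <- expand.grid(area_m2 = areas, refuge_fraction = refuge_fractions,
                        prey_count = 2^(0:ladder_max))
    design <- data.frame(area_m2 = grid$area_m2,
                         refuge_fraction = grid$refuge_fraction,
                         density_per_m2 = grid$prey_count / grid$area_m2)
  }
  stopifnot(all(c("area_m2", "refuge_fraction", "density_per_m2")
                %in% names(design)))
  design <- design[rep(seq_len(nrow(design)), each = reps), , drop = FALSE]
  rownames(design) <- NULL
  with_seed(seed, {
    pr <- predict_n0_h(params, design$area_m2, design$refuge_fraction)
    mu <- real_fr(design$density_per_m2, exp(params$ln_fmax), pr$N0, pr$h)
    design$eaten <- rnbinom(nrow(design), size = k, mu = mu)
    design
  })
}
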