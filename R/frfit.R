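#' Real's functional response
#'
#' Per-capita feeding rate
#' \deqn{f(N) = \frac{f_{max} N^h}{N_0^h + N^h}}
#' with maximum feeding rate \eqn{f_{max}} (prey per trial), half-saturation
#' density \eqn{N_0} (prey m^-2) and Hill exponent \eqn{h}. \eqn{h = 1}
#' gives the hyperbolic type II response; \eqn{h > 1} a sigmoid type III.
#'
#' @param N prey density (prey m^-2), > 0 (vectorized).
#' @param fmax maximum feeding rate.
#' @param N0 half-saturation density, > 0.
#' @param h Hill exponent, > 0.
#' @return Expected feeding rate(s), same length as the longest argument.
#' @examples
#' real_fr(100, fmax = 6.7, N0 = 100, h = 1.28)  # half saturation: fmax/2
#' @export
real_fr <- function(N, fmax, N0, h) {
  if (any(N0 <= 0) || any(h <= 0))
    stop("'N0' and 'h' must be positive")
  fmax * N^h / (N0^h + N^h)
}

#' Maximum feeding rate by intercept-only Poisson regression
#'
#' Fits an intercept-only log-link Poisson GLM to replicate maximum-feeding
#' counts. The estimate is `ln` of the sample mean; its standard error is
#' `1/sqrt(sum(counts))`.
#'
#' @param counts non-negative integer feeding counts, not all zero.
#' @return A list with `ln_fmax`, `se`, `p_value` (Wald, against 0) and the
#'   underlying `glm` object (`fit`).
#' @export
fit_max_feeding <- function(counts) {
  if (length(counts) == 0 || any(counts < 0))
    stop("'counts' must be non-negative and non-empty")
  if (all(counts == 0))
    stop("all counts are zero: maximum feeding rate is degenerate")
  fit <- glm(counts ~ 1, family = poisson())
  sm <- summary(fit)$coefficients
  list(ln_fmax = unname(sm[1, 1]), se = unname(sm[1, 2]),
       p_value = unname(sm[1, 4]), fit = fit)
}

#' Habitat scaling structure of a functional-response parameter
#'
#' Describes how `ln(N0)` or `ln(h)` depends on patch area `A` and refuge
#' availability `R`: which terms enter (area, refuge, their interaction)
#' and on which scale each covariate enters -- `"power"` puts the
#' coefficient on the log covariate (a power law on the natural scale),
#' `"exponential"` on the identity covariate. The interaction term is the
#' product of the two transformed covariates and is only admissible when
#' both main terms are present.
#'
#' @param area,refuge,interaction logical: include the term?
#' @param form_area,form_refuge `"power"` or `"exponential"`.
#' @return An object of class `"scaling_spec"`.
#' @examples
#' scaling_spec(area = TRUE, refuge = TRUE)  # ln N0 ~ ln A + R
#' @export
scaling_spec <- function(area = FALSE, refuge = FALSE, interaction = FALSE,
                         form_area = c("power", "exponential"),
                         form_refuge = c("exponential", "power")) {
  if (interaction && !(area && refuge))
    stop("the interaction term requires both main terms")
  structure(list(area = area, refuge = refuge, interaction = interaction,
                 form_area = match.arg(form_area),
                 form_refuge = match.arg(form_refuge)),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.scaling_spec <- function(x, ...) {
  tA <- if (x$form_area == "power") "ln(A)" else "A"
  tR <- if (x$form_refuge == "power") "ln(R)" else "R"
  terms <- c("1", if (x$area) tA, if (x$refuge) tR,
             if (x$interaction) paste0(tA, ":", tR))
  paste(terms, collapse = " + ")
}

spec_covariate <- function(x, form) if (form == "power") log(x) else x

# design matrix of the ln-linear predictor for one parameter
spec_design <- function(spec, area, refuge, prefix) {
  X <- cbind(intercept = rep(1, length(area)))
  if (spec$area) X <- cbind(X, area = spec_covariate(area, spec$form_area))
  if (spec$refuge)
    X <- cbind(X, refuge = spec_covariate(refuge, spec$form_refuge))
  if (spec$interaction)
    X <- cbind(X, interaction = spec_covariate(area, spec$form_area) *
                                spec_covariate(refuge, spec$form_refuge))
  colnames(X) <- paste(prefix, colnames(X), sep = ".")
  X
}

n_spec_par <- function(spec) 1L + spec$area + spec$refuge + spec$interaction

#' Negative-binomial log-likelihood of a habitat-scaled functional response
#'
#' Mean of observation i is Real's functional response at its density, with
#' `N0` and `h` given by the exponentiated ln-linear predictors of the two
#' scaling specs; counts are negative binomial with variance
#' \eqn{\mu + \mu^2/k}.
#'
#' @param params numeric parameter vector: coefficients of the `N0`
#'   predictor, then of the `h` predictor, then `ln(k)`.
#' @param data `data.frame` with columns `area_m2`, `refuge_fraction`,
#'   `density_per_m2`, `eaten`.
#' @param n0_spec,h_spec [scaling_spec()] objects for `ln(N0)` and `ln(h)`.
#' @param ln_fmax fixed log maximum feeding rate (from [fit_max_feeding()]).
#' @return The summed log-likelihood (`-Inf` for unusable parameters).
#' @export
nb_loglik <- function(params, data, n0_spec, h_spec, ln_fmax) {
  if (any(!is.finite(params))) return(-Inf)
  p1 <- n_spec_par(n0_spec)
  p2 <- n_spec_par(h_spec)
  stopifnot(length(params) == p1 + p2 + 1L)
  X1 <- spec_design(n0_spec, data$area_m2, data$refuge_fraction, "n0")
  X2 <- spec_design(h_spec, data$area_m2, data$refuge_fraction, "h")
  N0 <- exp(drop(X1 %*% params[seq_len(p1)]))
  h  <- exp(drop(X2 %*% params[p1 + seq_len(p2)]))
  # above exp(35) the NB is numerically Poisson; capping keeps dnbinom finite
  k  <- exp(min(params[p1 + p2 + 1L], 35))
  mu <- real_fr(data$density_per_m2, exp(ln_fmax), N0, h)
  ll <- sum(dnbinom(data$eaten, size = k, mu = mu, log = TRUE))
  if (!is.finite(ll)) -Inf else ll
}

#' Fit Real's functional response with habitat-dependent parameters
#'
#' The central model of the package: feeding counts from trials at prey
#' density `N`, patch area `A` and refuge availability `R` are modelled as
#' negative binomial with mean
#' \deqn{\mu = \frac{f_{max} N^h}{N_0^h + N^h},}
#' where \eqn{f_{max}} is fixed beforehand (physiological ceiling,
#' estimated from maximum-feeding trials) and \eqn{\ln N_0} and
#' \eqn{\ln h} are ln-linear in habitat covariates as described by two
#' [scaling_spec()]s. All remaining parameters -- the scaling coefficients
#' and the log dispersion \eqn{\ln k} (variance \eqn{\mu + \mu^2/k}) -- are
#' estimated by maximum likelihood with multiple starts; standard errors
#' come from the observed information at the optimum.
#'
#' @param data trial table with columns `area_m2`, `refuge_fraction`,
#'   `density_per_m2`, `eaten` (e.g. from [run_experiment()]).
#' @param n0_spec,h_spec [scaling_spec()]s for `ln(N0)` and `ln(h)`; the
#'   defaults fit habitat-independent `N0` and `h`.
#' @param ln_fmax fixed log maximum feeding rate.
#' @param starts optional matrix of starting values (one start per row).
#' @param control passed to [stats::optim()] (method `"BFGS"`).
#' @return An object of class `"fr_fit"`: a list with `coefficients`,
#'   `se`, `vcov`, `logLik`, `bic`, `n_obs`, `k`, `ln_fmax`, the specs and
#'   the data. Methods: `print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `BIC`, `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @seealso [select_scaling_model()], [screen_functional_forms()],
#'   [hill_test()]
#' @export
fr_fit <- function(data, n0_spec = scaling_spec(), h_spec = scaling_spec(),
                   ln_fmax, starts = NULL, control = list(maxit = 1000)) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("area_m2", "refuge_fraction", "density_per_m2", "eaten")
                %in% names(data)))
  if (h_spec$refuge && any(data$refuge_fraction <= 0))
    stop("refuge availability must be > 0 when ln(R) enters the h predictor")
  p1 <- n_spec_par(n0_spec)
  p2 <- n_spec_par(h_spec)
  npar <- p1 + p2 + 1L

  if (is.null(starts)) {
    # coarse grid over the two intercepts; slopes 0; moment start for ln k
    q <- log(quantile(data$density_per_m2, c(0.25, 0.5, 0.75), names = FALSE))
    starts <- do.call(rbind, lapply(q, function(lnN0) {
      do.call(rbind, lapply(c(0, 0.5), function(lnh) {
        s <- numeric(npar)
        s[1] <- lnN0
        s[p1 + 1L] <- lnh
        s[npar] <- log(2)
        s
      }))
    }))
  }

  # finite sentinel keeps BFGS line searches inside the feasible region;
  # overflow NaNs in far-out parameter regions are expected and handled
  nll <- function(par) {
    ll <- suppressWarnings(nb_loglik(par, data, n0_spec, h_spec, ln_fmax))
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  keep_best <- function(best, fit) {
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) return(best)
    if (is.null(best) || fit$value < best$value) fit else best
  }
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, method = "BFGS", control = control),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
      # simplex fallback for starts BFGS cannot leave, then a BFGS polish
      fit <- tryCatch(
        optim(starts[i, ], nll, method = "Nelder-Mead",
              control = list(maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e10)
        fit <- tryCatch(
          optim(fit$par, nll, method = "BFGS", control = control),
          error = function(e) fit)
    }
    best <- keep_best(best, fit)
  }
  if (is.null(best))
    stop("functional-response fit failed to converge from all starts")

  hess <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) matrix(NA_real_, npar, npar))
  else matrix(NA_real_, npar, npar)

  nm1 <- colnames(spec_design(n0_spec, 1, 1, "n0"))
  nm2 <- colnames(spec_design(h_spec, 1, 1, "h"))
  nms <- c(nm1, nm2, "ln_k")
  cf <- setNames(best$par, nms)
  dimnames(vc) <- list(nms, nms)
  ll <- -best$value
  structure(list(
    coefficients = cf,
    se = setNames(sqrt(pmax(diag(vc), 0)), nms),
    vcov = vc,
    logLik = ll,
    bic = -2 * ll + npar * log(nrow(data)),
    n_obs = nrow(data),
    n_par = npar,
    k = exp(unname(cf["ln_k"])),
    ln_fmax = ln_fmax,
    n0_spec = n0_spec,
    h_spec = h_spec,
    convergence = best$convergence,
    data = data), class = "fr_fit")
}

#' Predict half-saturation density and Hill exponent for a habitat
#'
#' Exponentiates the fitted ln-linear predictors of a [fr_fit()] at given
#' patch areas and refuge availabilities.
#'
#' @param fit an `fr_fit` object (or a list of coefficients from
#'   [fr_params()]).
#' @param area_m2,refuge_fraction habitat covariates (vectorized).
#' @return A `data.frame` with columns `area_m2`, `refuge_fraction`, `N0`,
#'   `h`.
#' @export
predict_n0_h <- function(fit, area_m2, refuge_fraction) {
  stopifnot(inherits(fit, "fr_fit"))
  n <- max(length(area_m2), length(refuge_fraction))
  A <- rep_len(area_m2, n)
  R <- rep_len(refuge_fraction, n)
  if (fit$h_spec$refuge && any(R <= 0))
    stop("refuge availability must be > 0 when ln(R) enters the h predictor")
  p1 <- n_spec_par(fit$n0_spec)
  p2 <- n_spec_par(fit$h_spec)
  X1 <- spec_design(fit$n0_spec, A, R, "n0")
  X2 <- spec_design(fit$h_spec, A, R, "h")
  data.frame(area_m2 = A, refuge_fraction = R,
             N0 = exp(drop(X1 %*% fit$coefficients[seq_len(p1)])),
             h = exp(drop(X2 %*% fit$coefficients[p1 + seq_len(p2)])))
}

#' Construct a functional-response parameter object directly
#'
#' Builds a minimal `fr_fit`-classed object from known coefficients, so the
#' population layer (and plotting) can be driven without refitting.
#' Standard errors are `NA`.
#'
#' @param ln_c_n0 intercept of the `ln(N0)` predictor.
#' @param a_n0,b_n0,gamma_n0 optional `ln(A)`, refuge and interaction
#'   coefficients of the `ln(N0)` predictor (`NULL` to omit the term).
#' @param ln_c_h intercept of the `ln(h)` predictor.
#' @param a_h,b_h,gamma_h optional area/refuge/interaction coefficients of
#'   the `ln(h)` predictor.
#' @param ln_fmax log maximum feeding rate (prey per hour).
#' @return An object of class `"fr_fit"` without data or likelihood.
#' @export
fr_params <- function(ln_c_n0, a_n0 = NULL, b_n0 = NULL, gamma_n0 = NULL,
                      ln_c_h = 0, a_h = NULL, b_h = NULL, gamma_h = NULL,
                      ln_fmax) {
  n0_spec <- scaling_spec(area = !is.null(a_n0), refuge = !is.null(b_n0),
                          interaction = !is.null(gamma_n0))
  h_spec <- scaling_spec(area = !is.null(a_h), refuge = !is.null(b_h),
                         interaction = !is.null(gamma_h),
                         form_refuge = "power")
  cf <- c(ln_c_n0, a_n0, b_n0, gamma_n0, ln_c_h, a_h, b_h, gamma_h, NA_real_)
  nms <- c(colnames(spec_design(n0_spec, 1, 1, "n0")),
           colnames(spec_design(h_spec, 1, 1, "h")), "ln_k")
  structure(list(coefficients = setNames(cf, nms),
                 se = setNames(rep(NA_real_, length(cf)), nms),
                 ln_fmax = ln_fmax, n0_spec = n0_spec, h_spec = h_spec),
            class = "fr_fit")
}

#' Wald test of the Hill exponent against 1
#'
#' Tests the intercept of the `ln(h)` predictor against 0 (a Hill exponent
#' of 1, the type II response) and reports the implied Hill exponent.
#'
#' @param fit an [fr_fit()] object.
#' @return A list with `h` (`exp` of the intercept), `ln_c_h`, `se`, `z`
#'   and `p_value`.
#' @export
hill_test <- function(fit) {
  stopifnot(inherits(fit, "fr_fit"))
  est <- fit$coefficients["h.intercept"]
  se <- fit$se["h.intercept"]
  if (!is.finite(se)) stop("no standard error available for ln(C_h)")
  z <- est / se
  list(h = exp(unname(est)), ln_c_h = unname(est), se = unname(se),
       z = unname(z), p_value = unname(2 * pnorm(-abs(z))))
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.fr_fit <- function(object, ...) object$coefficients

#' @export
vcov.fr_fit <- function(object, ...) object$vcov

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.fr_fit <- function(object, ...) {
  pr <- predict_n0_h(object, object$data$area_m2,
                     object$data$refuge_fraction)
  real_fr(object$data$density_per_m2, exp(object$ln_fmax), pr$N0, pr$h)
}

#' Expected feeding rates from a fitted functional response
#'
#' @param object an [fr_fit()] object.
#' @param newdata optional `data.frame` with `area_m2`, `refuge_fraction`,
#'   `density_per_m2`; defaults to the fitting data.
#' @param ... unused.
#' @return Numeric vector of expected feeding counts per trial.
#' @export
predict.fr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  pr <- predict_n0_h(object, newdata$area_m2, newdata$refuge_fraction)
  real_fr(newdata$density_per_m2, exp(object$ln_fmax), pr$N0, pr$h)
}

#' @export
residuals.fr_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$eaten - mu
  if (type == "pearson") r / sqrt(mu + mu^2 / object$k) else r
}

#' @export
simulate.fr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed, {
    mu <- fitted(object)
    as.data.frame(replicate(nsim, rnbinom(length(mu), size = object$k,
                                          mu = mu)))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Habitat-scaled functional response (negative binomial MLE)\n")
  cat("  ln(N0) ~", format(x$n0_spec), "\n")
  cat("  ln(h)  ~", format(x$h_spec), "\n")
  cat("  fixed ln(fmax) =", format(x$ln_fmax, digits = 4), "\n")
  print(x$coefficients)
  if (!is.null(x$bic))
    cat("logLik", format(x$logLik, digits = 6), "  BIC",
        format(x$bic, digits = 6), "  n", x$n_obs, "\n")
  invisible(x)
}

#' @export
summary.fr_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.fr_fit")
}

#' @export
print.summary.fr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Plot observed and fitted functional responses
#'
#' Feeding counts against ln prey density, one panel-colour per refuge
#' level, with the fitted curves superimposed (at the median patch area).
#'
#' @param x an [fr_fit()] object fitted to data.
#' @param ... passed to [plot()].
#' @export
plot.fr_fit <- function(x, ...) {
  d <- x$data
  lev <- sort(unique(d$refuge_fraction))
  cols <- grDevices::hcl.colors(max(length(lev), 2), "viridis")
  plot(log(d$density_per_m2), d$eaten,
       col = cols[match(d$refuge_fraction, lev)],
       xlab = "ln prey density [ln # m^-2]", ylab = "prey eaten per trial",
       ...)
  A <- stats::median(d$area_m2)
  for (i in seq_along(lev)) {
    N <- exp(seq(log(min(d$density_per_m2)), log(max(d$density_per_m2)),
                 length.out = 200))
    pr <- predict_n0_h(x, A, lev[i])
    lines(log(N), real_fr(N, exp(x$ln_fmax), pr$N0, pr$h), col = cols[i])
  }
  legend("topleft", legend = sprintf("R = %.2f", lev), col = cols[seq_along(lev)],
         lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
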