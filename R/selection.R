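term_sets <- function(form_area, form_refuge) {
  list(
    `1`       = scaling_spec(FALSE, FALSE, FALSE, form_area, form_refuge),
    `A`       = scaling_spec(TRUE,  FALSE, FALSE, form_area, form_refuge),
    `R`       = scaling_spec(FALSE, TRUE,  FALSE, form_area, form_refuge),
    `A+R`     = scaling_spec(TRUE,  TRUE,  FALSE, form_area, form_refuge),
    `A+R+A:R` = scaling_spec(TRUE,  TRUE,  TRUE,  form_area, form_refuge)
  )
}

rank_fits <- function(fits, labels) {
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed")
  if (any(!ok))
    warning(sum(!ok), " candidate model(s) failed to fit and were excluded")
  tab <- data.frame(
    model = labels,
    n_par = vapply(fits, function(f)
      if (is.null(f)) NA_integer_ else f$n_par, integer(1)),
    logLik = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$logLik, numeric(1)),
    BIC = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$bic, numeric(1)),
    stringsAsFactors = FALSE)
  # minimum BIC wins; ties (within numerical noise) go to fewer parameters
  ord <- order(round(tab$BIC, 6), tab$n_par, na.last = TRUE)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  list(table = tab, best_index = ord[1])
}

#' BIC selection over the 25 admissible habitat-scaling models
#'
#' Crosses the five admissible term sets for the `ln(N0)` predictor with
#' the five for the `ln(h)` predictor -- no terms, area only, refuge only,
#' both, or both plus their interaction (an interaction is only admissible
#' with both main terms) -- on the selected covariate scales (area as a
#' power law for both parameters; refuge exponentially for `N0` and as a
#' power law for `h`). All 25 candidates are fitted by [fr_fit()] and
#' compared by BIC; ties are broken toward the smaller model.
#'
#' @inheritParams fr_fit
#' @return A list of class `"fr_selection"`: `best` (the winning
#'   `fr_fit`), `table` (25-row `data.frame` with term sets, `n_par`,
#'   `logLik`, `BIC`, `rank`) and `fits` (all candidates).
#' @export
select_scaling_model <- function(data, ln_fmax, control = list(maxit = 1000)) {
  n0_sets <- term_sets("power", "exponential")
  h_sets  <- term_sets("power", "power")
  grid <- expand.grid(n0 = seq_along(n0_sets), h = seq_along(h_sets))
  fits <- vector("list", nrow(grid))
  labels <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n0s <- n0_sets[[grid$n0[i]]]
    hs  <- h_sets[[grid$h[i]]]
    labels[i] <- sprintf("N0 ~ %s | h ~ %s",
                         names(n0_sets)[grid$n0[i]], names(h_sets)[grid$h[i]])
    fits[i] <- list(tryCatch(fr_fit(data, n0s, hs, ln_fmax, control = control),
                          error = function(e) NULL))
  }
  rk <- rank_fits(fits, labels)
  structure(list(best = fits[[rk$best_index]], table = rk$table,
                 fits = fits), class = "fr_selection")
}

#' @export
print.fr_selection <- function(x, ...) {
  cat("Habitat-scaling model selection (", nrow(x$table), " candidates)\n",
      sep = "")
  tab <- x$table[order(x$table$rank), ]
  print(utils::head(tab, 8), row.names = FALSE, digits = 6)
  cat("...\nBest model:\n")
  print(x$best)
  invisible(x)
}

#' Screen power-law versus exponential habitat dependencies
#'
#' Fits the 16 full models (area, refuge and interaction terms on both
#' `ln(N0)` and `ln(h)`) arising from crossing a power-law or exponential
#' dependence on patch area and on refuge availability for each parameter,
#' and ranks them by BIC. This decides the covariate scales used by
#' [select_scaling_model()].
#'
#' @inheritParams fr_fit
#' @return A list of class `"fr_selection"` with `best`, 16-row `table`
#'   and `fits`.
#' @export
screen_functional_forms <- function(data, ln_fmax,
                                    control = list(maxit = 1000)) {
  forms <- c("power", "exponential")
  grid <- expand.grid(n0_A = forms, n0_R = forms, h_A = forms, h_R = forms,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  labels <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n0s <- scaling_spec(TRUE, TRUE, TRUE, grid$n0_A[i], grid$n0_R[i])
    hs  <- scaling_spec(TRUE, TRUE, TRUE, grid$h_A[i], grid$h_R[i])
    labels[i] <- sprintf("N0: A %s, R %s | h: A %s, R %s",
                         grid$n0_A[i], grid$n0_R[i], grid$h_A[i], grid$h_R[i])
    fits[i] <- list(tryCatch(fr_fit(data, n0s, hs, ln_fmax, control = control),
                          error = function(e) NULL))
  }
  rk <- rank_fits(fits, labels)
  structure(list(best = fits[[rk$best_index]], table = rk$table,
                 fits = fits), class = "fr_selection")
}
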