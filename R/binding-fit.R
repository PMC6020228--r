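# One-site equilibrium binding model Y = Bmax * X / (Kd + X) and its
# nonlinear least-squares fit for steady-state surface-binding responses.
#
# The fit is unweighted. Positivity of both parameters is enforced by
# fitting on the log scale (lb = log Bmax, lk = log Kd); standard errors on
# the natural scale are obtained from the linearized covariance at the
# optimum by the delta method (se(Bmax) = Bmax * se(lb), etc.).

#' One-site binding response
#'
#' Equilibrium saturation curve `Y = Bmax * X / (Kd + X)`: half-saturation
#' at `X = Kd`, plateau `Bmax` as `X` grows.
#'
#' @param x Analyte concentration (uM), non-negative.
#' @param bmax Maximum response (R.U.), positive.
#' @param kd Equilibrium dissociation constant (uM), positive.
#' @return Response in the units of `bmax`.
#' @examples
#' one_site_response(3.1, bmax = 1466, kd = 3.1)  # half of Bmax
#' @export
one_site_response <- function(x, bmax, kd) {
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (any(bmax <= 0) || any(kd <= 0)) abort("bmax and kd must be positive")
  bmax * x / (kd + x)
}

#' Fit the one-site binding model
#'
#' Unweighted nonlinear least squares of `response ~ Bmax * X / (Kd + X)`
#' on a concentration/response table, via Levenberg-Marquardt on
#' log-parameters. Initial guesses: `Bmax0 = max(response)`,
#' `Kd0 = median(concentration)`. Duplicate injections at the same
#' concentration are averaged before fitting by default.
#'
#' @param data Data frame with columns `concentration` (uM) and `response`
#'   (R.U.); extra columns (e.g. replicate ids) are ignored.
#' @param average_replicates Average responses per concentration before
#'   fitting (default `TRUE`); set `FALSE` to fit raw replicates.
#' @param max_iter Iteration cap for the optimizer.
#' @return A `one_site_fit` object with elements `bmax`, `kd`, `se_bmax`,
#'   `se_kd`, `r_squared`, `converged`, `n`, `data` (the fitted table), and
#'   the underlying `fit`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' d <- simulate_binding(c(0.1, 0.5, 1, 2, 5, 10, 15), bmax = 1466, kd = 3.1)
#' fit <- fit_one_site(d)
#' glance(fit)
#' @export
fit_one_site <- function(data, average_replicates = TRUE, max_iter = 500) {
  if (!all(c("concentration", "response") %in% names(data))) {
    abort("data must have columns 'concentration' and 'response'")
  }
  d <- tibble(concentration = as.numeric(data$concentration),
              response = as.numeric(data$response))
  if (any(d$concentration < 0)) abort("concentrations must be non-negative")
  if (average_replicates) {
    d <- d |>
      dplyr::group_by(.data$concentration) |>
      dplyr::summarise(response = mean(.data$response), .groups = "drop")
  }
  if (length(unique(d$concentration)) < 3) {
    abort("need at least 3 distinct concentrations")
  }
  if (diff(range(d$response)) == 0) {
    abort("degenerate data: all responses equal")
  }
  bmax0 <- max(d$response)
  kd0 <- median(d$concentration)
  if (bmax0 <= 0) bmax0 <- 1
  if (kd0 <= 0) kd0 <- mean(d$concentration[d$concentration > 0])
  fit <- minpack.lm::nlsLM(
    response ~ exp(lb) * concentration / (exp(lk) + concentration),
    data = d,
    start = list(lb = log(bmax0), lk = log(kd0)),
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  converged <- fit$convInfo$isConv
  if (!converged) {
    warn(sprintf("one-site fit did not converge in %d iterations", max_iter))
  }
  est <- coef(fit)
  bmax <- exp(est[["lb"]]); kd <- exp(est[["lk"]])
  # delta method from the log-scale linearized covariance
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  se_bmax <- bmax * sqrt(vc[1, 1])
  se_kd <- kd * sqrt(vc[2, 2])
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((d$response - mean(d$response))^2)
  out <- list(bmax = bmax, kd = kd, se_bmax = se_bmax, se_kd = se_kd,
              r_squared = 1 - ss_res / ss_tot, converged = converged,
              n = nrow(d), data = d, fit = fit)
  class(out) <- "one_site_fit"
  out
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf(
    "<one_site_fit> Bmax = %.4g +/- %.2g R.U., Kd = %.4g +/- %.2g uM, R2 = %.4f\n",
    x$bmax, x$se_bmax, x$kd, x$se_kd, x$r_squared))
  invisible(x)
}

#' @method tidy one_site_fit
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble(term = c("bmax", "kd"),
         estimate = c(x$bmax, x$kd),
         std.error = c(x$se_bmax, x$se_kd))
}

#' @method glance one_site_fit
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble(bmax = x$bmax, kd = x$kd, se_bmax = x$se_bmax, se_kd = x$se_kd,
         r.squared = x$r_squared, converged = x$converged, nobs = x$n)
}

#' @method augment one_site_fit
#' @export
augment.one_site_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- one_site_response(d$concentration, x$bmax, x$kd)
  d$.resid <- d$response - d$.fitted
  d
}

#' Predicted response at new concentrations
#'
#' @param object A [fit_one_site()] result.
#' @param newdata Optional data frame with a `concentration` column.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  one_site_response(x, object$bmax, object$kd)
}
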