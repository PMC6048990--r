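#' The modified Gompertz growth function
#'
#' Sigmoidal model of cell infiltration into the scratch, parameterised so
#' every parameter is biologically interpretable:
#' \deqn{N(t) = A \exp\!\left(-\exp\!\left(\frac{\mu_m e}{A}(\lambda - t) + 1\right)\right)}
#' with `A` the plateau cell number, `mu_m` the maximum infiltration
#' (repair) rate in cells/minute — the slope at the inflection point
#' `t* = lambda + A / (mu_m * e)`, where `N(t*) = A / e` — and `lambda`
#' the lag time in minutes, where the inflection tangent crosses zero.
#' `lambda` may legitimately be negative when migration started before
#' imaging. `N` is strictly increasing with `0 < N(t) < A`.
#'
#' @param t Time(s) in minutes.
#' @param A Plateau cell count (> 0).
#' @param mu_m Repair rate, cells/minute (> 0).
#' @param lam Lag time, minutes (any finite value).
#' @return Predicted cell count(s) inside the scratch.
#' @export
gompertz <- function(t, A, mu_m, lam) {
  A * exp(-exp(mu_m * exp(1) / A * (lam - t) + 1))
}

#' Initial parameter guess for the Gompertz fit
#'
#' `A0` is the maximum observed count; `mu_m0` the steepest secant slope
#' between consecutive timepoints (floored at 1e-6 to survive flat
#' series); `lambda0` the zero-crossing of the tangent through the
#' midpoint of the steepest segment.
#'
#' @param series An `infiltration_series`.
#' @return `list(A, mu_m, lam)`.
#' @export
initial_guess <- function(series) {
  stopifnot(inherits(series, "infiltration_series"))
  initial_guess_xy(series$times, series$inside)
}

initial_guess_xy <- function(t, n) {
  if (length(n) < 4L) stop("at least 4 timepoints required", call. = FALSE)
  if (all(n == 0L)) {
    stop("degenerate input: all counts are zero, nothing to fit", call. = FALSE)
  }
  A0 <- max(n)
  slopes <- diff(n) / diff(t)
  mu0 <- max(max(slopes), 1e-6)
  k <- which.max(slopes)
  t_mid <- (t[k] + t[k + 1L]) / 2
  n_mid <- (n[k] + n[k + 1L]) / 2
  lam0 <- t_mid - n_mid / mu0
  list(A = A0, mu_m = mu0, lam = lam0)
}

#' Goodness of fit of predicted counts
#'
#' @param observed,fitted Equal-length numeric vectors (n >= 2); the
#'   observations must not all be equal.
#' @return `c(r_squared = , rmse = )` with `R^2 = 1 - SS_res / SS_tot`
#'   (total sum of squares about the observed mean) and
#'   `RMSE = sqrt(SS_res / n)`.
#' @export
goodness_of_fit <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("degenerate input: observed counts have zero variance", call. = FALSE)
  }
  ss_res <- sum((observed - fitted)^2)
  c(r_squared = 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / length(observed)))
}

#' Flag a kinetic fit for inspection
#'
#' A fit is flagged when `r_squared < 0.9` (strict: exactly 0.9 is not
#' flagged) or when the optimizer did not converge. Flagged wells are kept
#' in the outputs — a poor Gompertz fit is itself informative, e.g. when
#' an adverse treatment causes counts to decline after the plateau.
#'
#' @param fit A `kinetic_fit`.
#' @param r2_threshold Flagging threshold on R-squared (default 0.9).
#' @return Logical.
#' @export
flag_fit <- function(fit, r2_threshold = 0.9) {
  stopifnot(inherits(fit, "kinetic_fit"))
  !isTRUE(fit$converged) || (is.finite(fit$r_squared) &&
                               fit$r_squared < r2_threshold) ||
    !is.finite(fit$r_squared)
}

#' Fit the modified Gompertz model to an infiltration series
#'
#' Ordinary (unweighted) nonlinear least squares via the
#' Levenberg-Marquardt algorithm. `A` and `mu_m` are kept positive by
#' optimizing their logarithms; `lambda` is unconstrained (it may be
#' negative). Convergence is declared on a relative residual-sum-of-squares
#' or parameter change below 1e-10 within 1000 iterations; an optimizer
#' failure returns a non-converged, flagged fit rather than an error.
#'
#' @param series An `infiltration_series` with at least 4 timepoints.
#' @param r2_threshold Flagging threshold passed to [flag_fit()].
#' @return A `kinetic_fit`: `params` (list `A`, `mu_m`, `lam`),
#'   `r_squared`, `rmse`, `converged`, `n_points`, `flagged`, `fitted`.
#' @export
fit_gompertz <- function(series, r2_threshold = 0.9) {
  stopifnot(inherits(series, "infiltration_series"))
  fit_gompertz_counts(series$times, series$inside,
                      r2_threshold = r2_threshold, well_id = series$well_id)
}

#' Fit the modified Gompertz model to raw time/count vectors
#'
#' Workhorse behind [fit_gompertz()]; counts may be non-integer (e.g.
#' replicate means or exact model samples).
#'
#' @param times Strictly increasing times in minutes.
#' @param counts Cell counts inside the scratch at those times.
#' @param r2_threshold Flagging threshold passed to [flag_fit()].
#' @param well_id Optional identifier carried into the fit.
#' @return A `kinetic_fit`, as [fit_gompertz()].
#' @export
fit_gompertz_counts <- function(times, counts, r2_threshold = 0.9,
                                well_id = NULL) {
  t <- as.numeric(times)
  y <- as.numeric(counts)
  if (length(y) < 4L) {
    stop("validation error: at least 4 timepoints are required to fit 3 parameters",
         call. = FALSE)
  }

  failed <- function() {
    structure(list(params = list(A = NA_real_, mu_m = NA_real_, lam = NA_real_),
                   r_squared = NA_real_, rmse = NA_real_, converged = FALSE,
                   n_points = length(y), flagged = TRUE,
                   fitted = rep(NA_real_, length(y)),
                   well_id = well_id),
              class = "kinetic_fit")
  }

  guess <- tryCatch(initial_guess_xy(t, y), error = function(e) NULL)
  if (is.null(guess)) return(failed())

  resid_fn <- function(p) {
    y - gompertz(t, A = exp(p[1L]), mu_m = exp(p[2L]), lam = p[3L])
  }
  p0 <- c(log(guess$A), log(guess$mu_m), guess$lam)
  out <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(out)) return(failed())

  # keep the better of the initial guess and the optimizer result so the
  # returned residual never exceeds the starting one
  rss0 <- sum(resid_fn(p0)^2)
  rss1 <- sum(out$fvec^2)
  p <- if (rss1 <= rss0) out$par else p0
  converged <- out$info %in% c(1L, 2L, 3L) && rss1 <= rss0
  params <- list(A = exp(p[1L]), mu_m = exp(p[2L]), lam = p[3L])
  fitted <- gompertz(t, params$A, params$mu_m, params$lam)
  gof <- tryCatch(goodness_of_fit(y, fitted), error = function(e) NULL)
  if (is.null(gof)) return(failed())
  fit <- structure(list(params = params,
                        r_squared = unname(gof["r_squared"]),
                        rmse = unname(gof["rmse"]),
                        converged = converged, n_points = length(y),
                        flagged = FALSE, fitted = fitted,
                        well_id = well_id),
                   class = "kinetic_fit")
  fit$flagged <- flag_fit(fit, r2_threshold)
  fit
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged && !is.finite(x$r_squared)) {
    cat("kinetic_fit: optimizer failed (flagged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "kinetic_fit%s: A = %.4g cells, mu_m = %.4g cells/min, lambda = %.4g min\n  R^2 = %.4f, RMSE = %.4g over %d points%s%s\n",
    if (!is.null(x$well_id)) paste0(" [", x$well_id, "]") else "",
    x$params$A, x$params$mu_m, x$params$lam, x$r_squared, x$rmse, x$n_points,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$flagged) ", FLAGGED for inspection" else ""))
  invisible(x)
}

#' Z-prime factor of a plate run
#'
#' Screening-assay quality score from the separation of positive and
#' negative control distributions of a kinetic parameter (typically `mu_m`
#' or `A`):
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' Values approaching 1 indicate a wide dynamic range; negative values an
#' unusable assay window.
#'
#' @param positive,negative Numeric vectors (>= 2 values each) of the
#'   parameter under the positive and negative control treatments; the
#'   group means must differ.
#' @return Scalar Z-prime (<= 1).
#' @export
z_prime <- function(positive, negative) {
  stopifnot(length(positive) >= 2L, length(negative) >= 2L)
  delta <- abs(mean(positive) - mean(negative))
  if (delta == 0) {
    stop("degenerate input: control group means are equal", call. = FALSE)
  }
  1 - 3 * (stats::sd(positive) + stats::sd(negative)) / delta
}
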