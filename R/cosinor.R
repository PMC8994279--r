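#' Fit a fixed-period cosinor model
#'
#' Ordinary least squares fit of \eqn{y = M + A\cos(2\pi(t-\phi)/\tau)} at a
#' fixed period \eqn{\tau}, via the linearisation on regressors
#' \eqn{\cos(2\pi t/\tau)} and \eqn{\sin(2\pi t/\tau)}. The mesor \eqn{M} is
#' the rhythm midline, the amplitude \eqn{A = \sqrt{\beta_c^2+\beta_s^2}} is
#' half the peak-to-trough range, and the acrophase \eqn{\phi} is reported as
#' the clock time of the curve maximum in hours within `[0, period_h)` (not
#' as a negative angle, as in some of the classical cosinor literature).
#'
#' Standard errors for amplitude and acrophase are delta-method
#' transformations of the OLS coefficient covariance.
#'
#' @param t Numeric vector of sampling times in hours.
#' @param y Numeric response vector, same length as `t`.
#' @param period_h Fixed period \eqn{\tau} in hours (default 24).
#' @return An object of class `cosinor_fit`: a list with elements `mesor`,
#'   `amplitude`, `acrophase_h`, `period_h`, `residual_sd`, `se` (named
#'   vector for mesor/amplitude/acrophase), `r_squared`, `n_points`,
#'   `flat` (`TRUE` when `y` is constant, in which case the acrophase is
#'   undefined and `acrophase_h` is `NA`), and the input data.
#' @examples
#' t <- 0:23
#' fit <- fit_cosinor(t, 2 + cos(2 * pi * (t - 5) / 24), period_h = 24)
#' tidy(fit)
#' @export
fit_cosinor <- function(t, y, period_h = 24) {
  stopifnot(is.numeric(t), is.numeric(y))
  if (length(t) != length(y)) {
    stop("`t` and `y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]
  y <- y[keep]
  n <- length(y)
  if (length(unique(t)) < 3) {
    stop("cosinor fit needs at least 3 distinct time points", call. = FALSE)
  }
  if (!is.numeric(period_h) || length(period_h) != 1 || period_h <= 0) {
    stop("`period_h` must be a single positive number", call. = FALSE)
  }

  omega <- 2 * pi / period_h
  xc <- cos(omega * t)
  xs <- sin(omega * t)

  if (stats::sd(y) == 0) {
    out <- new_cosinor_fit(
      mesor = y[1], amplitude = 0, acrophase_h = NA_real_,
      period_h = period_h, residual_sd = 0,
      se = c(mesor = 0, amplitude = NA_real_, acrophase = NA_real_),
      r_squared = NA_real_, n_points = n, flat = TRUE, t = t, y = y
    )
    return(out)
  }

  X <- cbind(1, xc, xs)
  if (qr(X)$rank < 3) {
    stop("collinear design: times are indistinguishable modulo the period",
         call. = FALSE)
  }

  fit <- stats::lm(y ~ xc + xs)
  beta <- stats::coef(fit)
  bc <- beta[["xc"]]
  bs <- beta[["xs"]]
  A <- sqrt(bc^2 + bs^2)
  phi <- (period_h / (2 * pi)) * atan2(bs, bc)
  phi <- phi %% period_h

  # vcov routes through summary.lm, which warns on exact fits; noise-free
  # inputs are a legitimate, tested case here
  V <- suppressWarnings(stats::vcov(fit))
  # delta method: A = sqrt(bc^2 + bs^2), phi = (tau/2pi) atan2(bs, bc)
  if (A > 0) {
    gA <- c(0, bc / A, bs / A)
    gP <- (period_h / (2 * pi)) * c(0, -bs / A^2, bc / A^2)
    se_A <- sqrt(drop(gA %*% V %*% gA))
    se_phi <- sqrt(drop(gP %*% V %*% gP))
  } else {
    se_A <- sqrt(V[2, 2])
    se_phi <- NA_real_
  }

  # noise-free inputs give an exact fit; the r.squared of 1 is meaningful
  # here, so the "essentially perfect fit" warning is silenced
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_cosinor_fit(
    mesor = unname(beta[1]), amplitude = A, acrophase_h = phi,
    period_h = period_h,
    residual_sd = stats::sigma(fit),
    se = c(mesor = sqrt(V[1, 1]), amplitude = se_A, acrophase = se_phi),
    r_squared = r2,
    n_points = n, flat = FALSE, t = t, y = y
  )
}

new_cosinor_fit <- function(mesor, amplitude, acrophase_h, period_h,
                            residual_sd, se, r_squared, n_points, flat,
                            t, y) {
  structure(
    list(
      mesor = mesor, amplitude = amplitude, acrophase_h = acrophase_h,
      period_h = period_h, residual_sd = residual_sd, se = se,
      r_squared = r_squared, n_points = n_points, flat = flat,
      data = tibble::tibble(t = t, y = y)
    ),
    class = "cosinor_fit"
  )
}

#' @exportS3Method base::print
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period ", format(x$period_h), " h, n = ", x$n_points,
      ")\n", sep = "")
  cat(sprintf("  mesor     %8.4f (SE %.4f)\n", x$mesor, x$se[["mesor"]]))
  cat(sprintf("  amplitude %8.4f (SE %s)\n", x$amplitude,
              format(x$se[["amplitude"]], digits = 4)))
  if (x$flat || is.na(x$acrophase_h)) {
    cat("  acrophase  undefined (flat series)\n")
  } else {
    cat(sprintf("  acrophase %8.4f h (SE %s)\n", x$acrophase_h,
                format(x$se[["acrophase"]], digits = 4)))
  }
  invisible(x)
}

#' Fitted values of a cosinor model
#'
#' @param object A `cosinor_fit`.
#' @param t Times (hours) at which to evaluate the fitted curve; defaults to
#'   the observed times.
#' @param ... Unused.
#' @export
predict.cosinor_fit <- function(object, t = object$data$t, ...) {
  if (object$flat || is.na(object$acrophase_h)) {
    return(rep(object$mesor, length(t)))
  }
  object$mesor + object$amplitude *
    cos(2 * pi * (t - object$acrophase_h) / object$period_h)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cosinor fit
#'
#' One row per rhythm parameter (mesor, amplitude, acrophase) with delta
#' method standard errors.
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h),
    std.error = unname(x$se)
  )
}

#' Glance at a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    period_h = x$period_h,
    nobs = x$n_points,
    flat = x$flat
  )
}

#' Signed minimal difference between two phases on the circle
#'
#' Returns `phi1 - phi2` wrapped into `(-period_h/2, period_h/2]`, i.e. the
#' signed displacement of `phi1` relative to `phi2` along the shorter arc.
#' Vectorised over `phi1` and `phi2`.
#'
#' @param phi1,phi2 Phases in hours.
#' @param period_h Period of the circle in hours (default 24).
#' @examples
#' circular_diff(23, 1)  # -2: 23 h is 2 h before 1 h
#' circular_diff(1, 23)  # +2
#' @export
circular_diff <- function(phi1, phi2, period_h = 24) {
  stopifnot(is.numeric(phi1), is.numeric(phi2),
            is.numeric(period_h), period_h > 0)
  if (any(!is.finite(phi1)) || any(!is.finite(phi2))) {
    stop("phases must be finite", call. = FALSE)
  }
  d <- (phi1 - phi2) %% period_h
  ifelse(d > period_h / 2, d - period_h, d)
}

#' Circular mean of phases
#'
#' Mean direction of a set of phase values in hours, computed from the
#' resultant of the corresponding unit vectors.
#'
#' @param phi Phases in hours (NA dropped).
#' @param period_h Period in hours (default 24).
#' @return Mean phase in `[0, period_h)`.
#' @export
circular_mean <- function(phi, period_h = 24) {
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0) return(NA_real_)
  ang <- 2 * pi * phi / period_h
  out <- (atan2(mean(sin(ang)), mean(cos(ang))) * period_h / (2 * pi)) %%
    period_h
  # guard against period-length results from floating-point wrap
  if (period_h - out < 1e-9) out <- 0
  out
}
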