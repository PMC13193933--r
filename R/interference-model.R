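#' Nonlinear aerobic-interference model for rate of force development
#'
#' Constructs and validates the parameter set of the interference model. The
#' model predicts post-exercise rate of force development (RFD) after a single
#' bout of aerobic exercise of duration `d` minutes as
#'
#' \deqn{RFD(d) = RFD_0 \left[1 - \kappa \left(1 - e^{-\alpha (d - d_0)_+}\right)\right]}
#'
#' where \eqn{(x)_+ = \max(x, 0)}. Below the onset delay `d0` no decline is
#' predicted; as `d` grows the prediction approaches the floor
#' \eqn{RFD_0 (1 - \kappa)}.
#'
#' @param rfd0 Baseline peak rate of force development, N/s. Strictly positive.
#' @param kappa Scaling factor: maximal fractional RFD reduction, in \[0, 1\].
#'   The default 0.8 caps the loss at 80% of baseline.
#' @param alpha Rate constant, per minute: steepness of interference onset.
#'   Non-negative.
#' @param d0 Onset delay, minutes: duration at or below which no decline is
#'   predicted. Non-negative and at most `d_max`.
#' @param d_max Upper end of the supported duration domain, minutes.
#'   Predictions beyond it are extrapolations and draw a warning.
#'
#' @return An object of class `interference_model`: a list with components
#'   `rfd0`, `kappa`, `alpha`, `d0`, `d_max`.
#'
#' @examples
#' m <- interference_model()
#' predict(m, durations = 10)          # about 4088.6 N/s
#' percent_loss(10, m)                 # about 72.7 percent
#' @export
interference_model <- function(rfd0 = 15000, kappa = 0.8, alpha = 0.3,
                               d0 = 2, d_max = 60) {
  check_scalar(rfd0, "rfd0")
  check_scalar(kappa, "kappa")
  check_scalar(alpha, "alpha")
  check_scalar(d0, "d0")
  check_scalar(d_max, "d_max")
  if (rfd0 <= 0)
    stop("invalid parameter 'rfd0': must be strictly positive, got ", rfd0,
         call. = FALSE)
  if (kappa < 0 || kappa > 1)
    stop("invalid parameter 'kappa': must lie in [0, 1], got ", kappa,
         call. = FALSE)
  if (alpha < 0)
    stop("invalid parameter 'alpha': must be non-negative, got ", alpha,
         call. = FALSE)
  if (d0 < 0)
    stop("invalid parameter 'd0': must be non-negative, got ", d0,
         call. = FALSE)
  if (d_max <= d0)
    stop("invalid parameter 'd_max': must exceed d0 (", d0, "), got ", d_max,
         call. = FALSE)
  structure(
    list(rfd0 = rfd0, kappa = kappa, alpha = alpha, d0 = d0, d_max = d_max),
    class = "interference_model"
  )
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("invalid parameter '", name, "': must be a finite numeric scalar",
         call. = FALSE)
  invisible(TRUE)
}

check_durations <- function(d, model, allow_empty = FALSE) {
  if (!is.numeric(d))
    stop("durations must be numeric", call. = FALSE)
  if (!allow_empty && length(d) == 0L)
    stop("durations must be non-empty", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("durations must be finite; got NA or Inf", call. = FALSE)
  bad <- which(d < 0)
  if (length(bad))
    stop("negative duration not allowed: d = ", d[bad[1L]],
         " (element ", bad[1L], ")", call. = FALSE)
  over <- which(d > model$d_max)
  if (length(over))
    warning("duration ", d[over[1L]], " min exceeds the supported domain (0-",
            model$d_max, " min); the prediction is an extrapolation",
            call. = FALSE)
  invisible(TRUE)
}

#' Predict post-exercise RFD
#'
#' Evaluates the nonlinear interference equation at one or more aerobic
#' exercise durations.
#'
#' @param d Aerobic exercise duration(s), minutes. Non-negative; values above
#'   the model's `d_max` are accepted with an extrapolation warning.
#' @param model An [interference_model()].
#' @return Predicted RFD in N/s, same length as `d`, full double precision.
#' @examples
#' predict_rfd(10, interference_model())   # 4088.615...
#' @export
predict_rfd <- function(d, model = interference_model()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(d, model)
  model$rfd0 * (1 - model$kappa * (1 - exp(-model$alpha * pmax(d - model$d0, 0))))
}

#' Percent loss of RFD after aerobic exercise
#'
#' The fractional RFD reduction in percent,
#' \eqn{100 \kappa (1 - e^{-\alpha (d - d_0)_+})}. Independent of the baseline
#' `rfd0`.
#'
#' @inheritParams predict_rfd
#' @return Percent loss in \[0, 100*kappa\], same length as `d`.
#' @export
percent_loss <- function(d, model = interference_model()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(d, model)
  100 * model$kappa * (1 - exp(-model$alpha * pmax(d - model$d0, 0)))
}

#' Linear comparison variant of the interference model
#'
#' A straight-line decline anchored at the same endpoints as the nonlinear
#' model: `rfd0` at `d = d0` and the floor `rfd0 * (1 - kappa)` at `d = d_max`,
#' clamped constant outside that interval. Used to contrast linear against
#' exponential loss of RFD.
#'
#' @inheritParams predict_rfd
#' @return Predicted RFD in N/s under the linear decline, same length as `d`.
#' @export
predict_linear <- function(d, model = interference_model()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(d, model)
  floor_rfd <- model$rfd0 * (1 - model$kappa)
  frac <- pmin(pmax((d - model$d0) / (model$d_max - model$d0), 0), 1)
  model$rfd0 - (model$rfd0 - floor_rfd) * frac
}

#' Tabulate predictions over a set of durations
#'
#' Evaluates the model per duration and returns both full-precision and
#' display-rounded values (RFD to the nearest N/s, percent loss to the nearest
#' percent, matching the field's reporting convention).
#'
#' @param durations Non-empty vector of aerobic exercise durations, minutes.
#' @param model An [interference_model()].
#' @return A data frame of class `rfd_prediction_table` with columns
#'   `duration_min`, `predicted_rfd`, `absolute_loss`, `percent_loss`,
#'   `predicted_rfd_rounded`, `percent_loss_rounded`, in input order.
#' @examples
#' predict_table(c(0, 2, 5, 10, 20, 30, 60))
#' @export
predict_table <- function(durations, model = interference_model()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(durations, model)
  rfd <- predict_rfd(durations, model)
  pct <- percent_loss(durations, model)
  out <- data.frame(
    duration_min = durations,
    predicted_rfd = rfd,
    absolute_loss = model$rfd0 - rfd,
    percent_loss = pct,
    predicted_rfd_rounded = round(rfd),
    percent_loss_rounded = round(pct)
  )
  class(out) <- c("rfd_prediction_table", "data.frame")
  out
}

#' Packaged athlete baseline profiles
#'
#' Group-average baseline peak RFD values from isometric mid-thigh pull testing
#' of national-caliber weightlifters, usable as `rfd0` via the `--profile` CLI
#' flag or directly.
#'
#' @return A data frame with columns `label` and `baseline_rfd` (N/s),
#'   containing at least the male (16652 N/s) and female (7663 N/s) group
#'   baselines.
#' @export
athlete_profiles <- function() {
  data.frame(
    label = c("male_national", "female_national"),
    baseline_rfd = c(16652, 7663),
    stringsAsFactors = FALSE
  )
}

#' @export
print.interference_model <- function(x, ...) {
  cat("Aerobic-interference model for rate of force development\n")
  cat(sprintf("  baseline RFD (rfd0) : %g N/s\n", x$rfd0))
  cat(sprintf("  scaling factor kappa: %g (max loss %g%%)\n",
              x$kappa, 100 * x$kappa))
  cat(sprintf("  rate constant alpha : %g per min\n", x$alpha))
  cat(sprintf("  onset delay d0      : %g min\n", x$d0))
  cat(sprintf("  duration domain     : 0-%g min\n", x$d_max))
  invisible(x)
}

#' @export
coef.interference_model <- function(object, ...) {
  c(rfd0 = object$rfd0, kappa = object$kappa, alpha = object$alpha,
    d0 = object$d0, d_max = object$d_max)
}

#' Predict method for interference models
#'
#' @param object An [interference_model()].
#' @param durations Durations in minutes.
#' @param type `"rfd"` for predicted RFD (N/s), `"percent_loss"` for percent
#'   loss, `"linear"` for the linear comparison variant (N/s).
#' @param ... Unused.
#' @return Numeric vector, one value per duration.
#' @export
predict.interference_model <- function(object, durations,
                                       type = c("rfd", "percent_loss", "linear"),
                                       ...) {
  type <- match.arg(type)
  switch(type,
         rfd = predict_rfd(durations, object),
         percent_loss = percent_loss(durations, object),
         linear = predict_linear(durations, object))
}

#' @export
summary.interference_model <- function(object, durations = c(0, 2, 5, 10, 20, 30, 60),
                                       ...) {
  tab <- predict_table(durations, object)
  structure(list(model = object, table = tab),
            class = "summary.interference_model")
}

#' @export
print.summary.interference_model <- function(x, ...) {
  print(x$model)
  cat("\nPredicted RFD by aerobic exercise duration:\n")
  print(x$table)
  invisible(x)
}

#' @export
print.rfd_prediction_table <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  df$predicted_rfd <- round(df$predicted_rfd, digits)
  df$absolute_loss <- round(df$absolute_loss, digits)
  df$percent_loss <- round(df$percent_loss, digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' Plot the interference dose-response
#'
#' Draws predicted RFD (and optionally the linear comparison variant) against
#' aerobic exercise duration.
#'
#' @param x An [interference_model()].
#' @param show_linear Overlay the linear decline variant.
#' @param n Number of grid points across the duration domain.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.interference_model <- function(x, show_linear = FALSE, n = 200, ...) {
  d <- seq(0, x$d_max, length.out = n)
  rfd <- predict_rfd(d, x)
  graphics::plot(d, rfd, type = "l", lwd = 2,
                 xlab = "Aerobic exercise duration (min)",
                 ylab = "Predicted RFD (N/s)", ...)
  if (show_linear) {
    graphics::lines(d, predict_linear(d, x), lty = 2)
    graphics::legend("topright", legend = c("nonlinear", "linear"),
                     lty = c(1, 2), lwd = c(2, 1), bty = "n")
  }
  invisible(x)
}
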