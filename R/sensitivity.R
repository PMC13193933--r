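#' Default sensitivity grids
#'
#' Representative grids bracketing the model's selected values (alpha = 0.3,
#' kappa = 0.8) for coach-facing exploration of athlete-specific
#' susceptibility.
#' @name sweep_defaults
#' @keywords internal
NULL

default_alphas <- function() c(0.05, 0.1, 0.2, 0.3, 0.5)
default_kappas <- function() c(0.2, 0.4, 0.6, 0.8, 1.0)

new_sweep_result <- function(varied_name, varied_values, durations,
                             rfd_grid, percent_grid) {
  structure(list(varied_name = varied_name, varied_values = varied_values,
                 durations = durations, rfd_grid = rfd_grid,
                 percent_grid = percent_grid),
            class = "rfd_sweep")
}

sweep_param <- function(name, values, durations, base) {
  stopifnot(inherits(base, "interference_model"))
  if (length(values) == 0L)
    stop("sweep grid for '", name, "' must be non-empty", call. = FALSE)
  check_durations(durations, base)
  rows <- lapply(values, function(v) {
    args <- unclass(base)
    args[[name]] <- v
    m <- do.call(interference_model, args)
    list(rfd = predict_rfd(durations, m), pct = percent_loss(durations, m))
  })
  rfd_grid <- do.call(rbind, lapply(rows, `[[`, "rfd"))
  pct_grid <- do.call(rbind, lapply(rows, `[[`, "pct"))
  dimnames(rfd_grid) <- dimnames(pct_grid) <-
    list(paste0(name, "=", values), paste0("d=", durations))
  new_sweep_result(name, values, durations, rfd_grid, pct_grid)
}

#' Sensitivity sweep over the decay rate alpha
#'
#' Predicts RFD over a duration grid for each candidate rate constant,
#' holding the other parameters at `base`. At any fixed duration beyond the
#' onset delay, predicted RFD is non-increasing in alpha.
#'
#' @param alphas Non-empty vector of rate constants, per minute, each >= 0.
#' @param durations Duration grid, minutes.
#' @param base The [interference_model()] supplying the non-swept parameters.
#' @return An `rfd_sweep` with matrices `rfd_grid` and `percent_grid` of
#'   dimension `length(alphas) x length(durations)`.
#' @examples
#' sweep_alpha(c(0.1, 0.3, 0.5), durations = c(5, 10, 20))
#' @export
sweep_alpha <- function(alphas = default_alphas(),
                        durations = 0:60,
                        base = interference_model()) {
  if (length(alphas) && any(alphas < 0))
    stop("invalid parameter 'alpha': must be non-negative", call. = FALSE)
  sweep_param("alpha", alphas, durations, base)
}

#' Sensitivity sweep over the scaling factor kappa
#'
#' Predicts RFD over a duration grid for each candidate maximal-loss scaling
#' factor. The large-duration limit of each row is `rfd0 * (1 - kappa)`.
#'
#' @param kappas Non-empty vector of scaling factors, each in \[0, 1\].
#' @inheritParams sweep_alpha
#' @return An `rfd_sweep`, as for [sweep_alpha()].
#' @export
sweep_kappa <- function(kappas = default_kappas(),
                        durations = 0:60,
                        base = interference_model()) {
  if (length(kappas) && any(kappas < 0 | kappas > 1))
    stop("invalid parameter 'kappa': must lie in [0, 1]", call. = FALSE)
  sweep_param("kappa", kappas, durations, base)
}

#' Compare nonlinear and linear decline side by side
#'
#' Pairs the exponential interference prediction with the anchored linear
#' variant at each duration. Because the exponential lies below its chord,
#' the nonlinear prediction never exceeds the linear one on the open interval
#' between the anchors.
#'
#' @param durations Duration grid, minutes.
#' @param model An [interference_model()].
#' @return A data frame with columns `duration_min`, `nonlinear_rfd`,
#'   `linear_rfd`.
#' @export
compare_decay_models <- function(durations, model = interference_model()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(durations, model)
  data.frame(duration_min = durations,
             nonlinear_rfd = predict_rfd(durations, model),
             linear_rfd = predict_linear(durations, model))
}

#' @export
print.rfd_sweep <- function(x, ...) {
  cat("Sensitivity sweep over", x$varied_name, "\n")
  cat("  values :", paste(x$varied_values, collapse = ", "), "\n")
  cat("  grid   :", length(x$varied_values), "x", length(x$durations),
      "(parameter x duration)\n")
  cat("  duration range:", min(x$durations), "-", max(x$durations), "min\n")
  invisible(x)
}

#' Long-format serialization of a sweep
#'
#' @param x An `rfd_sweep`.
#' @param ... Unused.
#' @return A data frame with columns `varied_name`, `varied_value`,
#'   `duration_min`, `rfd`, `percent_loss`, one row per grid cell.
#' @export
as.data.frame.rfd_sweep <- function(x, ...) {
  nv <- length(x$varied_values)
  nd <- length(x$durations)
  data.frame(
    varied_name = rep(x$varied_name, nv * nd),
    varied_value = rep(x$varied_values, each = nd),
    duration_min = rep(x$durations, times = nv),
    rfd = as.vector(t(x$rfd_grid)),
    percent_loss = as.vector(t(x$percent_grid))
  )
}

#' @export
plot.rfd_sweep <- function(x, ...) {
  graphics::matplot(x$durations, t(x$rfd_grid), type = "l", lty = 1,
                    xlab = "Aerobic exercise duration (min)",
                    ylab = "Predicted RFD (N/s)", ...)
  graphics::legend("topright", legend = rownames(x$rfd_grid),
                   col = seq_along(x$varied_values), lty = 1, bty = "n")
  invisible(x)
}
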