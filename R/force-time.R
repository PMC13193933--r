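#' Sampling parameters for simulated isometric mid-thigh pull curves
#'
#' @param peak_force Asymptotic plateau force, N. Default 4000 N, a typical
#'   IMTP peak force. Strictly positive.
#' @param t_end Simulated pull duration, seconds.
#' @param dt Sampling interval, seconds; the default 0.001 s corresponds to a
#'   1000 Hz force plate. Must satisfy `0 < dt < t_end`.
#' @param noise_sd Standard deviation of optional additive Gaussian force
#'   noise, N. Zero (default) gives a noiseless analytic curve.
#' @param seed Integer seed governing noise reproducibility.
#' @return A list of class `curve_params`.
#' @export
curve_params <- function(peak_force = 4000, t_end = 5, dt = 0.001,
                         noise_sd = 0, seed = 42L) {
  check_scalar(peak_force, "peak_force")
  check_scalar(t_end, "t_end")
  check_scalar(dt, "dt")
  check_scalar(noise_sd, "noise_sd")
  if (peak_force <= 0)
    stop("invalid parameter 'peak_force': must be strictly positive",
         call. = FALSE)
  if (dt <= 0 || dt >= t_end)
    stop("invalid parameter 'dt': need 0 < dt < t_end", call. = FALSE)
  if (noise_sd < 0)
    stop("invalid parameter 'noise_sd': must be non-negative", call. = FALSE)
  structure(list(peak_force = peak_force, t_end = t_end, dt = dt,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "curve_params")
}

new_force_time_curve <- function(times, forces, rfd_used = NULL, label = NULL) {
  if (length(times) != length(forces))
    stop("times and forces must have equal length", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 samples",
         call. = FALSE)
  structure(list(times = times, forces = forces,
                 rfd_used = rfd_used, label = label),
            class = "force_time_curve")
}

#' Simulate an isometric mid-thigh pull force-time curve
#'
#' Generates a mono-exponential rise
#' \deqn{F(t) = F_{peak}\,(1 - e^{-(RFD/F_{peak})\,t})}
#' whose analytic derivative at `t = 0` equals `rfd`, so the curve's initial
#' slope carries exactly the (possibly interference-reduced) RFD. Optional
#' additive Gaussian noise is drawn under the seed in `cp`, making curves
#' bit-reproducible.
#'
#' @param rfd Rate of force development generating the initial slope, N/s.
#'   Strictly positive.
#' @param cp A [curve_params()] object.
#' @param label Optional provenance tag, e.g. `"d=10 min"`.
#' @return A `force_time_curve`: list with `times` (s), `forces` (N),
#'   `rfd_used`, `label`.
#' @examples
#' cv <- generate_curve(15000)
#' estimate_rfd_from_curve(cv, window = 0.01)
#' @export
generate_curve <- function(rfd, cp = curve_params(), label = NULL) {
  stopifnot(inherits(cp, "curve_params"))
  if (!is.numeric(rfd) || length(rfd) != 1L || !is.finite(rfd) || rfd <= 0)
    stop("rfd must be a strictly positive finite scalar", call. = FALSE)
  times <- seq(0, cp$t_end, by = cp$dt)
  forces <- cp$peak_force * (1 - exp(-(rfd / cp$peak_force) * times))
  if (cp$noise_sd > 0) {
    noise <- withr_seed(cp$seed, stats::rnorm(length(times), 0, cp$noise_sd))
    forces <- forces + noise
  }
  new_force_time_curve(times, forces, rfd_used = rfd, label = label)
}

# evaluate expr under a local RNG state so simulation never disturbs the
# caller's random stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Family of post-exercise force-time curves
#'
#' One simulated curve per aerobic exercise duration, each generated with
#' `rfd_used = predict_rfd(d, model)`. All curves share the plateau force in
#' `cp`: the interference model acts on the initial slope only.
#'
#' @param durations Non-empty vector of durations, minutes.
#' @param model An [interference_model()].
#' @param cp A [curve_params()].
#' @return A list of `force_time_curve` objects in input order, labelled
#'   `"d=<x> min"`.
#' @export
curve_family <- function(durations, model = interference_model(),
                         cp = curve_params()) {
  stopifnot(inherits(model, "interference_model"))
  check_durations(durations, model)
  rfds <- predict_rfd(durations, model)
  lapply(seq_along(durations), function(i) {
    generate_curve(rfds[i], cp, label = sprintf("d=%g min", durations[i]))
  })
}

#' Estimate RFD from a sampled force-time curve
#'
#' Least-squares slope of force against time over the initial window
#' `[0, window]`. For a noiseless generated curve this recovers the generating
#' RFD up to a small curvature bias of order `(rfd/peak_force) * window / 2`.
#'
#' @param curve A `force_time_curve` (generated or read from file).
#' @param window Length of the initial fitting window, seconds. The 0.02 s
#'   default balances noise averaging against curvature bias.
#' @return Estimated RFD, N/s.
#' @export
estimate_rfd_from_curve <- function(curve, window = 0.02) {
  stopifnot(inherits(curve, "force_time_curve"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("window must be a positive scalar (seconds)", call. = FALSE)
  if (any(diff(curve$times) <= 0))
    stop("curve times must be strictly increasing", call. = FALSE)
  keep <- curve$times >= 0 & curve$times <= window
  if (sum(keep) < 2L)
    stop("need at least 2 samples inside [0, ", window, "] to fit a slope",
         call. = FALSE)
  t <- curve$times[keep]
  f <- curve$forces[keep]
  unname(stats::cov(t, f) / stats::var(t))
}

#' @export
print.force_time_curve <- function(x, ...) {
  cat("Force-time curve")
  if (!is.null(x$label)) cat(" [", x$label, "]", sep = "")
  cat(":", length(x$times), "samples over",
      format(max(x$times)), "s\n")
  if (!is.null(x$rfd_used))
    cat("  generating RFD:", format(x$rfd_used), "N/s\n")
  cat("  force range: [", format(min(x$forces)), ",",
      format(max(x$forces)), "] N\n")
  invisible(x)
}

#' @export
as.data.frame.force_time_curve <- function(x, ...) {
  data.frame(time_s = x$times, force_N = x$forces)
}

#' @export
plot.force_time_curve <- function(x, ...) {
  graphics::plot(x$times, x$forces, type = "l",
                 xlab = "Time (s)", ylab = "Force (N)",
                 main = if (!is.null(x$label)) x$label else "", ...)
  invisible(x)
}

#' Write a force-time curve to a two-column text file
#'
#' Tab-delimited `time_s`/`force_N` with one header line, printed at full
#' double precision so [read_curve()] round-trips bit-exactly.
#'
#' @param curve A `force_time_curve`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_time_curve"))
  lines <- c("time_s\tforce_N",
             sprintf("%.17g\t%.17g", curve$times, curve$forces))
  writeLines(lines, path)
  invisible(path)
}

#' Read a force-time curve from a two-column text file
#'
#' Expects one header line followed by delimited time/force pairs, as written
#' by [write_curve()]. The result carries no `rfd_used` (provenance unknown
#' for external curves).
#'
#' @param path File to read.
#' @return A `force_time_curve`.
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (ncol(df) < 2L)
    stop("curve file must have two columns (time, force)", call. = FALSE)
  new_force_time_curve(df[[1L]], df[[2L]], rfd_used = NULL,
                       label = basename(path))
}
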