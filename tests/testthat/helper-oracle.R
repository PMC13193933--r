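# Independent scalar re-evaluation of the closed-form interference equation,
# used as the oracle against the package's vectorized implementation.
oracle_rfd <- function(d, rfd0 = 15000, kappa = 0.8, alpha = 0.3, d0 = 2) {
  vapply(d, function(di) {
    rfd0 * (1 - kappa * (1 - exp(-alpha * max(di - d0, 0))))
  }, numeric(1))
}

oracle_pct <- function(d, kappa = 0.8, alpha = 0.3, d0 = 2) {
  vapply(d, function(di) {
    100 * kappa * (1 - exp(-alpha * max(di - d0, 0)))
  }, numeric(1))
}

# random but valid parameter draws for property tests
random_model <- function() {
  interference_model(
    rfd0 = stats::runif(1, 1000, 30000),
    kappa = stats::runif(1, 0, 1),
    alpha = stats::runif(1, 0, 1),
    d0 = stats::runif(1, 0, 10),
    d_max = 60
  )
}
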