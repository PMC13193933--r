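test_that("constructor validates parameters and names the offending field", {
  m <- interference_model()
  expect_s3_class(m, "interference_model")
  expect_equal(coef(m),
               c(rfd0 = 15000, kappa = 0.8, alpha = 0.3, d0 = 2, d_max = 60))

  expect_error(interference_model(rfd0 = 0), "rfd0")
  expect_error(interference_model(rfd0 = -5), "rfd0")
  expect_error(interference_model(kappa = 1.5), "kappa")
  expect_error(interference_model(kappa = -0.1), "kappa")
  expect_error(interference_model(alpha = -0.3), "alpha")
  expect_error(interference_model(d0 = -1), "d0")
  expect_error(interference_model(d_max = 1), "d_max")
  expect_error(interference_model(rfd0 = "a"), "rfd0")
})

test_that("predicted RFD reproduces the published worked examples", {
  m <- interference_model()
  expect_equal(round(predict_rfd(10, m), 1), 4088.6)
  expect_equal(round(predict_rfd(10, m)), 4089)
  expect_identical(predict_rfd(2, m), 15000)
  expect_identical(predict_rfd(0, m), 15000)
  expect_equal(round(predict_rfd(5, m)), 7879)
  expect_equal(round(predict_rfd(10, interference_model(rfd0 = 16652)), 1),
               4538.9)
  expect_equal(round(predict_rfd(10, interference_model(rfd0 = 7663)), 1),
               2088.7)
})

test_that("large durations approach the floor rfd0 * (1 - kappa)", {
  m <- interference_model()
  expect_warning(far <- predict_rfd(1000, m), "extrapolation")
  expect_equal(far, 3000, tolerance = 1e-12)
  expect_equal(predict_rfd(60, m), 3000, tolerance = 1e-6)
})

test_that("percent loss matches published values and is rfd0-free", {
  m <- interference_model()
  expect_equal(round(percent_loss(10, m), 1), 72.7)
  expect_equal(round(percent_loss(10, m)), 73)
  expect_identical(percent_loss(0, m), 0)
  expect_equal(round(percent_loss(20, m), 1), 79.6)
  expect_equal(round(percent_loss(20, m)), 80)
  expect_equal(round(percent_loss(9, m), 1), 70.2)

  m2 <- interference_model(rfd0 = 7663)
  expect_equal(percent_loss(c(5, 10, 30), m2), percent_loss(c(5, 10, 30), m))
})

test_that("domain errors and extrapolation warnings fire as specified", {
  m <- interference_model()
  expect_error(predict_rfd(-1, m), "negative duration")
  expect_error(percent_loss(-0.5, m), "negative duration")
  expect_error(predict_rfd(NA_real_, m), "finite")
  expect_warning(predict_rfd(75, m), "extrapolation")
  expect_warning(v <- predict_rfd(75, m), "exceeds the supported domain")
  expect_true(v > 3000 && v < 3000 * 1.01)
})

test_that("linear variant is anchored at the onset delay and at d_max", {
  m <- interference_model()
  expect_identical(predict_linear(2, m), 15000)
  expect_identical(predict_linear(0, m), 15000)
  expect_equal(predict_linear(60, m), 3000)
  # midpoint of the declining segment (2, 60)
  expect_equal(predict_linear(31, m), 9000)
  # oracle: rfd0 - rfd0*kappa*(d - d0)/(d_max - d0)
  expect_equal(predict_linear(10, m), 15000 - 12000 * 8 / 58)
  # clamped constant beyond d_max
  expect_warning(past <- predict_linear(70, m), "extrapolation")
  expect_equal(past, 3000)
})

test_that("prediction table matches element-wise re-evaluation and keeps order", {
  m <- interference_model()
  d <- c(30, 0, 10, 5)
  tab <- predict_table(d, m)
  expect_s3_class(tab, "rfd_prediction_table")
  expect_equal(tab$duration_min, d)
  expect_equal(tab$predicted_rfd, oracle_rfd(d))
  expect_equal(tab$percent_loss, oracle_pct(d))
  expect_equal(tab$absolute_loss, 15000 - oracle_rfd(d))
  expect_equal(tab$predicted_rfd_rounded, round(oracle_rfd(d)))

  single <- predict_table(10, m)
  expect_equal(single$predicted_rfd, predict_rfd(10, m))

  expect_error(predict_table(numeric(0), m), "non-empty")
  expect_error(predict_table(c(5, -3), m), "-3")
})

test_that("identity, monotonicity, floor and homogeneity hold over random models", {
  set.seed(101)
  d_grid <- seq(0, 60, by = 0.5)
  for (i in 1:25) {
    m <- random_model()
    rfd <- predict_rfd(d_grid, m)
    # identity region
    below <- d_grid <= m$d0
    expect_identical(rfd[below], rep(m$rfd0, sum(below)))
    # monotone non-increasing
    expect_true(all(diff(rfd) <= 1e-9))
    # strictly decreasing past d0 when alpha, kappa > 0 (until the
    # exponential term is no longer resolvable in double precision)
    if (m$alpha > 0 && m$kappa > 0) {
      floor_rfd <- m$rfd0 * (1 - m$kappa)
      above <- d_grid > m$d0 & rfd > floor_rfd * (1 + 1e-12) + 1e-9
      expect_true(all(diff(rfd[above]) < 0))
    }
    # floor
    expect_true(all(rfd >= m$rfd0 * (1 - m$kappa) - 1e-9))
    # homogeneity in rfd0
    c_scale <- stats::runif(1, 0.5, 3)
    m2 <- interference_model(rfd0 = c_scale * m$rfd0, kappa = m$kappa,
                             alpha = m$alpha, d0 = m$d0, d_max = m$d_max)
    expect_equal(predict_rfd(d_grid, m2), c_scale * rfd)
    expect_equal(percent_loss(d_grid, m2), percent_loss(d_grid, m))
  }
})

test_that("kappa = 0 or alpha = 0 give a constant prediction at baseline", {
  d <- c(0, 5, 30, 60)
  expect_identical(predict_rfd(d, interference_model(kappa = 0)),
                   rep(15000, 4))
  expect_identical(predict_rfd(d, interference_model(alpha = 0)),
                   rep(15000, 4))
  expect_identical(percent_loss(d, interference_model(alpha = 0)), rep(0, 4))
})

test_that("prediction results are self-consistent and bounded", {
  m <- interference_model()
  tab <- predict_table(seq(0, 60, by = 3), m)
  expect_equal(tab$predicted_rfd + tab$absolute_loss,
               rep(m$rfd0, nrow(tab)))
  expect_true(all(tab$percent_loss >= 0))
  expect_true(all(tab$percent_loss <= 100 * m$kappa + 1e-9))
})

test_that("athlete profiles carry the published group baselines", {
  prof <- athlete_profiles()
  expect_true(16652 %in% prof$baseline_rfd)
  expect_true(7663 %in% prof$baseline_rfd)
  expect_true(all(prof$baseline_rfd > 0))
  expect_true(nrow(prof) >= 2)
  expect_false(anyDuplicated(prof$label) > 0)
})

test_that("model object methods print, summarise and predict coherently", {
  m <- interference_model()
  expect_output(print(m), "rate of force development")
  expect_output(print(summary(m)), "duration")
  expect_equal(predict(m, 10), predict_rfd(10, m))
  expect_equal(predict(m, 10, type = "percent_loss"), percent_loss(10, m))
  expect_equal(predict(m, 10, type = "linear"), predict_linear(10, m))
})
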