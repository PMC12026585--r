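# power-law cascade module: builders, rates, steady states, stability,
# simulation

test_that("cascade builder enforces structure and counts intermediates", {
  for (n in 3:9) {
    m <- build_end_product_cascade(n, g = 2)
    expect_s3_class(m, "cascade_model")
    expect_identical(m$intermediates, n - 2L)
    # chain structure: equation 1 depends on species 1 and n only,
    # equation i >= 2 on species i-1 and i only
    for (i in seq_len(n)) {
      eq <- m$equations[[i]]
      support <- sort(unique(unlist(lapply(c(eq$production, eq$degradation),
        function(tm) which(tm$exponents$const != 0 | tm$exponents$gcoef != 0)))))
      if (i == 1) expect_identical(support, sort(c(1L, n)))
      else expect_identical(support, sort(c(i - 1L, i)))
    }
  }
  expect_identical(build_end_product_cascade(3, 1)$intermediates, 1L)
  expect_identical(build_end_product_cascade(9, 1)$intermediates, 7L)
  expect_error(build_end_product_cascade(2, 1), "invalid pathway length")
  expect_error(build_end_product_cascade(5, 1, alpha = c(1, 1, -1, 1, 1)),
               "positive")
})

test_that("rate evaluation matches hand arithmetic and the naive oracle", {
  m <- build_end_product_cascade(4, g = 3)
  expect_equal(evaluate_rates(m, rep(1, 4)), rep(0, 4))

  m3 <- build_end_product_cascade(3, g = -1, alpha = c(2, 1, 1))
  r <- evaluate_rates(m3, c(1, 1, 2))
  expect_equal(r[1], 2 * 2^(-1) - 1)          # = 0
  expect_equal(r[2], 0)
  expect_equal(r[3], -1)

  expect_error(evaluate_rates(m3, c(1, -1, 2)), "positive")

  set.seed(42)
  for (rep_ in 1:20) {
    n <- sample(3:7, 1)
    g <- runif(1, 0, 3)
    m <- build_end_product_cascade(n, g = g,
                                   alpha = exp(rnorm(n, 0, 0.4)),
                                   beta = exp(rnorm(n, 0, 0.4)),
                                   h = runif(n, 0.5, 2))
    X <- exp(rnorm(n, 0, 0.5))
    expect_equal(evaluate_rates(m, X), naive_rates(m, X, g), tolerance = 1e-12)
  }
})

test_that("steady states: symmetry, two independent solvers, ODE endpoint", {
  m <- build_end_product_cascade(5, g = 2)
  expect_equal(solve_steady_state(m)$concentrations, rep(1, 5))

  m2 <- build_end_product_cascade(3, g = 1, alpha = c(2, 1, 1))
  ss_lin <- solve_steady_state(m2, method = "loglinear")
  ss_new <- solve_steady_state(m2, method = "newton")
  expect_lt(max(abs(ss_lin$concentrations - ss_new$concentrations)), 1e-8)
  expect_lt(ss_lin$residual_norm, 1e-10)

  traj <- simulate_cascade(m2, X0 = rep(1, 3),
                           t_grid = c(0, 10^seq(0, 3, length.out = 40)))
  expect_lt(max(abs(traj[nrow(traj), -1] - ss_lin$concentrations)), 1e-6)
})

test_that("fixed-point consistency holds for 100 random stable models", {
  set.seed(7)
  for (rep_ in 1:100) {
    n <- sample(3:7, 1)
    m <- build_end_product_cascade(n, g = runif(1, 0, 1.5),
                                   alpha = exp(rnorm(n, 0, 0.3)),
                                   beta = exp(rnorm(n, 0, 0.3)),
                                   h = runif(n, 0.8, 1.5))
    ss <- solve_steady_state(m)
    expect_lt(max(abs(evaluate_rates(m, ss$concentrations))), 1e-8)
  }
})

test_that("simulation: fixed point stays fixed, stable endpoint, overshoot", {
  m <- build_end_product_cascade(7, g = 1)
  ss <- solve_steady_state(m)
  tg <- seq(0, 50, length.out = 60)

  flat <- simulate_cascade(m, X0 = ss$concentrations, t_grid = tg)
  expect_lt(max(abs(t(flat[, -1]) - ss$concentrations)), 1e-7)

  traj <- simulate_cascade(m, X0 = 0.5 * ss$concentrations,
                           t_grid = seq(0, 300, length.out = 300))
  expect_true(all(traj[, -1] > 0))
  expect_lt(max(abs(traj[nrow(traj), -1] - ss$concentrations) /
                  ss$concentrations), 1e-4)
  # end product rises above its final level before settling back
  xn <- traj[, 8]
  expect_gt(max(xn), xn[length(xn)] + 1e-3)
  expect_lt(which.max(xn), length(xn))
})

test_that("linearization classifies stability and matches eigen oracles", {
  # no feedback: relaxation chain, real negative spectrum
  m0 <- build_end_product_cascade(3, g = 0)
  rep0 <- linearize_and_classify(m0)
  expect_identical(rep0$classification, "stable")
  expect_true(all(abs(Im(rep0$eigenvalues)) < 1e-9))
  expect_true(all(Re(rep0$eigenvalues) < 0))

  # symmetric rates: (lambda + 1)^n = -g closed form
  m1 <- build_end_product_cascade(3, g = -1)
  rep1 <- linearize_and_classify(m1)
  expect_identical(rep1$classification, "stable")
  ev <- sort(Re(rep1$eigenvalues))
  oracle <- sort(Re(closed_form_eigen(3, 1)))
  expect_equal(ev, oracle, tolerance = 1e-8)

  # sweeping |g| up crosses from stable to oscillatory at sec(pi/n)^n
  for (n in c(3, 7)) {
    m <- build_end_product_cascade(n, g = NA)
    thr <- stability_threshold(m)
    expect_lt(abs(thr - closed_form_threshold(n)), 1e-2)
    expect_identical(linearize_and_classify(m, thr - 0.1)$classification,
                     "stable")
    expect_identical(linearize_and_classify(m, thr + 0.1)$classification,
                     "unstable_oscillatory")
  }
})

test_that("model JSON and trajectory CSV round-trip", {
  m <- build_end_product_cascade(5, g = 3, alpha = c(2, 1, 1, 1, 1))
  f <- tempfile(fileext = ".json")
  write_cascade_json(m, f)
  m2 <- read_cascade_json(f)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$g, 3)

  ms <- build_end_product_cascade(4, g = NA)
  f2 <- tempfile(fileext = ".json")
  write_cascade_json(ms, f2)
  expect_true(read_cascade_json(f2)$symbolic)

  traj <- simulate_cascade(m, X0 = rep(1, 5), t_grid = c(0, 1, 2))
  fc <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, fc)
  back <- utils::read.csv(fc)
  expect_identical(names(back), c("t", paste0("X", 1:5)))
  expect_equal(as.matrix(back), traj, ignore_attr = TRUE)
})
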