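# Closed-form module and network onset distributions.

test_that("single-module bracket equals the phase-type hitting-time oracle", {
  # frozen reference point, oracle = explicit Exp(tau)/Exp(T) convolution
  spec <- module_spec(tau = 8, T = 1240, F = 0.63)
  expect_equal(module_permissive_cdf(spec, 30),
               phase_type_cdf(8, 1240, 0.63, 30), tolerance = 1e-14)
  # property over random parameter draws
  set.seed(42)
  for (k in 1:100) {
    tau <- runif(1, 0.5, 30)
    T <- tau * exp(runif(1, 0.5, 8))
    F <- runif(1)
    x <- runif(1, 0, 120)
    expect_equal(module_permissive_cdf(module_spec(tau, T, F), x),
                 phase_type_cdf(tau, T, F, x), tolerance = 1e-12)
  }
})

test_that("module permissive probability is a proper CDF for naive-protective modules", {
  spec <- module_spec(tau = 8, T = 1240, F = 0.63)
  x <- seq(0, 2000, by = 0.5)
  p <- module_permissive_cdf(spec, x)
  expect_identical(p[1], 0)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(module_permissive_cdf(spec, 1e6), 1, tolerance = 1e-12)
  # low-propensity module: mixture weights can leave (0,1) but the CDF must not
  spec2 <- module_spec(tau = 10, T = 30, F = 0.05)
  p2 <- module_permissive_cdf(spec2, x)
  expect_true(all(diff(p2) >= 0))
  expect_true(all(p2 >= 0 & p2 <= 1))
})

test_that("naive-permissive modules start permissive and drain to protective", {
  spec <- module_spec(tau = 8, T = 100, F = 0.4, naive_state = "permissive")
  expect_identical(module_permissive_cdf(spec, 0), 1)
  x <- seq(0, 3000, by = 1)
  p <- module_permissive_cdf(spec, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(module_permissive_cdf(spec, 3000), 1e-10)
  # Monte-Carlo check of the derived closed form (3-state chain)
  set.seed(7)
  n <- 2e5
  a <- rexp(n, 1 / 8)
  perm <- runif(n) < 0.4
  fail <- rexp(n, 1 / 100)   # mature permissive -> protective
  for (xx in c(5, 20, 60)) {
    mc <- mean(a > xx | (perm & a + fail > xx))
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(module_permissive_cdf(spec, xx) - mc), 3 * se)
  }
})

test_that("general-model CDF is the product of module brackets", {
  m1 <- module_spec(tau = 8, T = 1240, F = 0.63)
  m2 <- module_spec(tau = 15, T = 400, F = 0.4)
  x <- c(0, 5, 20, 50, 90)
  expect_equal(cdf_general(general_model(list(m1)), x),
               module_permissive_cdf(m1, x))
  expect_equal(cdf_general(general_model(list(m1, m2)), x),
               module_permissive_cdf(m1, x) * module_permissive_cdf(m2, x))
  # homogeneous network collapses to the N-th power form
  p <- ref_params()
  mods <- replicate(12, module_spec(8, 1240, 0.63), simplify = FALSE)
  grid <- seq(0, 100, by = 0.5)
  expect_lt(max(abs(cdf_general(general_model(mods), grid) -
                    cdf_homogenized(p, grid))), 1e-12)
})

test_that("homogenized CDF limits and monotonicity", {
  p <- ref_params()
  expect_identical(cdf_homogenized(p, 0), 0)
  grid <- seq(0, 100, by = 1)
  expect_true(all(diff(cdf_homogenized(p, grid)) >= 0))
  # immortal-protective limit: lifetime plateau Phi^N
  pinf <- homogenized_params(N = 12, tau = 8, T = Inf, Phi = 0.63)
  expect_equal(cdf_homogenized(pinf, 1e7), 0.63^12, tolerance = 1e-12)
  # explicit limit branch engages for astronomically large finite T and is
  # continuous with the finite-T formula across the switchover
  pswitch <- homogenized_params(N = 12, tau = 8, T = 1e13, Phi = 0.63)
  expect_identical(cdf_homogenized(pswitch, 50), cdf_homogenized(pinf, 50))
  pbig <- homogenized_params(N = 12, tau = 8, T = 8e11, Phi = 0.63)
  expect_equal(cdf_homogenized(pbig, 50), cdf_homogenized(pinf, 50),
               tolerance = 1e-7)
  # higher propensity -> higher CDF; more modules -> lower CDF
  for (x in c(10, 30, 60)) {
    expect_gt(cdf_homogenized(homogenized_params(12, 8, 1240, 0.75), x),
              cdf_homogenized(p, x))
    expect_lt(cdf_homogenized(homogenized_params(13, 8, 1240, 0.63), x),
              cdf_homogenized(p, x))
  }
})

test_that("incidence rate is the analytic derivative of the onset CDF", {
  p <- ref_params()
  expect_identical(incidence_rate(p, 0), 0)
  # numerical (5-point stencil) agreement across the age range
  h <- 1e-4
  xs <- seq(0.1, 90, by = 0.1)
  f <- function(x) cdf_homogenized(p, x)
  num <- (-f(xs + 2 * h) + 8 * f(xs + h) - 8 * f(xs - h) + f(xs - 2 * h)) / (12 * h)
  expect_lt(max(abs(num - incidence_rate(p, xs)) / pmax(abs(num), 1e-300)), 1e-6)
  # single-module immortal limit: pure exponential density
  p1 <- homogenized_params(N = 1, tau = 8, T = Inf, Phi = 1)
  xv <- c(0, 1, 10, 40)
  expect_equal(incidence_rate(p1, xv), exp(-xv / 8) / 8, tolerance = 1e-12)
  # a single interior maximum, located where the numeric optimizer puts it
  opt <- optimize(function(x) incidence_rate(p, x), c(0, 90), maximum = TRUE)
  ic <- incidence_rate(p, 0:90)
  expect_equal(which.max(ic) - 1, round(opt$maximum), tolerance = 1)
  pk <- detect_second_peak(ic, 0:90)
  expect_identical(pk$n_peaks, 1L)
})

test_that("incidence_curve scales the rate for registry comparison", {
  p <- ref_params()
  expect_identical(incidence_curve(p, numeric(0)), numeric(0))
  ages <- 0:90
  expect_equal(incidence_curve(p, ages, scale = 1), incidence_rate(p, ages))
  expect_equal(max(incidence_curve(p, ages)), 1e5 * max(incidence_rate(p, ages)))
  # bin-averaged evaluation matches the exact bin average (CDF increment)
  lo <- seq(0, 85, 5); hi <- seq(5, 90, 5)
  ba <- incidence_bin_average(p, lo, hi)
  exact <- (cdf_homogenized(p, hi) - cdf_homogenized(p, lo)) / 5 * 1e5
  expect_lt(max(abs(ba - exact) / pmax(exact, 1e-8)), 1e-3)
  # midpoint and bin average agree where the curve is locally near-linear
  mid <- incidence_curve(p, (lo + hi) / 2)
  sel <- lo >= 10 & lo <= 60
  expect_lt(max(abs(ba[sel] - mid[sel]) / mid[sel]), 0.05)
})

test_that("parameter containers validate and serialize", {
  expect_error(module_spec(tau = -1, T = 100, F = 0.5), "tau")
  expect_error(module_spec(tau = 8, T = 5, F = 0.5), "exceed")
  expect_error(module_spec(tau = 8, T = 100, F = 1.2), "0, 1")
  expect_error(homogenized_params(N = 2.5, tau = 8, T = 100, Phi = 0.5), "integer")
  expect_error(cdf_homogenized(ref_params(), -1), "nonnegative")
  p <- ref_params()
  expect_equal(params_from_list(params_to_list(p)), p)
  expect_error(params_from_list(list(N = 12, tau = 8)), "Phi")
})
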