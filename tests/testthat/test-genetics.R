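# Odds-ratio <-> module-disease-propensity mapping and the induced MDP
# density.

test_that("the null allele is a fixed point: OR = 1 maps to F = Phi", {
  for (p in c(0.01, 0.3, 0.9)) {
    expect_equal(or_from_mdp(0.63, p, 0.63), 1, tolerance = 1e-14)
    expect_identical(mdp_from_or(1, p, 0.63), 0.63)
  }
})

test_that("rare-allele limits hold", {
  expect_equal(or_from_mdp(0.5, 1e-9, 0.63), 0.5 / 0.63, tolerance = 1e-6)
  expect_equal(mdp_from_or(1.2, 1e-9, 0.63), 1.2 * 0.63, tolerance = 1e-6)
})

test_that("or_from_mdp and mdp_from_or are mutually inverse", {
  set.seed(11)
  done <- 0L
  while (done < 1000L) {
    phi <- runif(1, 0.2, 0.9)
    p <- runif(1, 0.01, 0.99)
    F <- runif(1)
    if (phi - (2 * p - p^2) * F <= 1e-6) next
    v <- or_from_mdp(F, p, phi)
    expect_equal(mdp_from_or(v, p, phi), F, tolerance = 1e-12)
    done <- done + 1L
  }
  # and on the OR side
  expect_equal(or_from_mdp(mdp_from_or(1.3, 0.25, 0.63), 0.25, 0.63), 1.3,
               tolerance = 1e-12)
})

test_that("odds ratios are monotone in the propensity and domain errors are explicit", {
  F <- seq(0.05, 0.9, by = 0.05)
  ors <- or_from_mdp(F, 0.3, 0.63)
  expect_true(all(diff(ors) > 0))
  expect_error(or_from_mdp(0.99, 0.9, 0.5), "undefined")
  expect_error(mdp_from_or(50, 0.05, 0.9), "exceeds 1")
  expect_error(or_from_mdp(0.5, 1.2, 0.63), "raf")
})

test_that("the carrier-contrast odds ratio matches a cohort simulation", {
  # one-locus model: carriers have module MDP F, non-carriers F_P chosen so
  # the population mean is Phi; disease risk proportional to the module MDP
  F <- 0.75; p <- 0.3; phi <- 0.63
  carrier_rate <- 1 - (1 - p)^2
  F_P <- (phi - carrier_rate * F) / (1 - carrier_rate)
  k <- 0.02                      # rare-disease scale
  set.seed(20)
  n <- 2e6
  carrier <- runif(n) < carrier_rate
  disease <- runif(n) < k * ifelse(carrier, F, F_P)
  tab <- table(carrier, disease)
  storage.mode(tab) <- "double"
  or_sim <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_sim) - log(or_from_mdp(F, p, phi))), 3 * se_log)
})

test_that("the MDP density concentrates near Phi and matches Monte Carlo", {
  nu <- or_distribution("lognormal", meanlog = log(1.1), sdlog = 0.15)
  rho <- raf_distribution("beta", 2, 2)
  phi <- 0.63
  # the density has an integrable log-cusp exactly at Phi (the OR = 1
  # contour), so integrals and comparisons use fine/bin-averaged grids
  fine <- seq(0.3, 0.99, length.out = 8000)
  gf <- mdp_density(nu, rho, phi, grid = fine)
  hf <- diff(fine[1:2])
  expect_lt(abs(sum(gf$density) * hf - 1), 1e-3)
  near <- abs(gf$grid - phi) < 0.08
  expect_gt(sum(gf$density[near]) * hf, 0.85)
  expect_lt(abs(gf$grid[which.max(gf$density)] - phi), 0.02)
  # change-of-variables Monte-Carlo oracle vs bin-averaged quadrature
  nb <- 120
  brk <- seq(0.35, 0.95, length.out = nb + 1)
  h <- diff(brk[1:2])
  sub <- (seq_len(11) - 0.5) / 11
  pts <- sort(as.vector(outer(sub * h, brk[-length(brk)], "+")))
  gq <- mdp_density(nu, rho, phi, grid = pts)
  q_avg <- colMeans(matrix(gq$density, nrow = 11))
  set.seed(9)
  n <- 1e6
  draws_or <- r_or(nu, n); draws_p <- r_raf(rho, n)
  Fd <- draws_or * phi / ((1 - draws_p)^2 + draws_or * (2 * draws_p - draws_p^2))
  keep <- Fd >= brk[1] & Fd <= brk[nb + 1]
  dens_mc <- hist(Fd[keep], breaks = brk, plot = FALSE)$density * mean(keep)
  expect_lt(max(abs(dens_mc - q_avg)) / max(q_avg), 0.02)
})

test_that("a point mass at OR = 1 induces a point mass at Phi", {
  g <- mdp_density(or_distribution("point", value = 1),
                   raf_distribution("beta"), 0.63,
                   grid = seq(0.3, 0.9, length.out = 200))
  h <- diff(g$grid[1:2])
  expect_lt(abs(g$grid[which.max(g$density)] - 0.63), h)
  expect_gt(max(g$density) * h, 0.99)
})

test_that("GWAS power behaves like a two-proportion test and corrects histograms", {
  # monotone in effect size and sample size
  expect_lt(gwas_power(1.05, 0.3), gwas_power(1.5, 0.3))
  expect_lt(gwas_power(1.2, 0.3, n_cases = 2000, n_controls = 3000),
            gwas_power(1.2, 0.3, n_cases = 50000, n_controls = 50000))
  expect_gt(gwas_power(3, 0.3, n_cases = 50000, n_controls = 50000), 0.999)
  # identity correction
  raw <- or_distribution("histogram", breaks = c(1, 1.1, 1.2, 1.4),
                         weights = c(3, 2, 1))
  same <- correct_or_distribution(raw, power_fn = function(x) rep(1, length(x)))
  expect_equal(same$weights, raw$weights)
  # analytic two-bin reweighting: powers (0.5, 1) -> masses (2/3, 1/3)
  two <- or_distribution("histogram", breaks = c(1, 1.2, 1.4), weights = c(1, 1))
  corr <- correct_or_distribution(two, power_fn = function(x) c(0.5, 1))
  expect_equal(corr$weights, c(2 / 3, 1 / 3))
  expect_error(correct_or_distribution(two, power_fn = function(x) c(0, 1)),
               "zero detection power")
})

test_that("power thinning is undone by the inverse-power correction", {
  # sample loci from a known OR histogram, thin by detection power, correct
  truth <- or_distribution("histogram",
                           breaks = exp(seq(log(1.1), log(1.8), length.out = 7)),
                           weights = c(6, 5, 4, 3, 2, 1))
  # detection power as a function of OR alone (risk-allele frequencies
  # integrated out), used both to thin and to correct: the correction then
  # inverts the thinning in expectation
  p_grid <- seq(0.02, 0.98, length.out = 49)
  w_rho <- dbeta(p_grid, 2, 2); w_rho <- w_rho / sum(w_rho)
  pow_or <- function(orv) vapply(orv, function(o)
    sum(w_rho * gwas_power(o, p_grid, n_cases = 20000, n_controls = 20000)),
    numeric(1))
  set.seed(31)
  n <- 1e4
  ors <- r_or(truth, n)
  # thin at bin-level power, the resolution at which the correction
  # operates (per-locus power varies within a bin; that residual bias is a
  # documented limitation of histogram-level correction)
  mids <- (truth$breaks[-1] + truth$breaks[-7]) / 2
  pw_bin <- pow_or(mids)[findInterval(ors, truth$breaks, rightmost.closed = TRUE)]
  detected <- ors[runif(n) < pw_bin]
  raw <- or_distribution("histogram", breaks = truth$breaks,
                         weights = tabulate(findInterval(detected, truth$breaks,
                                                         rightmost.closed = TRUE),
                                            nbins = 6))
  corr <- correct_or_distribution(raw, power_fn = pow_or)
  # bootstrap SE of each corrected bin mass
  B <- 200
  boots <- replicate(B, {
    res <- sample(detected, length(detected), replace = TRUE)
    w <- tabulate(findInterval(res, truth$breaks, rightmost.closed = TRUE),
                  nbins = 6)
    correct_or_distribution(
      or_distribution("histogram", breaks = truth$breaks, weights = w),
      power_fn = pow_or)$weights
  })
  se <- apply(boots, 1, sd)
  expect_true(all(abs(corr$weights - truth$weights) <= 3 * pmax(se, 1e-3)))
})
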