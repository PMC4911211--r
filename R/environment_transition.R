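# Secular change of age-specific and annual incidence while an
# environmental risk factor spreads through the population around calendar
# time t50.
#
# The transition model is a reconstruction built from three explicit,
# separately swappable ingredients:
#  * exposure rollout: logistic in calendar time, half the population
#    exposed at t50, scale = transition_width;
#  * exposure -> propensity coupling: a module stabilizing at calendar time
#    t adopts the exposed propensity Phi2 with probability equal to the
#    exposure fraction at t, else the baseline Phi1;
#  * transient destabilization: during a destabilized era (calendar
#    interval t50 + destab_window), mature protective modules fail at the
#    faster rate 1/T_star instead of 1/T. The default era runs from t50
#    forward for four decades, the time course over which registry fits
#    show the apparent T depressed during an outbreak before modules
#    re-stabilize; strategy "exposed" additionally gates the excess rate by
#    the exposure fraction, "none" disables it.
# See the methods vignette for the rationale behind each choice.

#' Define an environmental-transition scenario
#'
#' @param N,tau,T Stationary network parameters as in
#'   \code{\link{homogenized_params}} (T is the failure time outside the
#'   destabilized era).
#' @param Phi1 Module disease propensity before exposure.
#' @param Phi2 Propensity under exposure; must satisfy
#'   \code{Phi1 <= Phi2} (the risk factor is adverse).
#' @param T_star Transiently reduced failure time (years) during the
#'   destabilized era; must not exceed \code{T}.
#' @param t50 Calendar time at which half the population is exposed.
#' @param transition_width Logistic time scale of the exposure rollout
#'   (years; default 10).
#' @param destab_window Destabilized era as \code{c(start, end)} in years
#'   relative to \code{t50} (default \code{c(0, 40)}: the four decades
#'   following t50).
#' @param destab_strategy \code{"all"} (default): every mature protective
#'   module fails at 1/T_star inside the era; \code{"exposed"}: the excess
#'   failure rate is additionally scaled by the exposure fraction, so only
#'   the (newly) exposed part of the population is destabilized;
#'   \code{"none"}: no destabilization (T_star ignored).
#' @param decade_offsets Calendar offsets (years relative to t50) at which
#'   cross-sectional curves are computed (default -20 to +50 by decade).
#' @param age_grid Ages (years) for the cross-sectional curves (default
#'   0:90).
#' @return An object of class \code{transition_scenario}.
#' @export
transition_scenario <- function(N = 12, tau = 8, T = 1240,
                                Phi1 = 0.51, Phi2 = 0.63, T_star = 350,
                                t50 = 0, transition_width = 10,
                                destab_window = c(0, 40),
                                destab_strategy = c("all", "exposed", "none"),
                                decade_offsets = seq(-20, 50, by = 10),
                                age_grid = 0:90) {
  destab_strategy <- match.arg(destab_strategy)
  base <- homogenized_params(N = N, tau = tau, T = T, Phi = Phi1)
  if (Phi2 < Phi1 || Phi2 > 1) stop("'Phi2' must lie in [Phi1, 1]")
  if (T_star > T) stop("'T_star' must not exceed 'T'")
  if (T_star <= tau) stop("'T_star' must exceed 'tau'")
  if (transition_width <= 0) stop("'transition_width' must be positive")
  if (length(destab_window) != 2L || destab_window[1] >= destab_window[2])
    stop("'destab_window' must be c(start, end) with start < end")
  if (any(age_grid < 0) || (length(age_grid) > 1 && any(diff(age_grid) <= 0)))
    stop("'age_grid' must be nonnegative and strictly increasing")
  structure(list(base = base, Phi2 = Phi2, T_star = T_star, t50 = t50,
                 transition_width = transition_width,
                 destab_window = destab_window,
                 destab_strategy = destab_strategy,
                 decade_offsets = decade_offsets, age_grid = age_grid),
            class = "transition_scenario")
}

#' @export
print.transition_scenario <- function(x, ...) {
  cat(sprintf(paste0("Environmental-transition scenario: N = %d, tau = %g y, ",
                     "Phi %g -> %g, T = %g y, T* = %g y\n"),
              x$base$N, x$base$tau, x$base$Phi, x$Phi2, x$base$T, x$T_star))
  cat(sprintf("  t50 = %g, rollout width = %g y, destabilized era t50 + [%g, %g] y (strategy '%s')\n",
              x$t50, x$transition_width, x$destab_window[1], x$destab_window[2],
              x$destab_strategy))
  invisible(x)
}

#' Fraction of the population exposed at a calendar time
#'
#' Logistic rollout: 0 in the distant past, 1 in the distant future, and
#' exactly 1/2 at \code{t50}.
#'
#' @param scenario A \code{\link{transition_scenario}}.
#' @param t Calendar time(s).
#' @return Exposure probabilities in (0, 1).
#' @export
exposure_fraction <- function(scenario, t) {
  stopifnot(inherits(scenario, "transition_scenario"))
  stats::plogis((t - scenario$t50) / scenario$transition_width)
}

# destabilized era [w1, w2] in calendar time
.era <- function(scenario) scenario$t50 + scenario$destab_window

# instantaneous failure rate of a mature protective module at calendar t
.failure_rate <- function(scenario, t) {
  base_r <- 1 / scenario$base$T
  if (scenario$destab_strategy == "none") return(rep(base_r, length(t)))
  w <- .era(scenario)
  s <- as.numeric(t >= w[1] & t <= w[2])
  if (scenario$destab_strategy == "exposed") s <- s * exposure_fraction(scenario, t)
  base_r + (1 / scenario$T_star - base_r) * s
}

# integral of the destabilization intensity s(t) over calendar [lo, hi]
# (vectorized over lo/hi). "all": era overlap length; "exposed": the
# exposure CDF has the closed-form antiderivative w * log(1 + e^{(t-t50)/w}).
.s_integral <- function(scenario, lo, hi) {
  if (scenario$destab_strategy == "none") return(rep(0, length(lo)))
  w <- .era(scenario)
  n <- max(length(lo), length(hi))
  a <- rep_len(pmax(lo, w[1]), n); b <- rep_len(pmin(hi, w[2]), n)
  len <- pmax(0, b - a)
  if (scenario$destab_strategy == "all") return(len)
  tw <- scenario$transition_width
  E_anti <- function(t) tw * log1p(exp((t - scenario$t50) / tw))
  out <- rep(0, n)
  pos <- len > 0
  out[pos] <- E_anti(b[pos]) - E_anti(a[pos])
  out
}

# Integrated failure hazard of a mature protective module from age a to age
# x for an individual born at calendar time b.
.hazard_integral <- function(scenario, b, a, x) {
  base_r <- 1 / scenario$base$T
  (x - a) * base_r +
    (1 / scenario$T_star - base_r) * .s_integral(scenario, b + a, b + x)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal eigenproblem); computed once at load time.
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  bsub <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- bsub
  Jm[cbind(i + 1L, i)] <- bsub
  e <- eigen(Jm, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
}
.gl24 <- .gauss_legendre(24L)

# Per-module permissive probability q_b(x) and its age derivative for the
# cohort born at calendar time b, by quadrature over the stabilization age.
# The integrand has kinks where b + a crosses the era edges, so the
# integration range is split there and 24-point Gauss-Legendre is applied
# per segment.
.cohort_q <- function(scenario, b, x) {
  Phi_at <- function(t) scenario$base$Phi +
    (scenario$Phi2 - scenario$base$Phi) * exposure_fraction(scenario, t)
  if (x <= 0) return(list(q = 0, dq = Phi_at(b) / scenario$base$tau))
  tau <- scenario$base$tau
  w <- .era(scenario)
  brk <- sort(unique(pmin(pmax(c(0, w - b, x), 0), x)))
  nodes <- weights <- numeric(0)
  for (k in seq_len(length(brk) - 1L)) {
    lo <- brk[k]; hi <- brk[k + 1L]
    if (hi - lo < 1e-12) next
    nodes <- c(nodes, (lo + hi) / 2 + (hi - lo) / 2 * .gl24$nodes)
    weights <- c(weights, (hi - lo) / 2 * .gl24$weights)
  }
  a <- nodes
  f_mat <- exp(-a / tau) / tau
  Phi_a <- Phi_at(b + a)
  S <- exp(-.hazard_integral(scenario, b, a, x))
  # permissive by x: permissive at stabilization, or protective then failed
  q <- sum(weights * f_mat * (Phi_a + (1 - Phi_a) * (1 - S)))
  # d/dx: stabilize exactly at x (permissive), or fail exactly at x
  dq <- exp(-x / tau) / tau * Phi_at(b + x) +
    .failure_rate(scenario, b + x) * sum(weights * f_mat * (1 - Phi_a) * S)
  list(q = min(max(q, 0), 1), dq = max(dq, 0))
}

#' Onset CDF by age for a birth cohort during an environmental transition
#'
#' Probability that disease has arisen by age \code{x} for an individual
#' born at calendar time \code{birth_year}, under the reconstructed
#' transition dynamics. Two implementations are provided: deterministic
#' quadrature over the module stabilization age (default) and a seeded
#' Monte-Carlo cohort; they agree within Monte-Carlo error.
#'
#' @param scenario A \code{\link{transition_scenario}}.
#' @param birth_year Calendar time of birth (scalar).
#' @param x Age(s) in years, nonnegative (vectorized).
#' @param method \code{"quadrature"} (default, seed-free) or
#'   \code{"montecarlo"}.
#' @param n_mc Number of simulated individuals for the Monte-Carlo method.
#' @param seed Seed for the Monte-Carlo method.
#' @return Onset probabilities, same length as \code{x}.
#' @export
birth_cohort_cdf <- function(scenario, birth_year, x,
                             method = c("quadrature", "montecarlo"),
                             n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(scenario, "transition_scenario"), is.numeric(x))
  if (any(x < 0)) stop("ages 'x' must be nonnegative")
  method <- match.arg(method)
  if (method == "quadrature") {
    vapply(x, function(xi) .cohort_q(scenario, birth_year, xi)$q^scenario$base$N,
           numeric(1))
  } else {
    onset <- simulate_transition_onsets(scenario, birth_year, n = n_mc,
                                        seed = seed, max_age = max(x) + 1)
    vapply(x, function(xi) mean(onset <= xi), numeric(1))
  }
}

#' Simulate onset ages for a birth cohort under a transition scenario
#'
#' Monte-Carlo counterpart of the quadrature in
#' \code{\link{birth_cohort_cdf}}: per module, the stabilization age is
#' Exponential(tau); exposure at the stabilization time selects the
#' propensity; protective modules fail under the time-varying hazard
#' (sampled exactly by superposing the constant 1/T background with a
#' thinned inhomogeneous excess process bounded by 1/T_star). Onset is the
#' maximum permissive-entry age across modules.
#'
#' @param scenario A \code{\link{transition_scenario}}.
#' @param birth_year Calendar birth time (scalar).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param max_age Censoring horizon (years); onsets beyond it are returned
#'   as \code{Inf}.
#' @return Numeric vector of onset ages (years), \code{Inf} when censored.
#' @export
simulate_transition_onsets <- function(scenario, birth_year, n = 1e5,
                                       seed = 1L, max_age = 91) {
  stopifnot(inherits(scenario, "transition_scenario"), n >= 1)
  set.seed(seed)
  Nmod <- scenario$base$N
  tau <- scenario$base$tau
  base_r <- 1 / scenario$base$T
  excess <- 1 / scenario$T_star - base_r
  w <- .era(scenario)
  onset <- rep(0, n)
  for (m in seq_len(Nmod)) {
    a <- stats::rexp(n, rate = 1 / tau)
    exposed <- stats::runif(n) < exposure_fraction(scenario, birth_year + a)
    Phi_m <- ifelse(exposed, scenario$Phi2, scenario$base$Phi)
    permissive <- stats::runif(n) < Phi_m
    entry <- a
    idx <- which(!permissive)
    if (length(idx)) {
      # background failures at the constant rate 1/T
      t_bg <- stats::rexp(length(idx), rate = base_r)
      # excess failures inside the destabilized era by thinning: propose
      # jumps at the bound rate, accept with s(t) (1 for "all", exposure
      # fraction for "exposed"); only proposals inside the era count
      t_ex <- rep(Inf, length(idx))
      if (scenario$destab_strategy != "none" && excess > 0) {
        c_start <- birth_year + a[idx]             # calendar age of maturity
        t_prop <- pmax(w[1] - c_start, 0)          # era entry, module age offset
        alive <- seq_along(idx)
        while (length(alive)) {
          t_prop[alive] <- t_prop[alive] +
            stats::rexp(length(alive), rate = excess)
          cal <- c_start[alive] + t_prop[alive]
          inside <- cal <= w[2]
          acc_p <- ifelse(cal >= w[1] & inside,
                          if (scenario$destab_strategy == "exposed")
                            exposure_fraction(scenario, cal) else 1,
                          0)
          acc <- stats::runif(length(alive)) < acc_p
          t_ex[alive[acc]] <- t_prop[alive[acc]]
          alive <- alive[!acc & inside]
        }
      }
      entry[idx] <- a[idx] + pmin(t_bg, t_ex)
    }
    onset <- pmax(onset, entry)
  }
  onset[onset > max_age] <- Inf
  onset
}

#' Cross-sectional incidence curves and annual series around a transition
#'
#' For each calendar offset in \code{scenario$decade_offsets}, computes the
#' cross-sectional age-specific incidence curve: at calendar time t, the
#' individual aged x belongs to the cohort born at t - x, and the rate is
#' the age-derivative of that cohort's onset CDF (per 100,000 person-years).
#' Also computes the annual population incidence series from -20 to +80
#' years around t50 by averaging the cross-sectional rates over a
#' population age structure (uniform on 0-90 years by default).
#'
#' @param scenario A \code{\link{transition_scenario}}.
#' @param age_weights Optional data.frame with columns \code{age} and
#'   \code{weight} giving the population age structure for the annual
#'   series; defaults to uniform ages 0.5, 1.5, ..., 89.5.
#' @param annual_offsets Calendar offsets for the annual series (default
#'   -20:80).
#' @return A list of class \code{secular_curves}: \code{curves}, a
#'   data.frame (decade_offset, age, incidence_per_100k), and
#'   \code{annual}, a data.frame (year_offset, incidence_per_100k).
#' @export
secular_curves <- function(scenario, age_weights = NULL,
                           annual_offsets = -20:80) {
  stopifnot(inherits(scenario, "transition_scenario"))
  N <- scenario$base$N
  cross_inc <- function(t_cal, x) {
    qq <- .cohort_q(scenario, t_cal - x, x)
    N * qq$dq * qq$q^(N - 1L) * 1e5
  }
  curves <- do.call(rbind, lapply(scenario$decade_offsets, function(d) {
    data.frame(decade_offset = d, age = scenario$age_grid,
               incidence_per_100k = vapply(scenario$age_grid, cross_inc,
                                           numeric(1), t_cal = scenario$t50 + d))
  }))
  if (is.null(age_weights)) {
    age_weights <- data.frame(age = seq(0.5, 89.5, by = 1), weight = 1 / 90)
  } else {
    stopifnot(all(c("age", "weight") %in% names(age_weights)),
              all(age_weights$weight >= 0))
    age_weights$weight <- age_weights$weight / sum(age_weights$weight)
  }
  annual <- vapply(annual_offsets, function(d) {
    rates <- vapply(age_weights$age, cross_inc, numeric(1),
                    t_cal = scenario$t50 + d)
    sum(age_weights$weight * rates)
  }, numeric(1))
  structure(list(curves = curves,
                 annual = data.frame(year_offset = annual_offsets,
                                     incidence_per_100k = annual),
                 scenario = scenario),
            class = "secular_curves")
}

#' @export
print.secular_curves <- function(x, ...) {
  cat(sprintf("Secular incidence curves: %d decade offsets x %d ages; annual series %d-%d y around t50\n",
              length(unique(x$curves$decade_offset)),
              length(unique(x$curves$age)),
              min(x$annual$year_offset), max(x$annual$year_offset)))
  invisible(x)
}

#' Locate interior local maxima of an incidence curve
#'
#' Applies a 3-point moving-average smoother and reports the strict
#' interior local maxima of the smoothed curve — used to detect transient
#' secondary incidence peaks in cross-sectional curves around an
#' environmental transition.
#'
#' @param incidence Incidence values on a regular age grid (length >= 5).
#' @param ages Optional ages corresponding to the values (defaults to
#'   0-based indices).
#' @param smooth Apply the 3-point smoother before peak detection (default
#'   \code{TRUE}; note that it merges single-point spikes separated by one
#'   grid cell).
#' @return A list with \code{n_peaks} and \code{peak_ages}.
#' @export
detect_second_peak <- function(incidence, ages = seq_along(incidence) - 1,
                               smooth = TRUE) {
  if (length(incidence) < 5L) stop("curve must have at least 5 points")
  stopifnot(length(ages) == length(incidence))
  n <- length(incidence)
  sm <- incidence
  if (smooth)
    sm[2:(n - 1)] <- (incidence[1:(n - 2)] + incidence[2:(n - 1)] + incidence[3:n]) / 3
  i <- 2:(n - 1)
  is_max <- sm[i] > sm[i - 1] & sm[i] > sm[i + 1]
  list(n_peaks = sum(is_max), peak_ages = ages[i][is_max])
}
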