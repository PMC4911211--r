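# Closed-form evaluation of the modular-network onset model.
#
# A disease network consists of N functional modules. Each module starts in
# a naive state, stabilizes ("matures") after an Exponential(mean tau) time,
# and adopts a disease-permissive state with probability F (the module
# disease propensity, MDP) or a protective state with probability 1 - F.
# A stabilized protective module may still fail to the permissive state at
# rate 1/T, with T >> tau. Disease onset occurs at the first age at which
# ALL N modules are simultaneously permissive, i.e. at the maximum of the
# per-module permissive-entry times.

# T values beyond this ratio to tau are treated as infinite to avoid
# catastrophic cancellation in the 1 - tau/T denominators.
.T_INF_RATIO <- 1e12

.is_T_infinite <- function(tau, T) is.infinite(T) || (T / tau) > .T_INF_RATIO

#' Specify a single functional module
#'
#' @param tau Mean maturation time in years (rate of the naive-to-mature
#'   transition is \code{1/tau}). Must be positive.
#' @param T Mean failure time in years of the stabilized state
#'   (\code{Inf} allowed: the mature state never fails). Must exceed
#'   \code{tau}.
#' @param F Module disease propensity: the probability that the module
#'   stabilizes in the disease-permissive state. In \code{[0, 1]}.
#' @param naive_state State of the module at birth, \code{"protective"}
#'   (the default postulate) or \code{"permissive"}.
#'
#' @return An object of class \code{module_spec}.
#' @export
module_spec <- function(tau, T, F, naive_state = c("protective", "permissive")) {
  naive_state <- match.arg(naive_state)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(T), length(T) == 1L,
            is.numeric(F), length(F) == 1L, is.finite(F))
  if (tau <= 0) stop("'tau' must be positive")
  if (T <= tau) stop("'T' must exceed 'tau' (got T = ", T, ", tau = ", tau, ")")
  if (F < 0 || F > 1) stop("'F' must lie in [0, 1]")
  structure(list(tau = tau, T = T, F = F, naive_state = naive_state),
            class = "module_spec")
}

#' Assemble a general (heterogeneous) disease network model
#'
#' @param modules A list of \code{\link{module_spec}} objects (length N >= 1).
#' @return An object of class \code{general_model}.
#' @export
general_model <- function(modules) {
  if (inherits(modules, "module_spec")) modules <- list(modules)
  if (!length(modules) || !all(vapply(modules, inherits, logical(1), "module_spec")))
    stop("'modules' must be a non-empty list of module_spec objects")
  structure(list(modules = modules), class = "general_model")
}

#' Homogenized (geometric-mean) model parameters
#'
#' The mean-field approximation replaces the per-module parameters
#' (tau_i, T_i, F_i) by their geometric means tau, T and Phi, reducing the
#' 3N+1 free parameters of the general model to four: N, tau, T and Phi.
#'
#' @param N Number of functional modules (positive integer).
#' @param tau Geometric-mean maturation time (years).
#' @param T Geometric-mean failure time of the stabilized protective state
#'   (years); \code{Inf} allowed. Must exceed \code{tau}.
#' @param Phi Geometric-mean module disease propensity, in \code{[0, 1]}.
#'
#' @return An object of class \code{homogenized_params}.
#' @export
homogenized_params <- function(N, tau, T, Phi) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(T), length(T) == 1L,
            is.numeric(Phi), length(Phi) == 1L, is.finite(Phi))
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer")
  if (tau <= 0) stop("'tau' must be positive")
  if (T <= tau) stop("'T' must exceed 'tau'")
  if (Phi < 0 || Phi > 1) stop("'Phi' must lie in [0, 1]")
  structure(list(N = as.integer(N), tau = tau, T = T, Phi = Phi),
            class = "homogenized_params")
}

#' @export
print.homogenized_params <- function(x, ...) {
  cat(sprintf("Homogenized module-network parameters: N = %d, tau = %g y, T = %g y, Phi = %g\n",
              x$N, x$tau, x$T, x$Phi))
  invisible(x)
}

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf("Module: tau = %g y, T = %g y, F = %g, naive state %s\n",
              x$tau, x$T, x$F, x$naive_state))
  invisible(x)
}

#' Serialize homogenized parameters to a flat list
#'
#' @param params A \code{\link{homogenized_params}} object.
#' @return A plain named list \code{list(N, tau, T, Phi)} suitable for
#'   YAML/JSON serialization.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "homogenized_params"))
  list(N = params$N, tau = params$tau, T = params$T, Phi = params$Phi)
}

#' Deserialize homogenized parameters from a flat mapping
#'
#' @param x A named list (or coercible) with entries N, tau, T, Phi.
#' @return A \code{\link{homogenized_params}} object.
#' @export
params_from_list <- function(x) {
  need <- c("N", "tau", "T", "Phi")
  if (!all(need %in% names(x)))
    stop("mapping must contain fields: ", paste(need, collapse = ", "))
  Tval <- x$T
  if (is.character(Tval)) Tval <- as.numeric(Tval)  # "Inf" from YAML
  homogenized_params(N = x$N, tau = x$tau, T = Tval, Phi = x$Phi)
}

# Per-module permissive-entry CDF for a naive-protective module: the
# probability that the module has entered the permissive state by age x.
# With a = (1 - F) / (1 - tau/T):
#   q(x) = (1 - a) (1 - e^{-x/tau}) + a (1 - e^{-x/T})
# As T -> Inf, a -> 1 - F and the second term vanishes, leaving
# F (1 - e^{-x/tau}) with lifetime plateau F.
.bracket_cdf <- function(tau, T, F, x) {
  if (.is_T_infinite(tau, T)) {
    F * (1 - exp(-x / tau))
  } else {
    a <- (1 - F) / (1 - tau / T)
    (1 - a) * (1 - exp(-x / tau)) + a * (1 - exp(-x / T))
  }
}

# d/dx of .bracket_cdf
.bracket_pdf <- function(tau, T, F, x) {
  if (.is_T_infinite(tau, T)) {
    F * exp(-x / tau) / tau
  } else {
    a <- (1 - F) / (1 - tau / T)
    (1 - a) * exp(-x / tau) / tau + a * exp(-x / T) / T
  }
}

# Naive-permissive module (lower-panel type): probability of being in a
# permissive state (naive or mature-permissive) at age x. Derived from the
# transition matrix: naive -> mature at rate 1/tau (permissive with
# probability F), mature permissive -> protective at rate 1/T:
#   p(x) = e^{-x/tau} + F (e^{-x/T} - e^{-x/tau}) / (1 - tau/T)
.naive_permissive_prob <- function(tau, T, F, x) {
  if (.is_T_infinite(tau, T)) {
    exp(-x / tau) + F * (1 - exp(-x / tau))
  } else {
    exp(-x / tau) + F * (exp(-x / T) - exp(-x / tau)) / (1 - tau / T)
  }
}

#' Probability that a module is permissive at a given age
#'
#' For a module that is protective at birth this is the permissive-entry
#' CDF: the phase-type hitting-time distribution of the permissive state
#' (mixture of a direct Exponential(tau) path, probability F, and a two-step
#' Exponential(tau) then Exponential(T) path, probability 1 - F). For a
#' module that is permissive at birth it is the probability of still (or
#' again) being permissive, a decreasing function starting at 1.
#'
#' @param spec A \code{\link{module_spec}}.
#' @param x Age(s) in years, nonnegative (vectorized).
#' @return Probability vector in \code{[0, 1]}, same length as \code{x}.
#' @export
module_permissive_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "module_spec"), is.numeric(x))
  if (any(x < 0)) stop("ages 'x' must be nonnegative")
  if (spec$naive_state == "protective") {
    .bracket_cdf(spec$tau, spec$T, spec$F, x)
  } else {
    .naive_permissive_prob(spec$tau, spec$T, spec$F, x)
  }
}

#' Disease onset CDF of the general (heterogeneous) model
#'
#' The probability that disease has arisen before age x: the product over
#' the N modules of their permissive probabilities at age x.
#'
#' @param model A \code{\link{general_model}}.
#' @param x Age(s) in years, nonnegative (vectorized).
#' @return Probability vector in \code{[0, 1]}.
#' @export
cdf_general <- function(model, x) {
  stopifnot(inherits(model, "general_model"))
  out <- rep(1, length(x))
  for (m in model$modules) out <- out * module_permissive_cdf(m, x)
  out
}

#' Disease onset CDF of the homogenized model
#'
#' Closed form for N exchangeable modules with geometric-mean parameters:
#' the N-th power of the single-module permissive-entry CDF.
#'
#' @param params A \code{\link{homogenized_params}}.
#' @param x Age(s) in years, nonnegative (vectorized).
#' @return Probability vector in \code{[0, 1]}, nondecreasing in \code{x}.
#' @export
cdf_homogenized <- function(params, x) {
  stopifnot(inherits(params, "homogenized_params"), is.numeric(x))
  if (any(x < 0)) stop("ages 'x' must be nonnegative")
  .bracket_cdf(params$tau, params$T, params$Phi, x)^params$N
}

#' Age-specific incidence rate of the homogenized model
#'
#' The density of onset age: the analytic derivative of
#' \code{\link{cdf_homogenized}},
#' \deqn{I(x) = N\,q'(x)\,q(x)^{N-1}}
#' where q is the single-module permissive-entry CDF. Because the lifetime
#' risk Phi^N is small, this unconditional onset density is used directly
#' as the model counterpart of registry incidence rates.
#'
#' @param params A \code{\link{homogenized_params}}.
#' @param x Age(s) in years, nonnegative (vectorized).
#' @return Incidence rate per person-year (nonnegative), same length as
#'   \code{x}.
#' @export
incidence_rate <- function(params, x) {
  stopifnot(inherits(params, "homogenized_params"), is.numeric(x))
  if (any(x < 0)) stop("ages 'x' must be nonnegative")
  q  <- .bracket_cdf(params$tau, params$T, params$Phi, x)
  dq <- .bracket_pdf(params$tau, params$T, params$Phi, x)
  params$N * dq * q^(params$N - 1L)
}

#' Incidence curve on an age grid, scaled for registry comparison
#'
#' @param params A \code{\link{homogenized_params}}.
#' @param ages Strictly increasing nonnegative ages (years); may be empty.
#' @param scale Person denominator; the default 1e5 reports cases per
#'   100,000 person-years, the registry convention.
#' @return Numeric vector \code{incidence_rate(params, ages) * scale}.
#' @export
incidence_curve <- function(params, ages, scale = 1e5) {
  stopifnot(is.numeric(ages))
  if (length(ages) == 0L) return(numeric(0))
  if (any(ages < 0)) stop("ages must be nonnegative")
  if (length(ages) > 1L && any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  incidence_rate(params, ages) * scale
}

#' Model incidence averaged over an age bin
#'
#' Average of the incidence rate over [age_lo, age_hi] by 5-point
#' Gauss-Legendre quadrature; an alternative to midpoint evaluation when
#' comparing to wide registry bins.
#'
#' @param params A \code{\link{homogenized_params}}.
#' @param age_lo,age_hi Bin bounds (years), vectors of equal length.
#' @param scale Person denominator (default 1e5).
#' @return Bin-averaged incidence, length matching the bin vectors.
#' @export
incidence_bin_average <- function(params, age_lo, age_hi, scale = 1e5) {
  stopifnot(length(age_lo) == length(age_hi), all(age_hi > age_lo))
  # 5-point Gauss-Legendre nodes/weights on [-1, 1]
  gn <- c(-0.9061798459386640, -0.5384693101056831, 0,
          0.5384693101056831, 0.9061798459386640)
  gw <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
          0.4786286704993665, 0.2369268850561891)
  mid <- (age_lo + age_hi) / 2
  half <- (age_hi - age_lo) / 2
  out <- numeric(length(mid))
  for (k in seq_along(gn)) {
    out <- out + gw[k] * incidence_rate(params, mid + half * gn[k])
  }
  out / 2 * scale
}
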