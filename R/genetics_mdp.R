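# Mapping between GWAS odds ratios, risk-allele frequencies and module
# disease propensities (MDPs).
#
# A locus alpha with risk-allele frequency p predominantly affects one
# module, whose MDP among risk-allele carriers is F(alpha_R). For a rare
# disease the odds ratio of the carrier-vs-noncarrier (dominant) contrast
# satisfies
#   OR = (1-p)^2 F / (Phi - [1-(1-p)^2] F)
# where Phi is the population-mean MDP. The mapping is invertible:
#   F = OR * Phi / ((1-p)^2 + OR (2p - p^2)).

#' Odds ratio implied by a module disease propensity
#'
#' @param mdp Carrier MDP F(alpha_R), in \code{[0, 1]} (vectorized).
#' @param raf Risk-allele frequency p, in (0, 1).
#' @param phi Population-mean module disease propensity Phi.
#' @return Odds ratio(s) > 0 for the carrier-vs-noncarrier contrast.
#'   Errors when \code{phi - (2*raf - raf^2) * mdp <= 0} (the carrier class
#'   would exhaust the population risk and the odds ratio diverges).
#' @export
or_from_mdp <- function(mdp, raf, phi) {
  k <- .check_locus_args(mdp = mdp, raf = raf, phi = phi)
  denom <- phi - (2 * raf - raf^2) * k$mdp
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf(paste0("odds ratio undefined: Phi - (2p - p^2) F <= 0 for ",
                        "(F = %g, p = %g, Phi = %g)"),
                 k$mdp[bad[1]], k$raf[bad[1]], phi))
  (1 - k$raf)^2 * k$mdp / denom
}

#' Module disease propensity implied by an odds ratio
#'
#' Algebraic inverse of \code{\link{or_from_mdp}}:
#' \code{F = OR * Phi / ((1-p)^2 + OR * (2p - p^2))}.
#'
#' @param or_value Odds ratio(s) > 0 (vectorized).
#' @param raf Risk-allele frequency p, in (0, 1).
#' @param phi Population-mean module disease propensity Phi.
#' @return Carrier MDP(s) in \code{[0, 1]}; errors when the implied value
#'   leaves the unit interval (inconsistent OR/RAF/Phi triple).
#' @export
mdp_from_or <- function(or_value, raf, phi) {
  k <- .check_locus_args(or_value = or_value, raf = raf, phi = phi)
  F <- k$or_value * phi / ((1 - k$raf)^2 + k$or_value * (2 * k$raf - k$raf^2))
  bad <- which(F > 1)
  if (length(bad))
    stop(sprintf(paste0("implied MDP exceeds 1 for (OR = %g, p = %g, Phi = %g); ",
                        "the triple is inconsistent with the model"),
                 k$or_value[bad[1]], k$raf[bad[1]], phi))
  F
}

.check_locus_args <- function(raf, phi, mdp = NULL, or_value = NULL) {
  stopifnot(is.numeric(raf), is.numeric(phi), length(phi) == 1L)
  if (any(raf <= 0 | raf >= 1)) stop("'raf' must lie strictly in (0, 1)")
  if (phi <= 0 || phi > 1) stop("'phi' must lie in (0, 1]")
  n <- max(length(raf), length(mdp), length(or_value))
  if (!is.null(mdp)) {
    if (any(mdp < 0 | mdp > 1)) stop("'mdp' must lie in [0, 1]")
    mdp <- rep_len(mdp, n)
  }
  if (!is.null(or_value)) {
    if (any(or_value <= 0)) stop("'or_value' must be positive")
    or_value <- rep_len(or_value, n)
  }
  list(raf = rep_len(raf, n), mdp = mdp, or_value = or_value, phi = phi)
}

# ---- distribution objects -------------------------------------------------

#' Distribution of odds ratios across loci
#'
#' Represents the density nu of (significant) odds ratios either
#' parametrically or as a histogram. Supported types: \code{"lognormal"}
#' (parameters \code{meanlog}, \code{sdlog}), \code{"point"} (a point mass
#' at \code{value}), and \code{"histogram"} (bin \code{breaks} with
#' \code{weights}, normalized to integrate to 1; log-spaced breaks are the
#' convention for OR histograms).
#'
#' @param type One of \code{"lognormal"}, \code{"point"},
#'   \code{"histogram"}.
#' @param meanlog,sdlog Log-normal parameters.
#' @param value Location of the point mass.
#' @param breaks,weights Histogram breaks (length k+1, increasing,
#'   positive) and nonnegative bin weights (length k).
#' @return An object of class \code{or_distribution}.
#' @export
or_distribution <- function(type = c("lognormal", "point", "histogram"),
                            meanlog = log(1.1), sdlog = 0.15,
                            value = 1, breaks = NULL, weights = NULL) {
  type <- match.arg(type)
  obj <- switch(type,
    lognormal = {
      stopifnot(sdlog > 0)
      list(type = type, meanlog = meanlog, sdlog = sdlog)
    },
    point = {
      stopifnot(value > 0)
      list(type = type, value = value)
    },
    histogram = {
      stopifnot(!is.null(breaks), !is.null(weights),
                length(breaks) == length(weights) + 1L,
                all(diff(breaks) > 0), breaks[1] > 0, all(weights >= 0),
                sum(weights) > 0)
      mass <- weights / sum(weights)
      list(type = type, breaks = breaks, weights = mass,
           density = mass / diff(breaks))
    })
  structure(obj, class = "or_distribution")
}

#' Density of an odds-ratio distribution
#' @param nu An \code{\link{or_distribution}}.
#' @param x Odds ratio values.
#' @return Density values (point masses return \code{Inf} at the atom).
#' @export
d_or <- function(nu, x) {
  stopifnot(inherits(nu, "or_distribution"))
  switch(nu$type,
    lognormal = stats::dlnorm(x, nu$meanlog, nu$sdlog),
    point = ifelse(x == nu$value, Inf, 0),
    histogram = {
      idx <- findInterval(x, nu$breaks, rightmost.closed = TRUE)
      out <- rep(0, length(x))
      ok <- idx >= 1L & idx <= length(nu$density)
      out[ok] <- nu$density[idx[ok]]
      out
    })
}

#' Sample odds ratios
#' @param nu An \code{\link{or_distribution}}.
#' @param n Number of draws.
#' @return Numeric vector of odds ratios.
#' @export
r_or <- function(nu, n) {
  stopifnot(inherits(nu, "or_distribution"))
  switch(nu$type,
    lognormal = stats::rlnorm(n, nu$meanlog, nu$sdlog),
    point = rep(nu$value, n),
    histogram = {
      bin <- sample.int(length(nu$weights), n, replace = TRUE,
                        prob = nu$weights)
      stats::runif(n, nu$breaks[bin], nu$breaks[bin + 1L])
    })
}

#' Distribution of risk-allele frequencies across loci
#'
#' The density rho over p in (0, 1), either a Beta distribution or an
#' empirical sample (resampled with replacement; density by linear-binned
#' histogram on a fixed grid).
#'
#' @param type \code{"beta"} or \code{"empirical"}.
#' @param shape1,shape2 Beta parameters (default Beta(2, 2)).
#' @param values Observed frequencies for the empirical type.
#' @return An object of class \code{raf_distribution}.
#' @export
raf_distribution <- function(type = c("beta", "empirical"),
                             shape1 = 2, shape2 = 2, values = NULL) {
  type <- match.arg(type)
  obj <- switch(type,
    beta = {
      stopifnot(shape1 > 0, shape2 > 0)
      list(type = type, shape1 = shape1, shape2 = shape2)
    },
    empirical = {
      stopifnot(!is.null(values), all(values > 0 & values < 1))
      list(type = type, values = values)
    })
  structure(obj, class = "raf_distribution")
}

#' Density of a risk-allele-frequency distribution
#' @param rho A \code{\link{raf_distribution}}.
#' @param p Frequencies in (0, 1).
#' @return Density values.
#' @export
d_raf <- function(rho, p) {
  stopifnot(inherits(rho, "raf_distribution"))
  switch(rho$type,
    beta = stats::dbeta(p, rho$shape1, rho$shape2),
    empirical = {
      d <- stats::density(rho$values, from = 0, to = 1, n = 512)
      stats::approx(d$x, d$y, xout = p, rule = 2)$y
    })
}

#' Sample risk-allele frequencies
#' @param rho A \code{\link{raf_distribution}}.
#' @param n Number of draws.
#' @return Numeric vector in (0, 1).
#' @export
r_raf <- function(rho, n) {
  stopifnot(inherits(rho, "raf_distribution"))
  switch(rho$type,
    beta = stats::rbeta(n, rho$shape1, rho$shape2),
    empirical = sample(rho$values, n, replace = TRUE))
}

# ---- MDP density ----------------------------------------------------------

#' Density of module disease propensities implied by OR and RAF distributions
#'
#' Change of variables from the odds-ratio density nu and the risk-allele
#' frequency density rho to the density g of the carrier MDP F(alpha_R):
#' \deqn{g(x) = \int \nu\!\left(\frac{x (1-p)^2}{\Phi - x (2p - p^2)}\right)
#'   \frac{\Phi (1-p)^2}{[\Phi - x (2p - p^2)]^2} \rho(p)\, dp}
#' evaluated by adaptive quadrature over p on (eps, 1 - eps). Grid points
#' where the denominator condition \code{Phi - x(2p - p^2) > 0} fails for
#' part of the p range restrict the integral to the feasible p interval;
#' points with no feasible p are dropped with a warning.
#'
#' @param nu An \code{\link{or_distribution}}.
#' @param rho A \code{\link{raf_distribution}}.
#' @param phi Population-mean MDP Phi.
#' @param grid MDP evaluation grid in (0, 1) (default 400 points on
#'   (0.001, 0.999)).
#' @param eps Integration cutoff near the p boundaries (default 1e-6).
#' @return A list of class \code{mdp_density}: \code{grid}, \code{density}
#'   (nonnegative, integrating to ~1 over the feasible region), and
#'   \code{phi}.
#' @export
mdp_density <- function(nu, rho, phi, grid = seq(0.001, 0.999, length.out = 400),
                        eps = 1e-6) {
  stopifnot(inherits(nu, "or_distribution"), inherits(rho, "raf_distribution"),
            phi > 0, phi <= 1, all(grid > 0), all(grid < 1))
  if (nu$type == "point") {
    # point mass at OR = v maps p -> F deterministically; return the induced
    # density by change of variables p ~ rho
    return(.mdp_density_point(nu$value, rho, phi, grid))
  }
  dens <- vapply(grid, function(x) {
    # feasibility: Phi - x(2p - p^2) > 0  <=>  (1-p)^2 > 1 - Phi/x
    p_hi <- if (x <= phi) 1 - eps else min(1 - sqrt(1 - phi / x) - eps, 1 - eps)
    if (p_hi <= eps) return(NA_real_)
    f <- function(p) {
      den <- phi - x * (2 * p - p^2)
      d_or(nu, x * (1 - p)^2 / den) * phi * (1 - p)^2 / den^2 * d_raf(rho, p)
    }
    tryCatch(stats::integrate(f, eps, p_hi, rel.tol = 1e-8,
                              subdivisions = 400L)$value,
             error = function(e) NA_real_)
  }, numeric(1))
  drop <- which(is.na(dens))
  if (length(drop)) {
    warning(length(drop), " grid point(s) outside the feasible MDP region were dropped")
    grid <- grid[-drop]; dens <- dens[-drop]
  }
  structure(list(grid = grid, density = pmax(dens, 0), phi = phi),
            class = "mdp_density")
}

.mdp_density_point <- function(or_value, rho, phi, grid) {
  # F(p) = OR*Phi / ((1-p)^2 + OR(2p - p^2)); for OR = 1 this is Phi for
  # every p, a point mass at Phi: represent as all mass in the nearest cell.
  if (abs(or_value - 1) < 1e-12) {
    dens <- rep(0, length(grid))
    i <- which.min(abs(grid - phi))
    h <- mean(diff(grid))
    dens[i] <- 1 / h
    return(structure(list(grid = grid, density = dens, phi = phi),
                     class = "mdp_density"))
  }
  # general point mass: g(x) = rho(p(x)) |dp/dx| on the image of (0,1)
  p_of_x <- function(x) {
    # invert F(p) = x for p via uniroot on (0, 1)
    f <- function(p) or_value * phi /
      ((1 - p)^2 + or_value * (2 * p - p^2)) - x
    lo <- f(1e-9); hi <- f(1 - 1e-9)
    if (lo * hi > 0) return(NA_real_)
    stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }
  h <- 1e-6
  dens <- vapply(grid, function(x) {
    p <- p_of_x(x)
    if (is.na(p)) return(0)
    p2 <- p_of_x(min(x + h, 1 - 1e-9))
    if (is.na(p2)) return(0)
    d_raf(rho, p) * abs(p2 - p) / h
  }, numeric(1))
  structure(list(grid = grid, density = dens, phi = phi),
            class = "mdp_density")
}

#' @export
print.mdp_density <- function(x, ...) {
  mode_x <- x$grid[which.max(x$density)]
  cat(sprintf("MDP density on %d grid points (Phi = %g); mode near F = %.3f\n",
              length(x$grid), x$phi, mode_x))
  invisible(x)
}

# ---- GWAS power correction ------------------------------------------------

#' Detection power of a GWAS for a carrier-contrast locus
#'
#' Approximate power of the two-proportion z-test comparing carrier
#' frequencies between cases and controls at significance level
#' \code{alpha}. Carrier frequency in controls is \code{1 - (1-p)^2}; the
#' case frequency follows from the odds ratio.
#'
#' @param or_value Odds ratio(s) of the carrier contrast.
#' @param raf Risk-allele frequency (vectorized with \code{or_value}).
#' @param n_cases,n_controls Study sample sizes.
#' @param alpha Significance threshold (default genome-wide 5e-8).
#' @return Power in \code{[0, 1]}.
#' @export
gwas_power <- function(or_value, raf, n_cases = 20000, n_controls = 30000,
                       alpha = 5e-8) {
  stopifnot(all(or_value > 0), all(raf > 0 & raf < 1),
            n_cases > 0, n_controls > 0, alpha > 0, alpha < 1)
  p0 <- 1 - (1 - raf)^2                 # carrier freq in controls
  odds1 <- or_value * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)             # carrier freq in cases
  pbar <- (n_cases * p1 + n_controls * p0) / (n_cases + n_controls)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
  se1 <- sqrt(p1 * (1 - p1) / n_cases + p0 * (1 - p0) / n_controls)
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((abs(p1 - p0) - za * se0) / se1)
}

#' Correct an observed odds-ratio histogram for GWAS detection power
#'
#' Loci with small odds ratios are under-represented among genome-wide
#' significant hits because detection power falls with effect size. Each
#' histogram bin is reweighted by the reciprocal of the detection power at
#' its midpoint (evaluated at a representative risk-allele frequency or
#' averaged over a RAF distribution), then renormalized.
#'
#' @param raw An \code{\link{or_distribution}} of type \code{"histogram"}:
#'   the detected-locus histogram.
#' @param power_fn Function \code{(or_value) -> power in (0, 1]} applied at
#'   bin midpoints; defaults to \code{\link{gwas_power}} averaged over
#'   \code{rho}.
#' @param rho Optional \code{\link{raf_distribution}} used by the default
#'   power model (default Beta(2, 2)).
#' @param ... Passed to \code{\link{gwas_power}} (sample sizes, alpha).
#' @return A corrected \code{\link{or_distribution}} histogram.
#' @export
correct_or_distribution <- function(raw, power_fn = NULL,
                                    rho = raf_distribution("beta"), ...) {
  stopifnot(inherits(raw, "or_distribution"), raw$type == "histogram")
  mids <- (raw$breaks[-1] + raw$breaks[-length(raw$breaks)]) / 2
  if (is.null(power_fn)) {
    p_grid <- seq(0.02, 0.98, length.out = 49)
    w <- d_raf(rho, p_grid); w <- w / sum(w)
    power_fn <- function(orv) {
      vapply(orv, function(o) sum(w * gwas_power(o, p_grid, ...)), numeric(1))
    }
  }
  pw <- power_fn(mids)
  occupied <- raw$weights > 0
  if (any(pw[occupied] <= 0))
    stop("zero detection power on an occupied bin; truncate the histogram ",
         "support to the detectable range first")
  wts <- raw$weights
  wts[occupied] <- wts[occupied] / pw[occupied]
  or_distribution("histogram", breaks = raw$breaks, weights = wts)
}
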