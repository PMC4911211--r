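# Least-squares fitting of the 4-parameter homogenized model to binned
# age-specific incidence tables: box-constrained quasi-Newton (L-BFGS-B)
# from multiple seeded random starts, with N profiled over an integer grid.

#' Configuration for incidence-curve fitting
#'
#' @param N_grid Integer vector of module counts to profile over; a single
#'   value fixes N. Default \code{1:30}.
#' @param fix_tau Optional fixed maturation time tau (years); when given,
#'   only T and Phi are optimized.
#' @param tau_bounds,T_bounds,Phi_bounds Box bounds for the free
#'   parameters. Defaults: tau in [1, 40] y, T in [50, 1e5] y, Phi in
#'   [0.05, 0.95]. Random starts are drawn uniformly for tau and Phi and
#'   log-uniformly for T (its scale is weakly identified).
#' @param n_starts Number of random feasible starts per N (default 32).
#' @param seed Integer seed; the whole fit is a deterministic function of
#'   (table, config).
#' @param loss \code{"unweighted_ls"} (default): squared residuals on the
#'   per-100,000 scale. \code{"poisson_weighted_ls"}: residuals weighted by
#'   the inverse Poisson variance implied by \code{person_years} (requires
#'   that column).
#' @return A list of class \code{fit_config}.
#' @export
fit_config <- function(N_grid = 1:30, fix_tau = NULL,
                       tau_bounds = c(1, 40), T_bounds = c(50, 1e5),
                       Phi_bounds = c(0.05, 0.95),
                       n_starts = 32L, seed = 1L,
                       loss = c("unweighted_ls", "poisson_weighted_ls")) {
  loss <- match.arg(loss)
  stopifnot(length(N_grid) >= 1L, all(N_grid >= 1L), all(N_grid == round(N_grid)),
            n_starts >= 1L, length(seed) == 1L,
            tau_bounds[1] > 0, diff(tau_bounds) > 0,
            T_bounds[1] > 0, diff(T_bounds) > 0,
            Phi_bounds[1] >= 0, Phi_bounds[2] <= 1, diff(Phi_bounds) > 0)
  if (!is.null(fix_tau)) stopifnot(fix_tau > 0)
  structure(list(N_grid = as.integer(sort(unique(N_grid))), fix_tau = fix_tau,
                 tau_bounds = tau_bounds, T_bounds = T_bounds,
                 Phi_bounds = Phi_bounds, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), loss = loss),
            class = "fit_config")
}

# Sum of squared (optionally weighted) residuals of the model curve at bin
# midpoints against observed per-100k incidence.
.fit_objective <- function(theta, N, mids, obs, w, fix_tau) {
  if (is.null(fix_tau)) {
    tau <- theta[1L]; logT <- theta[2L]; Phi <- theta[3L]
  } else {
    tau <- fix_tau; logT <- theta[1L]; Phi <- theta[2L]
  }
  Tv <- exp(logT)
  if (Tv <= tau) return(1e300)  # infeasible corner of the box
  q  <- .bracket_cdf(tau, Tv, Phi, mids)
  dq <- .bracket_pdf(tau, Tv, Phi, mids)
  pred <- N * dq * q^(N - 1L) * 1e5
  sum(w * (pred - obs)^2)
}

.fit_one_N <- function(N, mids, obs, w, config) {
  lower_full <- c(config$tau_bounds[1], log(config$T_bounds[1]), config$Phi_bounds[1])
  upper_full <- c(config$tau_bounds[2], log(config$T_bounds[2]), config$Phi_bounds[2])
  free <- if (is.null(config$fix_tau)) 1:3 else 2:3
  lower <- lower_full[free]; upper <- upper_full[free]

  # seeded multi-start: uniform tau and Phi, log-uniform T
  starts <- matrix(stats::runif(config$n_starts * length(free),
                                min = rep(lower, each = config$n_starts),
                                max = rep(upper, each = config$n_starts)),
                   nrow = config$n_starts)
  run_lbfgsb <- function(par) {
    tryCatch(
      stats::optim(par, .fit_objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e-10 / .Machine$double.eps,
                                  maxit = 500L),
                   N = N, mids = mids, obs = obs, w = w,
                   fix_tau = config$fix_tau),
      error = function(e) NULL)
  }
  best <- NULL
  best_ok <- FALSE
  for (s in seq_len(config$n_starts)) {
    res <- run_lbfgsb(starts[s, ])
    if (is.null(res)) next
    ok <- res$convergence == 0L
    if (!ok) {
      # a tight factr can end in an abnormal line-search exit at the
      # optimum; converged if a restart cannot improve the incumbent
      res2 <- run_lbfgsb(res$par)
      if (!is.null(res2)) {
        ok <- res2$convergence == 0L ||
          res2$value >= res$value - 1e-10 * (abs(res$value) + 1e-300)
        if (res2$value < res$value) res <- res2
      }
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_ok <- ok
    }
  }
  if (is.null(best)) return(list(converged = FALSE, sse = Inf, params = NULL))
  th <- best$par
  if (is.null(config$fix_tau)) {
    tau <- th[1L]; Tv <- exp(th[2L]); Phi <- th[3L]
  } else {
    tau <- config$fix_tau; Tv <- exp(th[1L]); Phi <- th[2L]
  }
  list(converged = best_ok, sse = best$value,
       params = homogenized_params(N = N, tau = tau, T = max(Tv, tau * (1 + 1e-9)),
                                   Phi = min(max(Phi, 0), 1)))
}

#' Fit the homogenized model to an incidence table
#'
#' Minimizes the sum of squared residuals between the model incidence
#' (evaluated at bin midpoints, per 100,000 person-years) and the observed
#' incidence, over (tau, T, Phi) for each N in \code{N_grid}, using
#' box-constrained quasi-Newton optimization (L-BFGS-B, T on the log scale)
#' from \code{n_starts} seeded random starts. The returned fit is the
#' global best across the N grid.
#'
#' @param table An \code{\link{incidence_table}} with at least 5 bins.
#' @param config A \code{\link{fit_config}}.
#' @return An object of class \code{incidence_fit}: a list with elements
#'   \code{params} (\code{\link{homogenized_params}}), \code{sse},
#'   \code{r2} (fraction of variance explained), \code{residuals}
#'   (observed - fitted per bin), \code{fitted}, \code{converged},
#'   \code{n_profile} (named vector mapping each N to its best SSE), and
#'   \code{config}.
#' @export
fit_incidence <- function(table, config = fit_config()) {
  stopifnot(inherits(table, "incidence_table"), inherits(config, "fit_config"))
  if (nrow(table) < 5L)
    stop("need at least 5 incidence bins to constrain 4 parameters")
  mids <- bin_midpoints(table)
  obs <- table$incidence
  if (all(obs == 0))
    stop("degenerate table: all incidence values are zero (no signal to fit)")
  w <- rep(1, length(obs))
  if (config$loss == "poisson_weighted_ls") {
    if (is.null(table$person_years))
      stop("poisson_weighted_ls requires a person_years column")
    # Var(rate per 1e5) = mu * 1e10 / py, with mu floored at the smallest
    # positive observed rate to keep zero-count bins finitely weighted
    mu <- pmax(obs, min(obs[obs > 0]))
    w <- table$person_years / (mu * 1e10)
  }

  set.seed(config$seed)
  results <- lapply(config$N_grid, .fit_one_N,
                    mids = mids, obs = obs, w = w, config = config)
  sses <- vapply(results, `[[`, numeric(1), "sse")
  n_profile <- stats::setNames(sses, config$N_grid)
  ibest <- which.min(sses)
  best <- results[[ibest]]
  if (!is.finite(best$sse)) {
    return(structure(list(params = NULL, sse = Inf, r2 = NA_real_,
                          residuals = rep(NA_real_, length(obs)),
                          fitted = rep(NA_real_, length(obs)),
                          converged = FALSE, n_profile = n_profile,
                          config = config),
                     class = "incidence_fit"))
  }
  fitted <- incidence_curve(best$params, mids, scale = 1e5)
  sst <- sum((obs - mean(obs))^2)
  sse_plain <- sum((obs - fitted)^2)
  structure(list(params = best$params, sse = best$sse,
                 r2 = if (sst > 0) 1 - sse_plain / sst else NA_real_,
                 residuals = obs - fitted, fitted = fitted,
                 converged = best$converged, n_profile = n_profile,
                 config = config),
            class = "incidence_fit")
}

#' @export
print.incidence_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Incidence fit: FAILED to converge from any start\n")
    return(invisible(x))
  }
  cat(sprintf("Incidence fit: N = %d, tau = %.3g y, T = %.4g y, Phi = %.4g\n",
              x$params$N, x$params$tau, x$params$T, x$params$Phi))
  cat(sprintf("  SSE = %.6g, variance explained = %.4f%s\n", x$sse, x$r2,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Profile the fit over the number of modules N
#'
#' Runs an independent \code{\link{fit_incidence}} for each N in the grid
#' and returns all of them, exposing the characteristic near-ridge: many
#' values of N achieve nearly the same SSE with compensating (tau, T, Phi).
#'
#' @param table An \code{\link{incidence_table}}.
#' @param config A \code{\link{fit_config}}; its \code{N_grid} supplies the
#'   profile grid.
#' @return A named list of \code{incidence_fit} objects, one per N.
#' @export
profile_N <- function(table, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  out <- lapply(config$N_grid, function(N) {
    cfg <- config
    cfg$N_grid <- N
    fit_incidence(table, cfg)
  })
  stats::setNames(out, config$N_grid)
}

#' Fraction of variance explained by a parameter set
#'
#' Computes 1 - SSE/SST of the model curve (bin midpoints, per-100k scale)
#' against the table, where SST is taken about the table mean. Can be
#' negative for models worse than the mean.
#'
#' @param table An \code{\link{incidence_table}}.
#' @param params A \code{\link{homogenized_params}}.
#' @return A scalar, at most 1.
#' @export
variance_explained <- function(table, params) {
  stopifnot(inherits(table, "incidence_table"))
  obs <- table$incidence
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("zero-variance table: variance explained is undefined")
  pred <- incidence_curve(params, bin_midpoints(table), scale = 1e5)
  1 - sum((obs - pred)^2) / sst
}

#' Serialize a fit result to JSON
#'
#' @param fit An \code{incidence_fit}.
#' @param path Output path; when \code{NULL} the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "incidence_fit"))
  obj <- list(
    params = if (is.null(fit$params)) NULL else params_to_list(fit$params),
    sse = fit$sse, r2 = fit$r2, residuals = fit$residuals,
    converged = fit$converged,
    n_profile = as.list(fit$n_profile),
    seed = fit$config$seed, loss = fit$config$loss)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
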