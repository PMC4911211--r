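# Seeded generators for every input the pipeline consumes: Monte-Carlo
# onset cohorts drawn from the module Markov dynamics, binned incidence
# registries with optional Poisson noise, and synthetic locus catalogues.

#' Simulate disease onset ages from the module Markov dynamics
#'
#' Per individual and module: the stabilization age is Exponential(mean
#' tau); the mature state is permissive with probability F (the module's
#' MDP), otherwise protective with a later Exponential(mean T) failure to
#' the permissive state. Onset is the maximum permissive-entry age over
#' modules (disease requires all modules permissive). Ages beyond
#' \code{max_age} are censored to \code{Inf}.
#'
#' @param params A \code{\link{homogenized_params}} (exchangeable modules)
#'   or \code{\link{general_model}} (heterogeneous, naive-protective
#'   modules).
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; the cohort is a pure function of
#'   \code{(params, n, seed, max_age)}.
#' @param max_age Censoring horizon in years (default 90).
#' @param chunk_size Individuals per simulation chunk (memory control).
#' @return Numeric vector of length \code{n}: onset ages in years,
#'   \code{Inf} for individuals without onset by \code{max_age}.
#' @export
simulate_onset_ages <- function(params, n, seed = 1L, max_age = 90,
                                chunk_size = 2e5) {
  stopifnot(n >= 1, max_age > 0)
  if (inherits(params, "homogenized_params")) {
    mods <- replicate(params$N,
                      list(tau = params$tau, T = params$T, F = params$Phi),
                      simplify = FALSE)
  } else if (inherits(params, "general_model")) {
    if (any(vapply(params$modules, `[[`, character(1), "naive_state") != "protective"))
      stop("cohort simulation supports naive-protective modules only")
    mods <- params$modules
  } else stop("'params' must be homogenized_params or general_model")

  set.seed(seed)
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    m <- min(chunk_size, n - done)
    onset <- rep(0, m)
    for (mod in mods) {
      entry <- stats::rexp(m, rate = 1 / mod$tau)
      protective <- stats::runif(m) >= mod$F
      idx <- which(protective)
      if (length(idx)) {
        if (is.infinite(mod$T)) {
          entry[idx] <- Inf
        } else {
          entry[idx] <- entry[idx] + stats::rexp(length(idx), rate = 1 / mod$T)
        }
      }
      onset <- pmax(onset, entry)
    }
    onset[onset > max_age] <- Inf
    out[(done + 1L):(done + m)] <- onset
    done <- done + m
  }
  out
}

#' Generate a synthetic incidence registry
#'
#' Builds a binned age-specific incidence table from the homogenized model:
#' expected cases per bin are the model incidence at the bin midpoint times
#' the person-years at risk, optionally with Poisson sampling noise.
#'
#' @param params A \code{\link{homogenized_params}}.
#' @param person_years Person-years at risk per bin (scalar or per-bin
#'   vector; default 5e6, giving noise comparable to a large regional
#'   registry).
#' @param bin_width Bin width in years (default 5).
#' @param max_age Upper age bound (default 90); bins cover
#'   \code{[0, max_age)}.
#' @param noise \code{"poisson"} (default) or \code{"none"} (table equals
#'   the model curve exactly).
#' @param seed Integer seed (used only when \code{noise = "poisson"}).
#' @return An \code{\link{incidence_table}} with \code{person_years} and
#'   \code{cases} columns.
#' @export
generate_registry <- function(params, person_years = 5e6, bin_width = 5,
                              max_age = 90, noise = c("poisson", "none"),
                              seed = 1L) {
  stopifnot(inherits(params, "homogenized_params"),
            bin_width > 0, max_age > bin_width, all(person_years > 0))
  noise <- match.arg(noise)
  age_lo <- seq(0, max_age - bin_width, by = bin_width)
  age_hi <- age_lo + bin_width
  py <- rep_len(person_years, length(age_lo))
  mu <- incidence_rate(params, (age_lo + age_hi) / 2) * py   # expected cases
  if (noise == "poisson") {
    set.seed(seed)
    cases <- stats::rpois(length(mu), mu)
    incidence_table(age_lo, age_hi, incidence = cases / py * 1e5,
                    person_years = py, cases = cases)
  } else {
    incidence_table(age_lo, age_hi, incidence = mu / py * 1e5,
                    person_years = py)
  }
}

#' Generate a synthetic susceptibility-locus catalogue
#'
#' Draws risk-allele frequencies from \code{rho} and odds ratios from
#' \code{nu}, and fills in the implied carrier MDP via
#' \code{\link{mdp_from_or}}. Draws whose (OR, RAF) pair is inconsistent
#' with the model at the given \code{phi} (implied MDP > 1) are rejected
#' and redrawn; the rejection count is recorded as an attribute.
#'
#' @param n_loci Number of loci (0 allowed: empty catalogue).
#' @param nu An \code{\link{or_distribution}}.
#' @param rho A \code{\link{raf_distribution}}.
#' @param phi Population-mean MDP Phi.
#' @param seed Integer seed.
#' @param max_reject Abort after this many rejected draws (default 1e5).
#' @return A \code{data.frame} (class \code{locus_catalogue}) with columns
#'   \code{locus_id}, \code{raf}, \code{or_value}, \code{mdp}; attribute
#'   \code{n_rejected}.
#' @export
generate_locus_catalogue <- function(n_loci, nu, rho, phi, seed = 1L,
                                     max_reject = 1e5) {
  stopifnot(n_loci >= 0, inherits(nu, "or_distribution"),
            inherits(rho, "raf_distribution"), phi > 0, phi <= 1)
  set.seed(seed)
  raf <- numeric(0); orv <- numeric(0)
  n_rejected <- 0L
  while (length(raf) < n_loci) {
    need <- n_loci - length(raf)
    p <- r_raf(rho, need)
    o <- r_or(nu, need)
    F_try <- o * phi / ((1 - p)^2 + o * (2 * p - p^2))
    keep <- F_try <= 1
    n_rejected <- n_rejected + sum(!keep)
    if (n_rejected > max_reject)
      stop("more than ", max_reject, " rejected draws: the (nu, rho, phi) ",
           "combination is essentially infeasible under the model")
    raf <- c(raf, p[keep]); orv <- c(orv, o[keep])
  }
  out <- data.frame(
    locus_id = if (n_loci) sprintf("L%03d", seq_len(n_loci)) else character(0),
    raf = raf, or_value = orv,
    mdp = if (n_loci) mdp_from_or(orv, raf, phi) else numeric(0))
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("locus_catalogue", "data.frame")
  out
}

#' Read / write locus catalogues
#'
#' CSV columns: \code{locus_id}, \code{raf}, \code{or_value}, optional
#' \code{mdp}.
#'
#' @param path CSV path.
#' @return \code{read_locus_csv}: a \code{locus_catalogue} data.frame.
#' @export
read_locus_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("locus_id", "raf", "or_value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (any(raw$raf <= 0 | raw$raf >= 1)) stop("raf out of (0, 1) in ", path)
  if (any(raw$or_value <= 0)) stop("nonpositive odds ratio in ", path)
  class(raw) <- c("locus_catalogue", "data.frame")
  raw
}

#' @rdname read_locus_csv
#' @param catalogue A \code{locus_catalogue} data.frame.
#' @return \code{write_locus_csv}: \code{path}, invisibly.
#' @export
write_locus_csv <- function(catalogue, path) {
  utils::write.csv(as.data.frame(catalogue), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
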