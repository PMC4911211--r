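# Binned age-specific incidence observations with exposure denominators.

#' Construct a validated incidence table
#'
#' A registry-style table of age-specific incidence: non-overlapping age
#' bins with rates on the per-100,000 person-years scale, optionally with
#' the person-years and case counts they were derived from.
#'
#' @param age_lo,age_hi Bin bounds in years (age_lo < age_hi, bins must not
#'   overlap).
#' @param incidence Incidence per 100,000 person-years (nonnegative).
#' @param person_years Optional person-years at risk per bin.
#' @param cases Optional integer case counts; when both \code{cases} and
#'   \code{person_years} are given, \code{incidence} must equal
#'   \code{cases / person_years * 1e5} up to rounding.
#' @return A \code{data.frame} of class \code{incidence_table}, sorted by
#'   \code{age_lo}.
#' @export
incidence_table <- function(age_lo, age_hi, incidence,
                            person_years = NULL, cases = NULL) {
  n <- length(age_lo)
  if (n == 0L) stop("incidence table must have at least one bin")
  stopifnot(length(age_hi) == n, length(incidence) == n)
  bad <- which(!(age_lo < age_hi))
  if (length(bad))
    stop("age_lo must be < age_hi; offending row(s): ", paste(bad, collapse = ", "))
  if (any(age_lo < 0)) stop("age bounds must be nonnegative")
  if (any(incidence < 0)) {
    bad <- which(incidence < 0)
    stop("incidence must be nonnegative; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  ord <- order(age_lo)
  age_lo <- age_lo[ord]; age_hi <- age_hi[ord]; incidence <- incidence[ord]
  if (!is.null(person_years)) person_years <- person_years[ord]
  if (!is.null(cases)) cases <- cases[ord]
  if (n > 1L) {
    overlap <- which(age_lo[-1L] < age_hi[-n] - 1e-9)
    if (length(overlap))
      stop("overlapping age bins; offending row pair(s): ",
           paste(sprintf("%d-%d", overlap, overlap + 1L), collapse = ", "))
  }
  df <- data.frame(age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                   incidence = as.numeric(incidence))
  if (!is.null(person_years)) {
    if (any(person_years <= 0)) stop("person_years must be positive")
    df$person_years <- as.numeric(person_years)
  }
  if (!is.null(cases)) {
    if (any(cases < 0) || any(cases != round(cases)))
      stop("cases must be nonnegative integers")
    df$cases <- as.numeric(cases)
    if (!is.null(person_years)) {
      implied <- df$cases / df$person_years * 1e5
      # tolerate rounding of the published rate to ~3 significant digits
      off <- which(abs(implied - df$incidence) >
                     pmax(0.5e-2 * pmax(implied, 1e-12), 1e-6))
      if (length(off))
        stop("incidence inconsistent with cases/person_years * 1e5; ",
             "offending row(s): ", paste(off, collapse = ", "))
    }
  }
  class(df) <- c("incidence_table", "data.frame")
  df
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("Age-specific incidence table: %d bins, ages %g-%g y\n",
              nrow(x), min(x$age_lo), max(x$age_hi)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Bin midpoints of an incidence table
#'
#' @param table An \code{\link{incidence_table}}.
#' @return Numeric vector of bin midpoints (years).
#' @export
bin_midpoints <- function(table) {
  (table$age_lo + table$age_hi) / 2
}

#' Read an incidence table from CSV
#'
#' Expected columns: \code{age_lo}, \code{age_hi},
#' \code{incidence_per_100k}, and optionally \code{person_years} and
#' \code{cases}. All validation of \code{\link{incidence_table}} is applied,
#' with errors reporting row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @return An \code{\link{incidence_table}}.
#' @export
read_incidence_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("age_lo", "age_hi", "incidence_per_100k")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (col in intersect(c(need, "person_years", "cases"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    badnum <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(badnum) || anyNA(v))
      stop("malformed numeric in column '", col, "' of ", path, ", row(s): ",
           paste(unique(c(badnum, which(is.na(v)))), collapse = ", "))
    raw[[col]] <- v
  }
  incidence_table(age_lo = raw$age_lo, age_hi = raw$age_hi,
                  incidence = raw$incidence_per_100k,
                  person_years = raw[["person_years"]],
                  cases = raw[["cases"]])
}

#' Write an incidence table to CSV
#'
#' Inverse of \code{\link{read_incidence_csv}}; a write-then-read round
#' trip reproduces the table exactly.
#'
#' @param table An \code{\link{incidence_table}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_incidence_csv <- function(table, path) {
  stopifnot(inherits(table, "incidence_table"))
  out <- data.frame(age_lo = table$age_lo, age_hi = table$age_hi,
                    incidence_per_100k = table$incidence)
  if (!is.null(table$person_years)) out$person_years <- table$person_years
  if (!is.null(table$cases)) out$cases <- table$cases
  utils::write.csv(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
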