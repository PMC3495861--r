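# Competitive-fitness statistics.  Fitness W of a test phage is the relative
# change in its ratio to a marked common competitor across one assay
# culture, W = R1 / R0; analyses are on lnW.  A clone that cannot infect the
# assay host at all has W = 0 and undefined lnW, and is excluded from tests.

#' Competitive fitness from competitor ratios
#'
#' @param r0 Test/competitor ratio in the starting mixture (> 0).
#' @param r1 Test/competitor ratio in the harvested lysate (>= 0).
#' @return List with \code{w} (= r1/r0), \code{lnw} (\code{NA} when w = 0)
#'   and \code{defined} (FALSE when lnW is undefined).
#' @export
fitness_w <- function(r0, r1) {
  if (any(r0 <= 0)) stop("r0 must be > 0")
  if (any(r1 < 0)) stop("r1 must be >= 0")
  w <- r1 / r0
  list(w = w, lnw = ifelse(w > 0, log(w), NA_real_), defined = w > 0)
}

#' One-sample t test from summary statistics or raw values
#'
#' \code{t = (mean - mu0) / (sd / sqrt(n))} with \code{df = n - 1} and a
#' two-sided p-value.  Accepts either a vector of replicate values or the
#' (mean, sd, n) summary, so printed summary tables can be re-tested
#' directly.  A zero standard deviation yields a signed-infinite t with
#' p = 0, flagged as degenerate.
#'
#' @param x Optional numeric vector of replicate values.
#' @param mean,sd,n Summary statistics (ignored when \code{x} is given).
#' @param mu0 Null mean (default 0).
#' @return List with \code{t}, \code{df}, \code{p.value}, \code{degenerate}.
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL, mu0 = 0) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply either x or (mean, sd, n)")
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  df <- n - 1
  if (sd == 0) {
    t <- if (mean == mu0) 0 else sign(mean - mu0) * Inf
    return(list(t = t, df = df, p.value = if (mean == mu0) 1 else 0,
                degenerate = TRUE))
  }
  t <- (mean - mu0) / (sd / sqrt(n))
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Two-sample t test
#'
#' Pooled-variance Student's t test by default (df = n_a + n_b - 2), with
#' Welch's unequal-variance test as an option.  Accepts raw replicate
#' vectors.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param var_equal Pooled-variance Student test (default TRUE); FALSE for
#'   Welch.
#' @return List with \code{t}, \code{df}, \code{p.value}, \code{degenerate}
#'   (TRUE when the pooled variance is zero, with infinite t).
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- base::mean(a) - base::mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(a) + length(b) - 2,
                p.value = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, degenerate = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return \code{alpha / m} (0.05/31 = 0.0016, 0.05/17 = 0.003 at the
#'   precision usually reported).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Linear trend of lnW through time
#'
#' Ordinary least-squares regression of lnW on time (generations), with the
#' standard t test of the slope against zero.
#'
#' @param times Numeric vector of generation times (not all equal).
#' @param lnw Numeric vector of lnW values (same length, >= 3 points).
#' @return List with \code{slope}, \code{intercept}, \code{p.value} (slope
#'   = 0 test; 1 for an exactly constant response) and the fitted \code{lm}.
#' @export
lnw_trend <- function(times, lnw) {
  if (length(times) != length(lnw)) stop("times and lnw differ in length")
  if (length(times) < 3) stop("need at least three points")
  if (length(unique(times)) < 2) stop("times must not all be equal")
  fit <- stats::lm(lnw ~ times)
  # exact fits (handled below) trigger a spurious precision warning
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) < 2 || is.nan(sm["times", 4])) 1 else sm["times", 4]
  slope <- unname(coef(fit)["times"])
  if (all(lnw == lnw[1])) p <- 1
  list(slope = slope, intercept = unname(coef(fit)[1]), p.value = p,
       fit = fit)
}

#' Read a fitness-assay table
#'
#' Accepts either replicate form (columns \code{clone}, \code{host},
#' \code{replicate}, \code{lnw}) or summary form (\code{clone}, \code{host},
#' \code{mean}, \code{sd}, \code{n}), tab-separated.  Rows with missing lnW
#' (clones unable to infect the assay host) are retained with \code{NA}.
#'
#' @param path Path to the TSV file.
#' @return Data frame with a \code{form} attribute (\code{"replicate"} or
#'   \code{"summary"}).
#' @export
read_fitness_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("clone", "host", "mean", "sd", "n") %in% names(d))) {
    attr(d, "form") <- "summary"
  } else if (all(c("clone", "host", "replicate", "lnw") %in% names(d))) {
    attr(d, "form") <- "replicate"
  } else {
    stop("fitness table must have columns clone/host/mean/sd/n ",
         "or clone/host/replicate/lnw")
  }
  d
}
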