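# Closed-form statistics used in the SC kinetics analysis.

#' Poisson probability of k synapsis initiations
#'
#' \eqn{f(k, \lambda) = \lambda^k e^{-\lambda} / k!}.  Thin wrapper around
#' [stats::dpois()] with argument checking.
#'
#' @param k non-negative integer count(s).
#' @param lambda mean number of initiations per chromosome (>= 0).
#' @return probability.
#' @export
poisson_pmf <- function(k, lambda) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  stats::dpois(k, lambda)
}

#' Probability of two or more synapsis initiations per chromosome
#'
#' \eqn{f(\ge 2) = 1 - f(0,\lambda) - f(1,\lambda)} under a Poisson model
#' of initiation counts.  With five SCs on average distributed over 16
#' chromosomes, \eqn{\lambda = 5/16} and the multiple-initiation frequency
#' is about 4%.
#'
#' @param lambda mean initiations per chromosome (default 5/16).
#' @return probability in [0, 1].
#' @examples
#' multi_initiation_frequency(5 / 16)   # ~0.0398
#' @export
multi_initiation_frequency <- function(lambda = 5 / 16) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  stats::ppois(1, lambda, lower.tail = FALSE)
}

#' Probability of missing a rare event in n observations
#'
#' Binomial probability that an event of per-observation probability
#' `p_event` is seen zero times in `n` independent observations,
#' \eqn{(1 - p)^n}.
#'
#' @param p_event per-observation probability in [0, 1].
#' @param n number of observations (>= 0).
#' @return probability.
#' @examples
#' miss_probability(0.04, 230)   # ~8.3e-5, i.e. a 0.01 percent chance
#' @export
miss_probability <- function(p_event, n) {
  if (any(p_event < 0) || any(p_event > 1)) stop("p_event must be in [0, 1]")
  if (any(n < 0)) stop("n must be >= 0")
  (1 - p_event)^n
}

#' Two-proportion z test (pooled variance)
#'
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1 - \hat p)(1/n_1 +
#' 1/n_2)}} with the pooled proportion \eqn{\hat p = (x_1 + x_2)/(n_1 +
#' n_2)}; two-sided p from the standard normal.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z`, `p_value`, `p1`, `p2`, `pooled`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    stop("pooled proportion is degenerate (0 or 1); z undefined")
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2, pooled = pp)
}

#' Welch's unequal-variance t test
#'
#' Wrapper around [stats::t.test()] (Welch-Satterthwaite degrees of
#' freedom, two-sided), with the degenerate equal-constant case mapped to
#' t = 0, p = 1.
#'
#' @param sample1,sample2 numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop("each sample needs at least two values")
  }
  if (stats::var(sample1) == 0 && stats::var(sample2) == 0) {
    if (mean(sample1) == mean(sample2)) {
      return(list(t = 0, df = NA_real_, p_value = 1))
    }
    stop("both samples constant with different means: t undefined")
  }
  ht <- stats::t.test(sample1, sample2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least three pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Two-means clustering of telomere-led motion speeds
#'
#' Deterministic one-dimensional two-means clustering of per-step speeds:
#' clusters are initialised by splitting at the median and the usual
#' assign/update iteration is run to convergence.  Reports the mean and SD
#' of the low- and high-velocity clusters.
#'
#' @param speeds numeric vector of speeds (um/s), or a `"motion_track"`
#'   from [simulate_motion_track()] (speeds are computed from successive
#'   positions).
#' @return list with `low_mean`, `low_sd`, `high_mean`, `high_sd`,
#'   `assignment` (1 = low, 2 = high), `speeds`, `single_cluster` flag.
#' @export
velocity_clusters <- function(speeds) {
  if (inherits(speeds, "motion_track")) speeds <- track_speeds(speeds)
  speeds <- as.numeric(speeds)
  if (length(speeds) < 4) stop("need at least four speed samples")
  if (max(speeds) - min(speeds) < 1e-12) {
    return(list(low_mean = mean(speeds), low_sd = 0,
                high_mean = mean(speeds), high_sd = 0,
                assignment = rep(1L, length(speeds)),
                speeds = speeds, single_cluster = TRUE))
  }
  med <- stats::median(speeds)
  lo <- speeds <= med
  if (all(lo) || !any(lo)) lo <- speeds <= mean(range(speeds))
  centers <- c(mean(speeds[lo]), mean(speeds[!lo]))
  for (iter in 1:100) {
    assign_hi <- abs(speeds - centers[2]) < abs(speeds - centers[1])
    if (all(assign_hi) || !any(assign_hi)) break
    new_centers <- c(mean(speeds[!assign_hi]), mean(speeds[assign_hi]))
    if (max(abs(new_centers - centers)) < 1e-12) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  hi <- abs(speeds - centers[2]) < abs(speeds - centers[1])
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(low_mean = mean(speeds[!hi]), low_sd = sd0(speeds[!hi]),
       high_mean = mean(speeds[hi]), high_sd = sd0(speeds[hi]),
       assignment = as.integer(hi) + 1L,
       speeds = speeds, single_cluster = FALSE)
}
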