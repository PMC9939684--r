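#' Continuous piecewise-linear least-squares fit
#'
#' Fits a continuous segmented (broken-line) regression of SC length on time
#' with a fixed number of linear segments.  Breakpoints are located by
#' exhaustive search over the midpoints between consecutive observation
#' times, requiring at least three observations per segment, with ordinary
#' least squares on the induced basis at every admissible candidate.  The
#' global SSE minimiser is returned; ties are broken toward the earliest
#' breakpoints.
#'
#' Lengths are fitted in micrometres against time in minutes, so raw slopes
#' are in um/min; reported slopes are converted to nm/min.
#'
#' @param times numeric vector of observation times (minutes), strictly
#'   increasing.
#' @param lengths numeric vector of SC lengths (um), same length as `times`.
#' @param n_segments integer, number of linear segments (1, 2 or 3).
#' @return An object of class `"sc_segfit"`: a list with elements
#'   `n_segments`, `breakpoints` (minutes), `slopes` (nm/min, one per
#'   segment), `intercept` (um at time 0 of the first segment),
#'   `coefficients` (raw basis coefficients, um/min scale), `fitted`,
#'   `residuals`, `sse` (um^2), `r2`, `adj_r2`, `n_points`, `times`,
#'   `lengths`.
#' @examples
#' t <- seq(0, 42, by = 3)
#' y <- ifelse(t <= 12, 0.088 * t, 0.088 * 12 + 0.019 * (t - 12))
#' fit <- fit_piecewise_linear(t, y, n_segments = 2)
#' coef(fit)
#' @seealso [press_statistic()], [fit_sc_kinetics()]
#' @export
fit_piecewise_linear <- function(times, lengths, n_segments = 1L) {
  check_trajectory_args(times, lengths)
  k <- as.integer(n_segments)
  if (k < 1L || k > 3L) stop("n_segments must be 1, 2 or 3")
  n <- length(times)
  if (n < 3L * k) {
    stop(sprintf("need at least %d points for %d segments (have %d)",
                 3L * k, k, n))
  }
  ord <- order(times)
  times <- times[ord]; lengths <- lengths[ord]

  best <- pw_search(times, lengths, k)
  new_sc_segfit(times, lengths, k, best$breaks, best$fit)
}

# admissible breakpoint candidates: midpoints between consecutive
# observations, each needing >= 3 observations on both sides
break_candidates <- function(times) {
  n <- length(times)
  cand <- (times[-n] + times[-1]) / 2
  keep <- seq_along(cand) >= 3L & (n - seq_along(cand)) >= 3L
  cand[keep]
}

# exhaustive breakpoint search; returns list(breaks, fit = .lm.fit result).
# The scan evaluates every candidate's SSE in O(1) per candidate via
# suffix-sum normal equations; the winning candidate is refitted with
# .lm.fit for numerically clean coefficients and residuals.
pw_search <- function(times, lengths, k) {
  n <- length(times)
  if (k == 1L) {
    X <- cbind(1, times)
    return(list(breaks = numeric(0), fit = stats::.lm.fit(X, lengths)))
  }
  cand <- break_candidates(times)
  if (!length(cand)) {
    stop("no admissible breakpoint candidates (need >= 3 points per segment)")
  }
  # suffix sums: S*(j) = sum over i >= j
  rsum <- function(v) rev(cumsum(rev(v)))
  S0 <- c(rsum(rep(1, n)), 0)
  S1 <- c(rsum(times), 0)
  S2 <- c(rsum(times^2), 0)
  Sy <- c(rsum(lengths), 0)
  Sty <- c(rsum(times * lengths), 0)
  T1 <- S1[1]; T2 <- S2[1]; Y1 <- Sy[1]; TY <- Sty[1]
  yy <- sum(lengths^2)
  jj <- findInterval(cand, times) + 1L      # first index with t > b
  # per-candidate hinge moments
  hA  <- S1[jj] - cand * S0[jj]             # sum (t-b)+
  hAA <- S2[jj] - 2 * cand * S1[jj] + cand^2 * S0[jj]   # sum (t-b)+^2
  hT  <- S2[jj] - cand * S1[jj]             # sum t (t-b)+
  hY  <- Sty[jj] - cand * Sy[jj]            # sum y (t-b)+
  best_sse <- Inf; best_breaks <- NULL
  nc <- length(cand)
  # SSE of [X1, hinge] via the Schur complement: adding column x to a
  # design with Gram inverse G drops the SSE by (x'r)^2 / (x'M x), both
  # computable from the candidate moments, so each scan is vectorised.
  if (k == 2L) {
    G <- tryCatch(solve(matrix(c(n, T1, T1, T2), 2)),
                  error = function(e) NULL)
    if (is.null(G)) stop("degenerate time design")
    v1 <- c(Y1, TY)
    gv <- as.numeric(G %*% v1)
    sse1 <- max(yy - sum(v1 * gv), 0)
    uGu <- G[1, 1] * hA^2 + 2 * G[1, 2] * hA * hT + G[2, 2] * hT^2
    den <- hAA - uGu
    num <- hY - (hA * gv[1] + hT * gv[2])
    sse <- pmax(sse1 - ifelse(den > 1e-10, num^2 / den, 0), 0)
    i <- which(sse <= min(sse) + 1e-12)[1]   # earliest breakpoint on ties
    best_sse <- sse[i]; best_breaks <- cand[i]
  } else {
    nleq <- S0[1] - S0[jj]                  # points with t <= b
    neq <- vapply(cand, function(b) sum(times == b), numeric(1))
    for (ci in seq_len(nc - 1L)) {
      cjs <- which(seq_len(nc) > ci & nleq - nleq[ci] + neq[ci] >= 3L)
      if (!length(cjs)) next
      b1 <- cand[ci]
      M1 <- matrix(c(n, T1, hA[ci],
                     T1, T2, hT[ci],
                     hA[ci], hT[ci], hAA[ci]), 3, 3)
      G <- tryCatch(solve(M1), error = function(e) NULL)
      if (is.null(G)) next
      v1 <- c(Y1, TY, hY[ci])
      gv <- as.numeric(G %*% v1)
      sse1 <- max(yy - sum(v1 * gv), 0)
      b2 <- cand[cjs]; j2 <- jj[cjs]
      cross <- S2[j2] - (b1 + b2) * S1[j2] + b1 * b2 * S0[j2]
      u1 <- hA[cjs]; u2 <- hT[cjs]; u3 <- cross
      uGu <- G[1, 1] * u1^2 + G[2, 2] * u2^2 + G[3, 3] * u3^2 +
        2 * (G[1, 2] * u1 * u2 + G[1, 3] * u1 * u3 + G[2, 3] * u2 * u3)
      den <- hAA[cjs] - uGu
      num <- hY[cjs] - (u1 * gv[1] + u2 * gv[2] + u3 * gv[3])
      sse <- pmax(sse1 - ifelse(den > 1e-10, num^2 / den, 0), 0)
      i <- which(sse <= min(sse) + 1e-12)[1]
      if (sse[i] < best_sse - 1e-12) {
        best_sse <- sse[i]; best_breaks <- c(b1, b2[i])
      }
    }
  }
  if (is.null(best_breaks)) {
    stop("no admissible breakpoint candidates (need >= 3 points per segment)")
  }
  X <- cbind(1, times)
  for (b in best_breaks) X <- cbind(X, pmax(times - b, 0))
  list(breaks = best_breaks, fit = stats::.lm.fit(X, lengths))
}

new_sc_segfit <- function(times, lengths, k, breaks, lmf) {
  beta <- lmf$coefficients
  beta[is.na(beta)] <- 0         # rank-deficient (collinear) candidates
  fitted <- as.numeric(pw_eval(beta, breaks, times))
  res <- lengths - fitted
  sse <- sum(res^2)
  sst <- sum((lengths - mean(lengths))^2)
  r2 <- if (sst > 1e-300) 1 - sse / sst else as.numeric(sse < 1e-12)
  # cumulative sums of hinge coefficients give per-segment slopes (um/min)
  slopes_um <- cumsum(beta[-1])
  n <- length(times)
  p <- 2L * k    # k slopes + intercept + (k - 1) breakpoints
  adj <- if (n - p - 1L > 0L) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(list(
    n_segments  = k,
    breakpoints = breaks,
    slopes      = slopes_um * 1000,   # nm/min
    intercept   = unname(beta[1]),
    coefficients = unname(beta),
    fitted      = fitted,
    residuals   = res,
    sse         = sse,
    r2          = r2,
    adj_r2      = adj,
    n_points    = n,
    times       = times,
    lengths     = lengths
  ), class = "sc_segfit")
}

# evaluate the piecewise-linear basis model at arbitrary times
pw_eval <- function(beta, breaks, t) {
  y <- beta[1] + beta[2] * t
  for (m in seq_along(breaks)) y <- y + beta[2 + m] * pmax(t - breaks[m], 0)
  y
}

check_trajectory_args <- function(times, lengths) {
  if (length(times) != length(lengths)) {
    stop("times and lengths must have equal length")
  }
  if (anyNA(times) || anyNA(lengths)) stop("NA values in trajectory")
  if (any(diff(sort(times)) <= 0)) stop("times must be distinct")
}

#' Adjusted R-squared of a segmented fit
#'
#' Computes \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)} with the parameter count
#' \eqn{p = 2 k} for a k-segment continuous piecewise-linear model (k slopes,
#' one intercept and k - 1 breakpoints are all counted as free parameters).
#'
#' @param fit an `"sc_segfit"` object.
#' @return adjusted R-squared (dimensionless).
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, "sc_segfit"))
  n <- fit$n_points; p <- 2L * fit$n_segments
  if (n <= p + 1L) {
    stop(sprintf("adjusted R2 undefined: n = %d <= p + 1 = %d", n, p + 1L))
  }
  1 - (1 - fit$r2) * (n - 1) / (n - p - 1)
}

#' Leave-one-out PRESS statistic for a segmented model
#'
#' Predicted residual error sum of squares: each observation is held out in
#' turn, the k-segment model is refitted on the remaining points — including
#' a full re-search of the breakpoints — and the squared prediction error at
#' the held-out time is accumulated.  When removing a point leaves too few
#' observations for k segments, that fold falls back to the largest feasible
#' segment count; the number of such folds is attached as attribute
#' `"n_fallback"`.
#'
#' @param times,lengths trajectory as in [fit_piecewise_linear()].
#' @param n_segments number of segments (1-3).
#' @return PRESS in um^2, with attribute `n_fallback`.
#' @export
press_statistic <- function(times, lengths, n_segments = 1L) {
  check_trajectory_args(times, lengths)
  k <- as.integer(n_segments)
  n <- length(times)
  if (n < 3L * k + 1L && n < 4L) stop("too few points for leave-one-out")
  ord <- order(times); times <- times[ord]; lengths <- lengths[ord]
  press <- 0; n_fallback <- 0L
  for (i in seq_len(n)) {
    ti <- times[-i]; yi <- lengths[-i]
    ki <- k
    while (ki > 1L && length(ti) < 3L * ki) ki <- ki - 1L
    if (ki != k) n_fallback <- n_fallback + 1L
    sr <- pw_search(ti, yi, ki)
    beta <- sr$fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- pw_eval(beta, sr$breaks, times[i])
    press <- press + (lengths[i] - pred)^2
  }
  structure(press, n_fallback = n_fallback)
}

#' Logarithmic growth fit for comparison with segmented models
#'
#' Least-squares fit of \eqn{length = a + b \log(t - t_0)} where \eqn{t_0}
#' is fixed at the first observation time minus one sampling interval, used
#' only to compare goodness of fit (R-squared) against the segmented linear
#' models.
#'
#' @param times,lengths trajectory (minutes, um).
#' @param sampling_interval minutes; defaults to the median spacing of
#'   `times`.
#' @return R-squared of the logarithmic fit.
#' @export
fit_log_model <- function(times, lengths, sampling_interval = NULL) {
  check_trajectory_args(times, lengths)
  ord <- order(times); times <- times[ord]; lengths <- lengths[ord]
  if (is.null(sampling_interval)) {
    sampling_interval <- stats::median(diff(times))
  }
  t0 <- times[1] - sampling_interval
  shifted <- times - t0
  if (any(shifted <= 0)) stop("non-positive shifted times in log fit")
  sst <- sum((lengths - mean(lengths))^2)
  if (sst < 1e-300) return(0)
  f <- stats::lm.fit(cbind(1, log(shifted)), lengths)
  1 - sum(f$residuals^2) / sst
}

#' Predicted rate ratio under bidirectional SC growth
#'
#' Under the bidirectional-growth model, synapsis nucleates at an off-centre
#' (non-metacentric) site and two tips elongate at equal rate r, giving a
#' total elongation rate of 2r.  Once the short arm completes, a single tip
#' remains and the total rate drops to r, i.e. 50% of the initial rate,
#' regardless of where on the chromosome the nucleation site sits.
#'
#' @param arm_fraction share of chromosome length on the short arm, in
#'   (0, 0.5]; 0.5 is metacentric.
#' @return a list: `rate_ratio` (second-phase / initial total rate, always
#'   0.5), `phase1_length_fraction` (fraction of final length assembled
#'   before the short arm completes, `2 * arm_fraction`), and
#'   `phase2_time_fraction` (share of total assembly time spent in the
#'   single-tip phase, `(1 - 2 a)/(1 - a)`; zero for a metacentric).
#' @examples
#' bidirectional_prediction(0.3)$rate_ratio   # 0.5
#' @export
bidirectional_prediction <- function(arm_fraction) {
  if (!is.numeric(arm_fraction) || length(arm_fraction) != 1L ||
      arm_fraction <= 0 || arm_fraction > 0.5) {
    stop("arm_fraction must be in (0, 0.5]")
  }
  a <- arm_fraction
  list(rate_ratio = 0.5,
       phase1_length_fraction = 2 * a,
       phase2_time_fraction = (1 - 2 * a) / (1 - a))
}
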