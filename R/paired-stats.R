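#' @include AllClasses.R
NULL

#' Match optical transients to electrophysiological miniature events
#'
#' Greedy globally-nearest one-to-one matching: among all unpaired
#' cross-modal pairs with \eqn{|\Delta t| \le} `tolerance`, repeatedly accept
#' the pair with the smallest |time difference|, breaking exact ties toward
#' the earlier ephys event (then the earlier optical event). The result is
#' deterministic, order-invariant, and conserves counts.
#'
#' @param optical optical events: an event data.frame (uses `peak_time`,
#'   `amplitude`) or a data.frame with `time` and `amplitude` columns.
#' @param ephys electrophysiological events: data.frame with `time` (ms) and
#'   `amplitude` (mV) columns.
#' @param tolerance maximum |time difference| for a pair (ms, default 50).
#' @return A [MatchResult-class].
#' @export
matchEvents <- function(optical, ephys, tolerance = 50) {
  toTA <- function(df, timeCol) {
    data.frame(time = as.numeric(df[[timeCol]]),
               amplitude = as.numeric(df[["amplitude"]]))
  }
  opt <- toTA(optical, if ("peak_time" %in% names(optical)) "peak_time" else "time")
  eph <- toTA(ephys, "time")
  opt <- opt[order(opt$time), , drop = FALSE]
  eph <- eph[order(eph$time), , drop = FALSE]

  no <- nrow(opt); ne <- nrow(eph)
  usedE <- logical(ne); usedO <- logical(no)
  pairRows <- NULL
  if (no && ne) {
    dt <- abs(outer(eph$time, opt$time, "-"))
    cand <- which(dt <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      d <- dt[cand]
      ord <- order(d, eph$time[cand[, 1L]], opt$time[cand[, 2L]])
      cand <- cand[ord, , drop = FALSE]
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!usedE[i] && !usedO[j]) {
          usedE[i] <- TRUE; usedO[j] <- TRUE; keep[r] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) {
        pairRows <- data.frame(
          ephys_time = eph$time[cand[, 1L]],
          ephys_amplitude = eph$amplitude[cand[, 1L]],
          optical_time = opt$time[cand[, 2L]],
          optical_amplitude = opt$amplitude[cand[, 2L]],
          dt = dt[cand])
        pairRows <- pairRows[order(pairRows$ephys_time), , drop = FALSE]
        rownames(pairRows) <- NULL
      }
    }
  }
  if (is.null(pairRows)) {
    pairRows <- data.frame(ephys_time = numeric(0), ephys_amplitude = numeric(0),
                           optical_time = numeric(0),
                           optical_amplitude = numeric(0), dt = numeric(0))
  }
  new("MatchResult", pairs = pairRows,
      unmatchedEphys = eph[!usedE, , drop = FALSE],
      unmatchedOptical = opt[!usedO, , drop = FALSE],
      tolerance = as.numeric(tolerance))
}

#' Fraction of electrophysiological events captured optically
#'
#' The number of matched pairs divided by the total number of
#' electrophysiological events.
#'
#' @param match a [MatchResult-class].
#' @return Fraction in \[0, 1\].
#' @export
detectionFraction <- function(match) {
  stopifnot(is(match, "MatchResult"))
  ne <- nrow(matchedPairs(match)) + nrow(unmatchedEphys(match))
  if (!ne) stop("detection fraction undefined: no ephys events", call. = FALSE)
  nrow(matchedPairs(match)) / ne
}

#' Pearson correlation of paired miniature amplitudes
#'
#' Pearson correlation between the matched electrophysiological amplitudes
#' (mV) and optical amplitudes (dF/F or dR/R).
#'
#' @param match a [MatchResult-class] with >= 3 pairs.
#' @return A list: `r`, `r_squared`, `n`.
#' @export
amplitudeCorrelation <- function(match) {
  stopifnot(is(match, "MatchResult"))
  p <- matchedPairs(match)
  if (nrow(p) < 3L) stop("need >= 3 matched pairs", call. = FALSE)
  if (sd(p$ephys_amplitude) == 0 || sd(p$optical_amplitude) == 0) {
    stop("zero variance in one amplitude margin", call. = FALSE)
  }
  r <- cor(p$ephys_amplitude, p$optical_amplitude)
  list(r = r, r_squared = r^2, n = nrow(p))
}

#' Pairwise paired t-tests between active zones
#'
#' For every pair of active zones within a preparation, performs a paired
#' two-tailed t-test on their per-stimulus peak responses (paired by stimulus
#' number) and reports the fraction of pairs significant at `alpha`. The
#' tests are computed in closed form from the per-AZ means and the cross-AZ
#' covariance of the stimulus responses — identical to
#' `t.test(x, y, paired = TRUE)` — so that large replicate calibrations
#' remain fast. Pairs whose per-stimulus differences have zero variance have
#' an undefined t statistic; their p is NA and they are excluded from the
#' fraction.
#'
#' @param azm an [AZMatrix-class] with >= 2 AZs and >= 2 stimuli.
#' @param alpha significance level (default 0.05).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the convention of reporting raw fractions).
#' @return A list: `fraction_significant`, `p_matrix` (symmetric, NA
#'   diagonal), `n_pairs`, `n_excluded`.
#' @export
azPairwiseTests <- function(azm, alpha = 0.05, adjust = "none") {
  stopifnot(is(azm, "AZMatrix"))
  a <- azAmplitudes(azm)
  nAz <- nrow(a); nStim <- ncol(a)
  if (nAz < 2L) stop("need >= 2 active zones for pairwise tests", call. = FALSE)
  if (nStim < 2L) stop("need >= 2 paired observations per AZ", call. = FALSE)
  m <- rowMeans(a)
  # cross-AZ covariance of stimulus responses: var(x_i - x_j) =
  # C[i,i] + C[j,j] - 2 C[i,j]
  C <- stats::cov(t(a))
  md <- outer(m, m, "-")
  vd <- outer(diag(C), diag(C), "+") - 2 * C
  vd[vd < 0] <- 0   # guard tiny negative round-off
  tstat <- md / sqrt(vd / nStim)
  p <- 2 * pt(-abs(tstat), df = nStim - 1L)
  p[!is.finite(tstat)] <- NA_real_
  diag(p) <- NA_real_
  dimnames(p) <- list(azIds(azm), azIds(azm))

  up <- p[upper.tri(p)]
  if (adjust != "none") {
    adj <- stats::p.adjust(up, method = adjust)
    p[upper.tri(p)] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    up <- adj
  }
  defined <- !is.na(up)
  if (!any(defined)) {
    stop("all AZ pairs have zero-variance differences; no tests defined",
         call. = FALSE)
  }
  list(fraction_significant = mean(up[defined] < alpha),
       p_matrix = p, n_pairs = sum(defined), n_excluded = sum(!defined))
}

#' Flag active zones outside the pooled interquartile range
#'
#' Computes Q1 and Q3 by linear-interpolation quartiles over all individual
#' responses pooled across AZs, and flags every AZ whose mean response lies
#' below Q1 or above Q3.
#'
#' @param azm an [AZMatrix-class] with >= 4 pooled values.
#' @return A list: `q1`, `q3`, `flagged` (AZ ids), `az_means`.
#' @export
iqrFlags <- function(azm) {
  stopifnot(is(azm, "AZMatrix"))
  pooled <- as.vector(azAmplitudes(azm))
  if (length(pooled) < 4L) stop("need >= 4 pooled values", call. = FALSE)
  q <- quantile(pooled, c(0.25, 0.75), type = 7, names = FALSE)
  m <- rowMeans(azAmplitudes(azm))
  flagged <- azIds(azm)[m < q[1L] | m > q[2L]]
  list(q1 = q[1L], q3 = q[2L], flagged = flagged,
       az_means = setNames(m, azIds(azm)))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two amplitude distributions with the two-sample KS statistic
#' \eqn{D = \sup_x |ECDF_a(x) - ECDF_b(x)|} and its asymptotic two-sided p
#' value.
#'
#' @param a,b non-empty numeric samples.
#' @return A list: `D`, `p`, `n_a`, `n_b`.
#' @export
ksCompare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}
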