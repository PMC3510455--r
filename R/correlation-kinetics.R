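#' Normalized cross-correlation of two time series
#'
#' `CC(tau) = <da(t) db(t + tau)> / (SD(a) SD(b))` with mean-subtracted
#' series, evaluated at lags `0, 1, ..., max_lag` frames. For an
#' anticorrelated donor/acceptor pair the CC is negative near lag 0 and decays
#' to 0 at long lags; its decay constant is the cross-correlation time.
#'
#' @param a,b Equal-length numeric series (at least 10 times `max_lag` frames,
#'   both with nonzero variance).
#' @param max_lag Maximum lag in seconds.
#' @param frame_interval Frame time, s (default 0.030).
#' @return A `cc_result`: list with `lags` (s, starting at 0), `cc`,
#'   `frame_interval`, `n_molecules` (1), and `tau`/`amplitude` slots filled by
#'   [fit_cc_exponential()].
#' @export
cross_correlate <- function(a, b, max_lag = 1, frame_interval = 0.030) {
  stopifnot(length(a) == length(b), max_lag > 0, frame_interval > 0)
  n <- length(a)
  kmax <- floor(max_lag / frame_interval)
  if (n < 10 * kmax)
    stop("series too short: need >= 10 * max_lag frames")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance series")
  da <- a - mean(a); db <- b - mean(b)
  denom <- sd(a) * sd(b)
  cc <- vapply(0:kmax, function(k)
    mean(da[seq_len(n - k)] * db[seq_len(n - k) + k]) / denom,
    numeric(1))
  structure(list(lags = (0:kmax) * frame_interval, cc = cc,
                 frame_interval = frame_interval, n_molecules = 1L,
                 tau = NA_real_, amplitude = NA_real_),
            class = "cc_result")
}

#' Average per-molecule cross-correlations
#'
#' Arithmetic mean of per-molecule CC curves on a common lag grid (equal
#' weights per molecule).
#'
#' @param cc_list List of `cc_result` objects with identical lag grids.
#' @return A `cc_result` with `n_molecules` set to the number averaged.
#' @export
average_cc <- function(cc_list) {
  stopifnot(length(cc_list) >= 1)
  lags <- cc_list[[1]]$lags
  for (cc in cc_list)
    if (!isTRUE(all.equal(cc$lags, lags))) stop("lag grids differ")
  m <- rowMeans(vapply(cc_list, `[[`, numeric(length(lags)), "cc"))
  structure(list(lags = lags, cc = m,
                 frame_interval = cc_list[[1]]$frame_interval,
                 n_molecules = sum(vapply(cc_list, `[[`, integer(1),
                                          "n_molecules")),
                 tau = NA_real_, amplitude = NA_real_),
            class = "cc_result")
}

#' Donor/acceptor cross-correlation averaged over molecules
#'
#' Convenience wrapper: per molecule, cross-correlate two channels of an
#' intensity trace (or two series of a FRET trace), then average with equal
#' weights.
#'
#' @param traces List of [intensity_trace()] or [fret_trace()] objects.
#' @param channels Length-2 character vector naming the two series (default
#'   `c("donor", "acceptor1")`; use e.g. `c("e1", "e2")` for FRET traces).
#' @inheritParams cross_correlate
#' @return A `cc_result` averaged over molecules.
#' @export
cross_correlate_traces <- function(traces, channels = c("donor", "acceptor1"),
                                   max_lag = 1) {
  stopifnot(length(traces) >= 1, length(channels) == 2)
  ccs <- lapply(traces, function(tr) {
    series <- if (inherits(tr, "fret_trace")) tr$efficiencies else tr$channels
    cross_correlate(series[[channels[1]]], series[[channels[2]]],
                    max_lag = max_lag, frame_interval = tr$frame_interval)
  })
  average_cc(ccs)
}

#' Fit a single exponential to a cross-correlation curve
#'
#' Least-squares fit of `A * exp(-lag / tau)` to the sign-corrected CC,
#' excluding lag 0 (the shot-noise spike). The curve is flipped so its initial
#' decay is positive: the same fit then serves negatively correlated
#' donor/acceptor pairs and two-FRET pairs, since the sign carries no kinetic
#' information, while the zero-mean tail noise is left unrectified.
#'
#' @param cc A `cc_result` with at least 5 nonzero lag points.
#' @return The `cc_result` with `tau` (s) and `amplitude` filled in.
#' @export
fit_cc_exponential <- function(cc) {
  stopifnot(inherits(cc, "cc_result"))
  keep <- cc$lags > 0
  lag <- cc$lags[keep]
  y <- cc$cc[keep]
  if (length(lag) < 5) stop("need at least 5 nonzero lag points")
  head_sign <- sign(mean(y[seq_len(min(3, length(y)))]))
  if (head_sign == 0 || max(abs(y)) == 0)
    stop("flat cross-correlation: no decay to fit")
  y <- head_sign * y
  est <- tryCatch({
    # log-linear start values on the positive part of the curve
    pos <- y > max(y) * 1e-3
    fit0 <- lm(log(y[pos]) ~ lag[pos])
    tau0 <- unname(-1 / min(coef(fit0)[2], -1e-6))
    a0 <- unname(exp(coef(fit0)[1]))
    fit <- minpack.lm::nlsLM(y ~ A * exp(-lag / tau),
                             start = list(A = a0, tau = tau0),
                             lower = c(A = 0, tau = 1e-8),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(fit)
  }, error = function(e) NULL)
  if (is.null(est) || !is.finite(est["tau"]) || est["tau"] <= 0) {
    # fast-decay / low-amplitude curves can defeat the gradient-based fit;
    # fall back to a deterministic profiled least-squares search over tau
    # (amplitude solved in closed form for each candidate decay time)
    taus <- exp(seq(log(min(lag) / 10), log(max(lag) * 5), length.out = 400))
    sse <- vapply(taus, function(tau) {
      w <- exp(-lag / tau)
      a <- max(sum(w * y) / sum(w * w), 0)
      sum((y - a * w)^2)
    }, numeric(1))
    tau_hat <- taus[which.min(sse)]
    w <- exp(-lag / tau_hat)
    est <- c(A = max(sum(w * y) / sum(w * w), 0), tau = tau_hat)
    if (est["A"] <= 0)
      stop("cross-correlation exponential fit did not converge")
  }
  cc$tau <- unname(est["tau"])
  cc$amplitude <- unname(est["A"])
  cc
}

#' Detect binding (docking) events in an intensity trace
#'
#' Events are maximal runs of frames whose total intensity exceeds a
#' threshold, lasting at least `min_frames` frames. The default `"auto"`
#' threshold estimates the dark background from the lower half of the total
#' intensity distribution and sets `background mean + 4 * background SD`
#' (assumes the trace is dark at least half of the time, the typical docking
#' movie regime).
#'
#' @param trace An [intensity_trace()].
#' @param threshold Numeric threshold in a.u., or `"auto"`.
#' @param min_frames Minimum event length in frames (default 2).
#' @return Data frame of events: `start_frame`, `end_frame` (1-based,
#'   inclusive) and `dwell` (seconds). Zero rows when nothing is detected.
#' @export
detect_binding_events <- function(trace, threshold = "auto", min_frames = 2) {
  stopifnot(inherits(trace, "intensity_trace"))
  total <- Reduce(`+`, trace$channels)
  if (identical(threshold, "auto")) {
    # two-pass background estimate: a robust first cut isolates the dark
    # frames, whose untruncated moments then set the threshold
    dark <- total[total < median(total) + 2 * mad(total)]
    threshold <- mean(dark) + 4 * sd(dark)
  }
  above <- total > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             dwell = r$lengths[keep] * trace$frame_interval)
}

#' Exponential lifetime from dwell times
#'
#' Maximum-likelihood mean of exponentially distributed dwells with optional
#' right censoring: censored dwells contribute their observed duration to the
#' likelihood, so `mean = sum(all dwells) / n_uncensored`, with standard error
#' `mean / sqrt(n_uncensored)`. For fully uncensored data this is the sample
#' mean.
#'
#' @param dwells Numeric dwell times, seconds.
#' @param censored Logical vector (same length): TRUE where the dwell was cut
#'   short (e.g. by the end of the movie). Default: none censored.
#' @return List with `mean`, `se`, `n`, `n_censored`.
#' @export
fit_dwell_exponential <- function(dwells, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(dwells))
  stopifnot(length(censored) == length(dwells), all(dwells >= 0))
  n_unc <- sum(!censored)
  if (n_unc == 0) stop("all dwells censored: lifetime unidentifiable")
  if (n_unc < 10)
    warning("fewer than 10 uncensored dwells: estimate will be imprecise")
  m <- sum(dwells) / n_unc
  list(mean = m, se = m / sqrt(n_unc), n = length(dwells),
       n_censored = sum(censored))
}
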