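#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' One global model is fitted by Baum-Welch expectation-maximization, pooled
#' across all molecules (tied emission parameters), which stabilizes the state
#' means when many short traces are aggregated. Initialization is
#' deterministic: state means at evenly spaced quantiles of the pooled data,
#' common SD, sticky transition matrix. The log-likelihood is non-decreasing
#' over iterations (recorded in the result); a degenerate state (vanishing SD
#' or occupancy) triggers a restart from perturbed starting values, at most
#' `max_restarts` times. States are relabelled in ascending order of mean.
#'
#' @param traces List of [fret_trace()] objects (or numeric vectors).
#' @param n_states Number of states (e.g. 3 for NH/HS2/HS1-type data).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Convergence tolerance on the total log-likelihood (default 1e-6).
#' @param max_restarts Restarts allowed after degeneracy (default 5).
#' @param seed Seed for the restart perturbations (default 1; the first
#'   attempt is fully deterministic).
#' @return An `hmm_model`: list with `means`, `sds`, `trans` (per-frame
#'   transition matrix), `init`, `loglik`, `loglik_trace`, `n_iter`,
#'   `frame_interval`.
#' @export
fit_hmm <- function(traces, n_states, max_iter = 100, tol = 1e-6,
                    max_restarts = 5, seed = 1) {
  obs <- trace_series(traces)
  frame_interval <- trace_frame_interval(traces)
  total_frames <- sum(lengths(obs))
  if (total_frames < 50 * n_states)
    stop("need at least 50 frames per state in total")
  pooled <- unlist(obs)
  withr::local_seed(seed)
  for (attempt in 0:max_restarts) {
    par <- hmm_init(pooled, n_states, perturb = attempt > 0)
    fit <- tryCatch(hmm_em(obs, par, max_iter, tol),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      fit$frame_interval <- frame_interval
      return(fit)
    }
  }
  stop("HMM fit degenerate after ", max_restarts, " restarts")
}

trace_series <- function(traces) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  lapply(traces, function(tr) {
    x <- if (inherits(tr, "fret_trace")) tr$efficiencies[[1]] else as.numeric(tr)
    x[is.finite(x)]
  })
}

trace_frame_interval <- function(traces) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  fi <- unique(vapply(traces, function(tr)
    if (inherits(tr, "fret_trace")) tr$frame_interval else 0.030, numeric(1)))
  if (length(fi) > 1) stop("traces have differing frame intervals")
  fi
}

hmm_init <- function(pooled, k, perturb = FALSE) {
  q <- quantile(pooled, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (perturb) q <- q + rnorm(k, sd = max(sd(pooled) / 4, 1e-3))
  q <- sort(q)
  sd0 <- max(sd(pooled) / k, 1e-3)
  trans <- matrix(0.1 / max(k - 1, 1), k, k)
  diag(trans) <- 0.9
  list(means = q, sds = rep(sd0, k), trans = trans, init = rep(1 / k, k))
}

hmm_em <- function(obs, par, max_iter, tol) {
  k <- length(par$means)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    g_sum <- numeric(k); g_x <- numeric(k); g_xx <- numeric(k)
    xi <- matrix(0, k, k); g1 <- numeric(k); ll <- 0
    for (x in obs) {
      e <- .hmm_estep_cpp(x, par$means, par$sds, par$trans, par$init)
      g_sum <- g_sum + e$gamma_sum
      g_x <- g_x + e$gamma_x
      g_xx <- g_xx + e$gamma_xx
      xi <- xi + e$xi_sum
      g1 <- g1 + e$gamma1
      ll <- ll + e$loglik
    }
    ll_trace <- c(ll_trace, ll)
    if (any(g_sum < 1e-6)) stop("degenerate state: zero occupancy")
    par$means <- g_x / g_sum
    v <- g_xx / g_sum - par$means^2
    if (any(v < 1e-10)) stop("degenerate state: vanishing emission variance")
    par$sds <- sqrt(v)
    par$trans <- xi / rowSums(xi)
    par$init <- g1 / sum(g1)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(par$means)
  structure(list(means = par$means[ord], sds = par$sds[ord],
                 trans = par$trans[ord, ord, drop = FALSE],
                 init = par$init[ord], loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = length(ll_trace)),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states, logLik %.2f (%d EM iterations)\n",
              length(x$means), x$loglik, x$n_iter))
  cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  sds:  ", paste(signif(x$sds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Idealize a FRET trace with a fitted HMM
#'
#' Most-probable joint state path (Viterbi), run-length encoded into dwell
#' segments.
#'
#' Camera frames that straddle a direct low-to-high transition integrate an
#' intermediate intensity and are systematically idealized as spurious
#' one-frame visits to a middle state. `min_dwell = 2` removes such segments
#' (each short segment's frames are merged into the preceding dwell), which is
#' the appropriate setting when extracting transition rates and recognition
#' efficiencies from camera-binned data; the default `min_dwell = 1` retains
#' every Viterbi segment.
#'
#' @param model An `hmm_model` from [fit_hmm()].
#' @param trace A [fret_trace()] or numeric vector.
#' @param min_dwell Minimum dwell length in frames (default 1 = no filtering).
#' @return An `idealization`: list with `states` (per-frame index, ascending
#'   by state mean), `segments` (data frame `state`, `start`, `length` in
#'   frames), `means` (model state means), `frame_interval`, `molecule_id`.
#' @export
idealize <- function(model, trace, min_dwell = 1) {
  stopifnot(inherits(model, "hmm_model"), min_dwell >= 1)
  x <- trace_series(list(trace))[[1]]
  fi <- if (inherits(trace, "fret_trace")) trace$frame_interval
        else model$frame_interval
  path <- .hmm_viterbi_cpp(x, model$means, model$sds, model$trans, model$init)
  if (min_dwell > 1) path <- filter_short_dwells(path, min_dwell)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  segments <- data.frame(state = r$values,
                         start = ends - r$lengths + 1L,
                         length = r$lengths)
  structure(list(states = path, segments = segments, means = model$means,
                 frame_interval = fi,
                 molecule_id = if (inherits(trace, "fret_trace"))
                   trace$molecule_id else "mol1"),
            class = "idealization")
}

# Merge dwells shorter than min_dwell frames into the preceding dwell (the
# first dwell merges forward); repeat until no short dwell remains or only one
# segment is left.
filter_short_dwells <- function(path, min_dwell) {
  repeat {
    r <- rle(path)
    if (length(r$lengths) <= 1) return(path)
    short <- which(r$lengths < min_dwell)
    if (length(short) == 0) return(path)
    i <- short[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    path <- inverse.rle(r)
  }
}

#' @export
print.idealization <- function(x, ...) {
  cat(sprintf("<idealization> %s: %d frames, %d segments, %d states\n",
              x$molecule_id, length(x$states), nrow(x$segments),
              length(x$means)))
  invisible(x)
}
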