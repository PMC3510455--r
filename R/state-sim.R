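#' Kinetic state model for homology-recognition traces
#'
#' Continuous-time Markov model over the sliding/recognition states observed
#' when a duplex carries short homology to two sites on the filament:
#' `NH` (non-homologous sliding, low FRET), `HS2` (distal homology site, mid
#' FRET) and `HS1` (proximal site, high FRET), with Gaussian emission noise
#' around the per-state FRET means.
#'
#' The default rate matrix emulates the 6-nt-homology regime: the NH exit rate
#' is 2 /s with a 55:45 branching toward HS2 vs HS1, and the total exit rate
#' from either homology site is threefold lower (2/3 /s, split evenly).
#'
#' @param state_names Ordered state labels.
#' @param fret_means Per-state FRET means, strictly increasing.
#' @param emission_sd Per-state Gaussian emission SD (recycled if scalar).
#' @param rate_matrix Square matrix of transition rates `k[i, j]` (per second,
#'   `i != j`, diagonal ignored), dimnames matching `state_names`.
#' @param seed Optional default seed carried by the model.
#' @return A `state_model` object.
#' @export
state_model <- function(state_names = c("NH", "HS2", "HS1"),
                        fret_means = c(0.1, 0.5, 0.9),
                        emission_sd = 0.05,
                        rate_matrix = NULL,
                        seed = NULL) {
  k <- length(state_names)
  stopifnot(length(fret_means) == k, all(diff(fret_means) > 0),
            all(emission_sd > 0))
  emission_sd <- rep_len(emission_sd, k)
  if (is.null(rate_matrix)) {
    if (!identical(state_names, c("NH", "HS2", "HS1")))
      stop("supply rate_matrix for non-default state sets")
    rate_matrix <- matrix(c(0,    1.1,  0.9,
                            1/3,  0,    1/3,
                            1/3,  1/3,  0),
                          nrow = 3, byrow = TRUE,
                          dimnames = list(state_names, state_names))
  }
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(nrow(rate_matrix) == k, ncol(rate_matrix) == k)
  diag(rate_matrix) <- 0
  if (any(rate_matrix < 0)) stop("transition rates must be >= 0")
  dimnames(rate_matrix) <- list(state_names, state_names)
  structure(list(state_names = state_names, fret_means = fret_means,
                 emission_sd = emission_sd, rate_matrix = rate_matrix,
                 seed = seed),
            class = "state_model")
}

#' Simulate a continuous-time Markov dwell sequence
#'
#' Gillespie simulation: dwell in state `i` is exponential with mean
#' `1 / sum_j k[i, j]`; the next state is chosen with probability proportional
#' to `k[i, j]`. The final dwell is truncated at `duration` (and flagged as
#' censored).
#'
#' @param model A [state_model()].
#' @param duration Total trace duration, seconds (`> 0`).
#' @param initial_state State name or index to start in (default first state).
#' @param seed Optional seed (defaults to `model$seed`).
#' @return Data frame with columns `state` (factor), `start`, `length`
#'   (seconds) and `censored` (TRUE for the truncated final dwell).
#' @export
simulate_ctmc <- function(model, duration, initial_state = 1,
                          seed = model$seed) {
  stopifnot(inherits(model, "state_model"), duration > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.character(initial_state))
    initial_state <- match(initial_state, model$state_names)
  k_exit <- rowSums(model$rate_matrix)
  state <- integer(0); start <- numeric(0); len <- numeric(0)
  s <- initial_state
  t <- 0
  while (t < duration) {
    dwell <- if (k_exit[s] > 0) rexp(1, rate = k_exit[s]) else Inf
    dwell <- min(dwell, duration - t)
    state <- c(state, s); start <- c(start, t); len <- c(len, dwell)
    t <- t + dwell
    if (t >= duration) break
    s <- sample.int(length(k_exit), 1, prob = model$rate_matrix[s, ])
  }
  censored <- c(rep(FALSE, length(state) - 1), TRUE)
  data.frame(state = factor(model$state_names[state],
                            levels = model$state_names),
             start = start, length = len, censored = censored)
}

#' Render a dwell sequence as a camera-binned FRET trace
#'
#' Each frame takes the occupancy-weighted mean of the state FRET means over
#' the frame window (mimicking camera integration of frames that straddle a
#' transition), plus Gaussian emission noise with the occupancy-weighted SD.
#'
#' @param dwells Data frame from [simulate_ctmc()].
#' @param model The [state_model()] that produced the dwells.
#' @param frame_interval Frame time, s (default 0.030).
#' @param seed Optional seed for the noise draw.
#' @param molecule_id Label.
#' @return A [fret_trace()] with one series `e1` (storage-clipped).
#' @export
emit_fret <- function(dwells, model, frame_interval = 0.030, seed = NULL,
                      molecule_id = "mol1") {
  stopifnot(inherits(model, "state_model"), frame_interval > 0,
            nrow(dwells) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  duration <- dwells$start[nrow(dwells)] + dwells$length[nrow(dwells)]
  nf <- floor(duration / frame_interval + 1e-9)
  if (nf < 1) stop("trace shorter than one frame")
  # cumulative time-integral of the state mean is piecewise linear in t;
  # a frame mean is the difference of the integral at the frame edges
  bounds <- c(dwells$start, duration)
  mu <- model$fret_means[as.integer(dwells$state)]
  sd_state <- model$emission_sd[as.integer(dwells$state)]
  cum_mu <- c(0, cumsum(mu * dwells$length))
  cum_sd <- c(0, cumsum(sd_state * dwells$length))
  edges <- seq_len(nf + 1) - 1
  edges <- pmin(edges * frame_interval, duration)
  interp <- function(cum) {
    i <- findInterval(edges, bounds, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nrow(dwells))
    cum[i] + (edges - bounds[i]) * (cum[i + 1] - cum[i]) /
      pmax(dwells$length[i], .Machine$double.eps)
  }
  f_mu <- diff(interp(cum_mu)) / frame_interval
  f_sd <- diff(interp(cum_sd)) / frame_interval
  e <- f_mu + rnorm(nf, sd = f_sd)
  fret_trace(list(e1 = clip_fret(e, "storage")),
             frame_interval = frame_interval, molecule_id = molecule_id,
             metadata = list(generator = "emit_fret"))
}

#' Simulate a cohort of homology-recognition FRET traces
#'
#' Convenience wrapper: one CTMC realization plus camera-binned Gaussian
#' emissions per molecule, with per-trace derived seeds for reproducibility.
#'
#' @param model A [state_model()].
#' @param n_molecules Number of traces.
#' @param n_frames Frames per trace.
#' @param frame_interval Frame time, s.
#' @param seed Optional root seed.
#' @return List with `traces` (list of [fret_trace()]) and `dwells` (list of
#'   the underlying dwell tables, the ground truth for recovery tests).
#' @export
simulate_recognition_traces <- function(model, n_molecules, n_frames,
                                        frame_interval = 0.030,
                                        seed = model$seed) {
  if (!is.null(seed)) withr::local_seed(seed)
  duration <- n_frames * frame_interval
  init <- sample.int(length(model$state_names), n_molecules, replace = TRUE)
  seeds <- child_seeds(2 * n_molecules)
  dwells <- lapply(seq_len(n_molecules), function(i)
    simulate_ctmc(model, duration, initial_state = init[i],
                  seed = seeds[2 * i - 1]))
  traces <- lapply(seq_len(n_molecules), function(i)
    emit_fret(dwells[[i]], model, frame_interval, seed = seeds[2 * i],
              molecule_id = paste0("mol", i)))
  list(traces = traces, dwells = dwells)
}

#' Simulate a docking/dissociation intensity trace
#'
#' Alternating dark (unbound) and bright (bound) epochs: waiting times to the
#' next docking are exponential with rate `on_rate`, bound dwells are
#' exponential with mean `mean_dwell`. Epoch boundaries are quantized to the
#' frame grid. Bound frames carry the full photon budget split evenly between
#' donor and acceptor; Gaussian noise is added per channel throughout.
#'
#' @param on_rate Docking rate from the dark state, per second.
#' @param mean_dwell Mean bound-state lifetime, seconds.
#' @param duration Total trace duration, seconds.
#' @param frame_interval Frame time, s (default 0.030).
#' @param total_intensity Photon budget per bound frame (default 500).
#' @param noise_sd Gaussian channel noise SD (default 40).
#' @param seed Optional seed.
#' @return An [intensity_trace()] (`donor`, `acceptor1`) with the true bound
#'   epochs in `metadata$events` (data frame of start/end frames, 1-based).
#' @export
simulate_docking_series <- function(on_rate, mean_dwell, duration,
                                    frame_interval = 0.030,
                                    total_intensity = 500, noise_sd = 40,
                                    seed = NULL) {
  stopifnot(on_rate >= 0, mean_dwell > 0, duration > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  nf <- floor(duration / frame_interval)
  bound <- logical(nf)
  events <- data.frame(start_frame = integer(0), end_frame = integer(0))
  t_frame <- 0L  # current frame index (0-based)
  repeat {
    if (on_rate == 0) break
    wait <- rexp(1, rate = on_rate)
    t_frame <- t_frame + as.integer(round(wait / frame_interval))
    if (t_frame >= nf) break
    dwell <- max(1L, as.integer(round(rexp(1, rate = 1 / mean_dwell) /
                                        frame_interval)))
    end <- min(t_frame + dwell, nf)
    bound[(t_frame + 1):end] <- TRUE
    events <- rbind(events,
                    data.frame(start_frame = t_frame + 1L, end_frame = end))
    t_frame <- end
    if (t_frame >= nf) break
  }
  don <- ifelse(bound, total_intensity / 2, 0)
  acc <- ifelse(bound, total_intensity / 2, 0)
  if (noise_sd > 0) {
    don <- don + rnorm(nf, sd = noise_sd)
    acc <- acc + rnorm(nf, sd = noise_sd)
  }
  intensity_trace(list(donor = don, acceptor1 = acc),
                  frame_interval = frame_interval,
                  metadata = list(generator = "simulate_docking_series",
                                  events = events))
}
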