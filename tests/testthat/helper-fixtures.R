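# Shared fixture builders; everything is generated in code at test time.

# Symmetric two-state telegraph signal (+1/-1) with switching rate k per
# second, sampled on a frame grid. Returns the per-frame signal.
make_telegraph <- function(rate, frame_interval, n_frames, seed) {
  withr::local_seed(seed)
  t_total <- n_frames * frame_interval
  times <- cumsum(rexp(ceiling(3 * rate * t_total) + 50, rate = rate))
  times <- times[times < t_total]
  frame_t <- (seq_len(n_frames) - 0.5) * frame_interval
  level <- (findInterval(frame_t, times) %% 2L) * 2L - 1L
  as.numeric(level)
}

# Three-channel trace with an acceptor-2 photobleach step of known gamma:
# before the step acceptor2 emits `a2_level`; at the step that signal
# reappears in acceptor1 scaled by gamma_true (energy redistribution).
make_gamma_step_trace <- function(gamma_true, n_frames = 200,
                                  step_at = 100, a2_level = 60,
                                  noise_sd = 0, seed = 1) {
  withr::local_seed(seed)
  pre <- seq_len(n_frames) <= step_at
  a2 <- ifelse(pre, a2_level, 0)
  a1 <- ifelse(pre, 200, 200 + gamma_true * a2_level)
  d <- rep(250, n_frames)
  if (noise_sd > 0) {
    a1 <- a1 + rnorm(n_frames, sd = noise_sd)
    a2 <- a2 + rnorm(n_frames, sd = noise_sd)
    d <- d + rnorm(n_frames, sd = noise_sd)
  }
  intensity_trace(list(donor = d, acceptor1 = a1, acceptor2 = a2))
}

# Build an idealization object directly from a per-frame state path (oracle
# side-channel for transition bookkeeping tests).
make_idealization <- function(states, means, frame_interval = 0.030,
                              molecule_id = "mol1") {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  structure(list(states = states,
                 segments = data.frame(state = r$values,
                                       start = ends - r$lengths + 1L,
                                       length = r$lengths),
                 means = means, frame_interval = frame_interval,
                 molecule_id = molecule_id),
            class = "idealization")
}

# Brute-force transition counter over idealization segments (independent of
# transition_stats).
brute_force_counts <- function(idealizations, n_states) {
  counts <- matrix(0L, n_states, n_states)
  for (idl in idealizations) {
    st <- idl$segments$state
    if (length(st) < 2) next
    for (i in seq_len(length(st) - 1))
      counts[st[i], st[i + 1]] <- counts[st[i], st[i + 1]] + 1L
  }
  counts
}
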