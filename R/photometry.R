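#' Channel correction parameters
#'
#' Background offsets, spectral leakage fractions and the gamma factor used to
#' turn raw camera intensities into corrected channel intensities. Corrections
#' are applied in the order background, leakage, gamma.
#'
#' @param background Named numeric vector of per-channel background levels
#'   (a.u.), e.g. `c(donor = 50, acceptor1 = 40)`. Channels not named get 0.
#' @param leakage_donor_a1 Fractional bleed-through of donor signal into the
#'   acceptor-1 channel (default 0.12, a typical dual-view value).
#' @param leakage_a1_a2 Fractional bleed-through of acceptor-1 signal into the
#'   acceptor-2 channel (default 0.05).
#' @param gamma Detection-efficiency correction applied multiplicatively to
#'   the acceptor-2 channel (`> 0`); estimate it from an acceptor-2 photobleach
#'   step with [estimate_gamma()].
#' @return A `correction_set` object.
#' @export
correction_set <- function(background = c(donor = 0, acceptor1 = 0,
                                          acceptor2 = 0),
                           leakage_donor_a1 = 0.12, leakage_a1_a2 = 0.05,
                           gamma = 1) {
  stopifnot(leakage_donor_a1 >= 0, leakage_donor_a1 < 1,
            leakage_a1_a2 >= 0, leakage_a1_a2 < 1, gamma > 0)
  structure(list(background = background,
                 leakage_donor_a1 = leakage_donor_a1,
                 leakage_a1_a2 = leakage_a1_a2,
                 gamma = gamma),
            class = "correction_set")
}

#' Apply background, leakage and gamma corrections to a trace
#'
#' Per channel: subtract the background, then subtract the leakage
#' contribution of the upstream (already background-corrected) channel, then
#' scale acceptor 2 by gamma. With zero background, zero leakage and
#' `gamma = 1` this is the identity.
#'
#' @param trace An [intensity_trace()] with `donor`, `acceptor1` and
#'   optionally `acceptor2` channels.
#' @param corr A [correction_set()].
#' @return The corrected [intensity_trace()].
#' @export
apply_corrections <- function(trace, corr) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(corr, "correction_set"))
  ch <- trace$channels
  if (is.null(ch$donor) || is.null(ch$acceptor1))
    stop("trace must have 'donor' and 'acceptor1' channels")
  bg <- function(name) if (name %in% names(corr$background))
    corr$background[[name]] else 0
  d <- ch$donor - bg("donor")
  a1 <- ch$acceptor1 - bg("acceptor1") - corr$leakage_donor_a1 * d
  out <- list(donor = d, acceptor1 = a1)
  if (!is.null(ch$acceptor2)) {
    a2 <- ch$acceptor2 - bg("acceptor2") - corr$leakage_a1_a2 * a1
    out$acceptor2 <- corr$gamma * a2
  }
  intensity_trace(out, frame_interval = trace$frame_interval,
                  molecule_id = trace$molecule_id, metadata = trace$metadata)
}

#' Estimate the gamma factor from an acceptor-2 photobleach step
#'
#' Locates the acceptor-2 photobleaching event as the largest single-frame
#' drop exceeding `min_step_sd` times the robust noise SD (MAD of the
#' single-frame differences), then returns
#' `gamma = delta I_acceptor1 / delta I_acceptor2`, the ratio of the intensity
#' changes across the step (means over `window` frames on each side,
#' excluding the step frame itself). Invariant to overall intensity scaling.
#'
#' @param trace An [intensity_trace()] with `acceptor1` and `acceptor2`.
#' @param window Frames averaged on each side of the step (default 20).
#' @param min_step_sd Detection threshold in robust noise SDs (default 5).
#' @return Estimated gamma (scalar), with the step frame as attribute
#'   `"step_frame"`.
#' @export
estimate_gamma <- function(trace, window = 20, min_step_sd = 5) {
  stopifnot(inherits(trace, "intensity_trace"))
  a2 <- trace$channels$acceptor2
  a1 <- trace$channels$acceptor1
  if (is.null(a1) || is.null(a2))
    stop("trace must have 'acceptor1' and 'acceptor2' channels")
  d2 <- diff(a2)
  noise_sd <- mad(d2) / sqrt(2)
  step <- which.min(d2)  # largest drop
  if (-d2[step] < min_step_sd * noise_sd)
    stop("no acceptor-2 photobleach step found")
  pre <- max(1, step - window):step
  post <- (step + 1):min(length(a2), step + window)
  delta_a2 <- mean(a2[pre]) - mean(a2[post])
  delta_a1 <- mean(a1[post]) - mean(a1[pre])
  structure(delta_a1 / delta_a2, step_frame = step)
}

#' Compute apparent FRET efficiencies from a corrected trace
#'
#' Per frame and acceptor `i`: `E_i = I_{A,i} / (sum_j I_{A,j} + I_D)`. With a
#' single acceptor this is the usual `I_A / (I_A + I_D)`. Frames whose total
#' intensity is not positive are flagged invalid (`NA`). Values are stored
#' under the storage clipping policy (see [clip_fret()]).
#'
#' @param trace A corrected [intensity_trace()].
#' @param clip Clipping policy passed to [clip_fret()] (default `"storage"`);
#'   `NULL` disables clipping.
#' @return A [fret_trace()] with series `e1` (and `e2` when a second acceptor
#'   is present).
#' @export
fret_efficiencies <- function(trace, clip = "storage") {
  stopifnot(inherits(trace, "intensity_trace"))
  ch <- trace$channels
  acc_names <- grep("^acceptor", names(ch), value = TRUE)
  if (is.null(ch$donor) || length(acc_names) == 0)
    stop("trace must have 'donor' and at least one acceptor channel")
  acc <- do.call(cbind, ch[acc_names])
  total <- ch$donor + rowSums(acc)
  bad <- !(total > 0)
  if (any(bad)) warning(sum(bad), " frame(s) with non-positive total ",
                        "intensity flagged invalid")
  e <- acc / total
  e[bad, ] <- NA_real_
  if (!is.null(clip)) e <- apply(e, 2, clip_fret, policy = clip)
  e <- matrix(e, ncol = length(acc_names))
  out <- setNames(as.list(as.data.frame(e)),
                  paste0("e", seq_along(acc_names)))
  fret_trace(out, frame_interval = trace$frame_interval,
             molecule_id = trace$molecule_id, metadata = trace$metadata)
}

#' Pearson correlation between two FRET efficiency series
#'
#' Thin, argument-checked wrapper over the sample Pearson coefficient, used to
#' quantify the anticorrelation of the two apparent efficiencies in
#' three-color sliding data.
#'
#' @param e1,e2 Equal-length numeric series (length >= 3, non-constant);
#'   `NA` frames are dropped pairwise.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_correlation <- function(e1, e2) {
  stopifnot(length(e1) == length(e2), length(e1) >= 3)
  keep <- complete.cases(e1, e2)
  e1 <- e1[keep]; e2 <- e2[keep]
  if (sd(e1) == 0 || sd(e2) == 0) stop("zero variance series")
  cor(e1, e2)
}
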