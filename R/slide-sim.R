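#' Configuration of the 1D sliding Monte Carlo simulation
#'
#' Fully specifies a simulated sliding experiment: an unbiased random walk of
#' the duplex along the filament register with micro-step `step_size`, binned
#' into camera frames of `frame_interval` with a fixed photon budget of
#' `total_intensity` per frame and additive Gaussian noise per channel.
#'
#' The micro time step is derived from the random-walk/diffusion
#' correspondence, `tau_micro = step_size^2 / (2 * D_register)`, so each
#' +/- `step_size` move reproduces the requested diffusion coefficient
#' exactly; one 30 ms frame then averages on the order of 1e4-1e5 micro-steps.
#'
#' @param d_um2 Sliding diffusion coefficient in um^2/s. Ignored when `d_bp2`
#'   is given.
#' @param d_bp2 Alternative: diffusion coefficient directly in register
#'   (bp = nt) units squared per second.
#' @param step_size Monte Carlo step in bp; must be in (0, 0.1].
#' @param frame_interval Camera frame time, s (default 0.030).
#' @param n_frames Frames per simulated molecule.
#' @param total_intensity Photon budget per frame, a.u. (default 500).
#' @param noise_sd Gaussian noise SD added independently per channel, a.u.
#'   (default 40, the literal reading of a 40 a.u. "peak intensity").
#' @param min_overlap Minimum filament-duplex contact, bp (default 9). The
#'   sliding coordinate reflects between 0 (the junction, blocked by the
#'   anchored duplex stem) and `filament_length - min_overlap` (the duplex
#'   overhanging the free filament end at minimal contact).
#' @param seed Optional RNG seed for reproducible simulations.
#' @return A `slide_sim_config` object.
#' @export
slide_sim_config <- function(d_um2 = 0.9e-3, d_bp2 = NULL, step_size = 0.1,
                             frame_interval = 0.030, n_frames = 1000,
                             total_intensity = 500, noise_sd = 40,
                             min_overlap = 9, seed = NULL) {
  stopifnot(step_size > 0, step_size <= 0.1, frame_interval > 0,
            n_frames > 0, total_intensity > 0, noise_sd >= 0, min_overlap >= 0)
  if (is.null(d_bp2)) {
    stopifnot(d_um2 >= 0)
  } else {
    stopifnot(d_bp2 >= 0)
  }
  structure(list(d_um2 = d_um2, d_bp2 = d_bp2, step_size = step_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 min_overlap = min_overlap, seed = seed),
            class = "slide_sim_config")
}

# Diffusion coefficient on the register lattice (bp^2/s == nt^2/s). The
# register rise is geometry$rise_per_nt (Angstrom), i.e. rise_nm = rise/10.
register_diffusion <- function(config, geometry) {
  if (!is.null(config$d_bp2)) return(config$d_bp2)
  diffusion_um2_to_bp2(config$d_um2, rise_nm = geometry$rise_per_nt / 10)
}

micro_step_time <- function(config, geometry) {
  d_reg <- register_diffusion(config, geometry)
  if (d_reg == 0) return(Inf)
  config$step_size^2 / (2 * d_reg)
}

steps_per_frame <- function(config, geometry) {
  tau <- micro_step_time(config, geometry)
  if (!is.finite(tau)) return(0L)
  max(1L, as.integer(round(config$frame_interval / tau)))
}

# Reflecting domain of the tracked (junction-proximal) duplex end, register
# units. The junction side is blocked at 0: the anchored duplex stem sits
# there, so the incoming duplex cannot slide below the filament start. On the
# free-end side the duplex may overhang the filament as long as at least
# min_overlap bp remain in contact, so the end runs up to
# filament_length - min_overlap.
walk_domain <- function(geometry, min_overlap) {
  hi <- geometry$filament_length - min_overlap
  if (hi <= 0)
    stop("min_overlap leaves no sliding range on this filament")
  c(0, hi)
}

# Draw n child seeds for compiled kernels from the current R RNG stream.
child_seeds <- function(n) sample.int(2147483647L, n, replace = TRUE)

#' Simulate a 1D sliding trajectory
#'
#' Unbiased +/- `step_size` random walk of the tracked duplex end along the
#' filament register, with reflecting boundaries at the minimum-overlap limits
#' (or at user-supplied bounds, possibly infinite). With `d = 0` the
#' trajectory is constant.
#'
#' @param config A [slide_sim_config()].
#' @param geometry A [filament_geometry()].
#' @param n_steps Number of micro-steps; defaults to
#'   `n_frames * steps_per_frame`.
#' @param boundary Length-2 numeric, reflecting bounds of the walk; defaults
#'   to the minimum-overlap domain from `geometry`. Use `c(-Inf, Inf)` for an
#'   unbounded walk.
#' @param x0 Start position (register units); defaults to the first acceptor
#'   position clamped into the domain.
#' @param thin Keep every `thin`-th position (memory control for long walks).
#' @param seed Optional seed (defaults to `config$seed`).
#' @return Numeric vector of positions after each retained micro-step.
#' @export
simulate_trajectory <- function(config, geometry, n_steps = NULL,
                                boundary = NULL, x0 = NULL, thin = 1L,
                                seed = config$seed) {
  stopifnot(inherits(config, "slide_sim_config"),
            inherits(geometry, "filament_geometry"))
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(boundary)) boundary <- walk_domain(geometry, config$min_overlap)
  spf <- steps_per_frame(config, geometry)
  if (is.null(n_steps)) n_steps <- config$n_frames * max(spf, 1L)
  if (is.null(x0)) {
    x0 <- geometry$acceptor_positions[1] - geometry$donor_position
    x0 <- min(max(x0, boundary[1]), boundary[2])
  }
  if (spf == 0L) {  # D = 0: no diffusion
    keep <- floor(n_steps / thin)
    return(rep(x0, keep))
  }
  if (diff(boundary) == 0 && register_diffusion(config, geometry) > 0)
    warning("zero-width domain with D > 0: trajectory is static")
  .walk_positions_cpp(n_steps, config$step_size, x0,
                      boundary[1], boundary[2], as.integer(thin),
                      child_seeds(1))
}

# Per-position FRET efficiencies toward each acceptor (matrix, one column per
# acceptor), partitioning donor excitations by Foerster rate ratios. With a
# single acceptor this reduces to the standard E = 1/(1 + (L/R0)^6).
position_efficiencies <- function(positions, geometry, couplings) {
  if (inherits(couplings, "fret_coupling")) couplings <- list(couplings)
  na <- length(geometry$acceptor_positions)
  if (length(couplings) != na)
    stop("need one fret_coupling per acceptor position")
  donor_reg <- positions + geometry$donor_position
  k <- vapply(seq_len(na), function(i) {
    L <- register_to_distance(donor_reg, geometry$acceptor_positions[i],
                              geometry)
    foerster_rate_ratio(L, couplings[[i]])
  }, numeric(length(positions)))
  k <- matrix(k, ncol = na)
  k / (1 + rowSums(k))
}

add_channel_noise <- function(intensities, noise_sd) {
  if (noise_sd <= 0) return(intensities)
  intensities + matrix(rnorm(length(intensities), sd = noise_sd),
                       nrow = nrow(intensities))
}

mean_e_to_trace <- function(mean_e, config, molecule_id, noise, metadata) {
  total <- config$total_intensity
  acc <- total * mean_e
  don <- total * (1 - rowSums(mean_e))
  intens <- cbind(don, acc)
  colnames(intens) <- c("donor",
                        if (ncol(mean_e) == 1) "acceptor1"
                        else paste0("acceptor", seq_len(ncol(mean_e))))
  if (noise) intens <- add_channel_noise(intens, config$noise_sd)
  intensity_trace(as.list(as.data.frame(intens)),
                  frame_interval = config$frame_interval,
                  molecule_id = molecule_id, metadata = metadata)
}

#' Render a micro-step trajectory as a binned intensity trace
#'
#' Each camera frame averages the FRET efficiency over its micro-steps; the
#' photon budget is then split as `I_A = total * Ebar` and
#' `I_D = total * (1 - Ebar)` (noiseless channel sums are exactly
#' `total_intensity`), and Gaussian noise is added independently per channel.
#'
#' @param positions Micro-step positions from [simulate_trajectory()]
#'   (unthinned); length must be a multiple of the frame binning.
#' @param geometry A [filament_geometry()].
#' @param couplings A [fret_coupling()] (or list of them, one per acceptor).
#' @param config A [slide_sim_config()].
#' @param noise Add Gaussian channel noise? (default TRUE)
#' @param molecule_id Label.
#' @param seed Optional seed for the noise draw.
#' @return An [intensity_trace()].
#' @export
render_intensities <- function(positions, geometry, couplings, config,
                               noise = TRUE, molecule_id = "mol1",
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  spf <- max(steps_per_frame(config, geometry), 1L)
  nf <- length(positions) / spf
  if (nf != floor(nf))
    stop("length(positions) is not a whole number of frames")
  e <- position_efficiencies(positions, geometry, couplings)
  mean_e <- apply(e, 2, function(col)
    colMeans(matrix(col, nrow = spf)))
  mean_e <- matrix(mean_e, ncol = ncol(e))
  mean_e_to_trace(mean_e, config, molecule_id, noise,
                  metadata = list(generator = "render_intensities"))
}

# Shared fused simulate+render path (compiled kernel on the register lattice).
simulate_rendered <- function(config, geometry, couplings, n_molecules,
                              noise, seed, generator) {
  if (inherits(couplings, "fret_coupling")) couplings <- list(couplings)
  if (!is.null(seed)) withr::local_seed(seed)
  dom <- walk_domain(geometry, config$min_overlap)
  n_sites <- as.integer(round(diff(dom) / config$step_size)) + 1L
  sites <- dom[1] + (seq_len(n_sites) - 1L) * config$step_size
  e_table <- position_efficiencies(sites, geometry, couplings)
  start <- geometry$acceptor_positions[1] - geometry$donor_position
  start_idx <- as.integer(round((min(max(start, dom[1]), dom[2]) - dom[1]) /
                                  config$step_size))
  spf <- steps_per_frame(config, geometry)
  seeds <- child_seeds(n_molecules)
  lapply(seq_len(n_molecules), function(i) {
    res <- .slide_frames_cpp(config$n_frames, spf, start_idx, e_table,
                             seeds[i])
    mean_e_to_trace(res$mean_e, config, molecule_id = paste0("mol", i),
                    noise = noise,
                    metadata = list(generator = generator,
                                    d_um2 = config$d_um2, d_bp2 = config$d_bp2,
                                    filament_length = geometry$filament_length,
                                    duplex_length = geometry$duplex_length,
                                    seed = seeds[i]))
  })
}

#' Simulate two-color sliding intensity traces
#'
#' End-to-end calibration simulator: free 1D diffusion along the filament
#' register (reflecting minimum-overlap boundaries), frame-averaged FRET, and
#' a 500 a.u. photon budget split between donor and acceptor channels with
#' additive Gaussian noise.
#'
#' @inheritParams render_intensities
#' @param n_molecules Number of independent molecules to simulate.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List of [intensity_trace()] objects (`donor`, `acceptor1`).
#' @export
simulate_slide <- function(config, geometry, couplings = fret_coupling(56),
                           n_molecules = 1, noise = TRUE,
                           seed = config$seed) {
  stopifnot(inherits(config, "slide_sim_config"),
            inherits(geometry, "filament_geometry"))
  if (length(geometry$acceptor_positions) != 1)
    stop("simulate_slide expects a single acceptor; see simulate_three_color")
  simulate_rendered(config, geometry, couplings, n_molecules, noise, seed,
                    generator = "simulate_slide")
}

#' Simulate three-color sliding intensity traces
#'
#' As [simulate_slide()], with two acceptors fixed on the filament (e.g. at
#' the junction and 33 nt away). Donor excitations are partitioned among the
#' donor and the two acceptors by the distance-dependent Foerster rate ratios;
#' acceptor-acceptor transfer is neglected (the experimental design places the
#' acceptors far apart). The two apparent efficiencies of a diffusing
#' trajectory are anticorrelated.
#'
#' @inheritParams simulate_slide
#' @param couplings List of two [fret_coupling()] objects (donor-acceptor1,
#'   donor-acceptor2); defaults to R0 = 56 and 38 Angstrom.
#' @return List of [intensity_trace()] objects (`donor`, `acceptor1`,
#'   `acceptor2`).
#' @export
simulate_three_color <- function(config, geometry,
                                 couplings = list(fret_coupling(56),
                                                  fret_coupling(38)),
                                 n_molecules = 1, noise = TRUE,
                                 seed = config$seed) {
  stopifnot(inherits(config, "slide_sim_config"),
            inherits(geometry, "filament_geometry"))
  if (length(geometry$acceptor_positions) != 2)
    stop("simulate_three_color needs exactly two acceptor positions")
  if (diff(geometry$acceptor_positions) == 0)
    stop("acceptor positions coincide")
  simulate_rendered(config, geometry, couplings, n_molecules, noise, seed,
                    generator = "simulate_three_color")
}
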