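#' Per-molecule intensity time trace
#'
#' The universal exchange object of the package: per-frame channel intensities
#' (donor plus one or two acceptors) in arbitrary camera units, with the frame
#' interval as metadata.
#'
#' @param channels Named list of equal-length numeric vectors, e.g.
#'   `list(donor = ..., acceptor1 = ..., acceptor2 = ...)`.
#' @param frame_interval Frame integration time in seconds (default 0.030).
#' @param molecule_id Label for the molecule.
#' @param metadata Free-form named list.
#' @return An `intensity_trace` object.
#' @export
intensity_trace <- function(channels, frame_interval = 0.030,
                            molecule_id = "mol1", metadata = list()) {
  stopifnot(frame_interval > 0, length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  n <- unique(lengths(channels))
  if (length(n) != 1) stop("all channels must have equal length")
  structure(list(channels = lapply(channels, as.numeric),
                 frame_interval = frame_interval,
                 molecule_id = as.character(molecule_id),
                 metadata = metadata),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s: %d frames @ %.3g s, channels: %s\n",
              x$molecule_id, n_frames(x), x$frame_interval,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Per-molecule FRET efficiency trace
#'
#' One or two per-frame apparent FRET efficiency series (donor to acceptor 1,
#' optionally donor to acceptor 2). Values are stored after the storage
#' clipping policy, see [clip_fret()].
#'
#' @param efficiencies Named list of equal-length numeric vectors, e.g.
#'   `list(e1 = ..., e2 = ...)`.
#' @inheritParams intensity_trace
#' @return A `fret_trace` object.
#' @export
fret_trace <- function(efficiencies, frame_interval = 0.030,
                       molecule_id = "mol1", metadata = list()) {
  stopifnot(frame_interval > 0, length(efficiencies) >= 1)
  n <- unique(lengths(efficiencies))
  if (length(n) != 1) stop("all efficiency series must have equal length")
  structure(list(efficiencies = lapply(efficiencies, as.numeric),
                 frame_interval = frame_interval,
                 molecule_id = as.character(molecule_id),
                 metadata = metadata),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %s: %d frames @ %.3g s, series: %s\n",
              x$molecule_id, length(x$efficiencies[[1]]), x$frame_interval,
              paste(names(x$efficiencies), collapse = ", ")))
  invisible(x)
}

#' Clip apparent FRET efficiencies
#'
#' Intensity noise pushes apparent efficiencies outside `[0, 1]`. The explicit
#' clipping policy keeps downstream histograms reproducible: `"storage"` clips
#' to `[-0.2, 1.2]` (retains noise excursions for kinetic analysis),
#' `"unit"` clips to `[0, 1]` (for histogramming).
#'
#' @param e Numeric vector of efficiencies.
#' @param policy `"storage"` or `"unit"`.
#' @return Clipped vector.
#' @export
clip_fret <- function(e, policy = c("storage", "unit")) {
  policy <- match.arg(policy)
  lim <- if (policy == "storage") c(-0.2, 1.2) else c(0, 1)
  pmin(pmax(e, lim[1]), lim[2])
}

n_frames <- function(trace) {
  if (inherits(trace, "intensity_trace")) length(trace$channels[[1]])
  else length(trace$efficiencies[[1]])
}
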