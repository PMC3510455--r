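#' Transition density plot from idealized traces
#'
#' 2D histogram over (FRET before, FRET after) of every idealized transition,
#' pooled over molecules. By default the axis coordinates are the fitted model
#' state means (so transitions cluster exactly at the state grid and the
#' diagonal is empty by construction); `axis = "segment"` instead uses the
#' measured mean of each dwell segment, which shows the empirical scatter.
#'
#' @param idealizations List of `idealization` objects (or one).
#' @param traces Required for `axis = "segment"`: the list of [fret_trace()]
#'   objects the idealizations came from (same order).
#' @param bins Number of histogram bins per axis over `[0, 1]` (default 50).
#' @param axis `"model"` or `"segment"`.
#' @return A `tdp`: list with `counts` (bins x bins matrix, rows = E before),
#'   `breaks` (bin edges), `n_transitions`, `axis`.
#' @export
build_tdp <- function(idealizations, traces = NULL, bins = 50,
                      axis = c("model", "segment")) {
  axis <- match.arg(axis)
  if (inherits(idealizations, "idealization"))
    idealizations <- list(idealizations)
  if (axis == "segment" && is.null(traces))
    stop("axis = 'segment' needs the original traces")
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- matrix(0L, bins, bins)
  n_trans <- 0L
  for (i in seq_along(idealizations)) {
    idl <- idealizations[[i]]
    seg <- idl$segments
    if (nrow(seg) < 2) next
    if (axis == "model") {
      e_seg <- idl$means[seg$state]
    } else {
      x <- trace_series(list(traces[[i]]))[[1]]
      e_seg <- vapply(seq_len(nrow(seg)), function(s)
        mean(x[seg$start[s]:(seg$start[s] + seg$length[s] - 1L)]),
        numeric(1))
    }
    before <- e_seg[-length(e_seg)]
    after <- e_seg[-1]
    bi <- findInterval(pmin(pmax(before, 0), 1), breaks,
                       rightmost.closed = TRUE, all.inside = TRUE)
    ai <- findInterval(pmin(pmax(after, 0), 1), breaks,
                       rightmost.closed = TRUE, all.inside = TRUE)
    for (s in seq_along(bi)) counts[bi[s], ai[s]] <- counts[bi[s], ai[s]] + 1L
    n_trans <- n_trans + length(bi)
  }
  if (n_trans == 0L) warning("no transitions: empty TDP")
  structure(list(counts = counts, breaks = breaks, n_transitions = n_trans,
                 axis = axis),
            class = "tdp")
}

#' @export
print.tdp <- function(x, ...) {
  cat(sprintf("<tdp> %d transitions, %d x %d bins (%s-mean axes)\n",
              x$n_transitions, nrow(x$counts), ncol(x$counts), x$axis))
  invisible(x)
}

#' Transition counts, rates and occupancies from idealizations
#'
#' Counts `N(i -> j)` over all traces and converts them to per-second rates by
#' the exponential-exit estimator `k(i -> j) = N(i -> j) / time in state i`.
#' States never visited get `NA` rates (absent, not zero).
#'
#' @param idealizations List of `idealization` objects (or one), all from the
#'   same fitted model.
#' @param frame_interval Frame time, s; defaults to the idealizations' own.
#' @param state_names Optional labels, ascending by state mean (e.g.
#'   `c("NH", "HS2", "HS1")`).
#' @return A `transition_stats`: list with `counts` (K x K), `rates` (K x K,
#'   per second), `occupancy_time` (s in each state), `n_traces`.
#' @export
transition_stats <- function(idealizations, frame_interval = NULL,
                             state_names = NULL) {
  if (inherits(idealizations, "idealization"))
    idealizations <- list(idealizations)
  if (length(idealizations) == 0) stop("no idealizations supplied")
  k <- length(idealizations[[1]]$means)
  if (is.null(frame_interval))
    frame_interval <- idealizations[[1]]$frame_interval
  if (is.null(state_names)) state_names <- paste0("S", seq_len(k))
  stopifnot(length(state_names) == k)
  counts <- matrix(0L, k, k, dimnames = list(state_names, state_names))
  frames_in <- setNames(numeric(k), state_names)
  for (idl in idealizations) {
    seg <- idl$segments
    frames_in <- frames_in + vapply(seq_len(k), function(s)
      sum(seg$length[seg$state == s]), numeric(1))
    if (nrow(seg) >= 2) {
      from <- seg$state[-nrow(seg)]
      to <- seg$state[-1]
      for (s in seq_along(from))
        counts[from[s], to[s]] <- counts[from[s], to[s]] + 1L
    }
  }
  occ <- frames_in * frame_interval
  rates <- sweep(counts, 1, occ, "/")
  rates[occ == 0, ] <- NA_real_
  diag(rates) <- NA_real_
  structure(list(counts = counts, rates = rates, occupancy_time = occ,
                 n_traces = length(idealizations)),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("<transition_stats> %d traces, %d transitions\n",
              x$n_traces, sum(x$counts)))
  cat("rates (/s):\n")
  print(signif(x$rates, 3))
  invisible(x)
}

#' Homology-recognition efficiency
#'
#' Fraction of exits from the non-homologous sliding state that pair first at
#' the nearer homology site:
#' `N(NH -> HS2) / (N(NH -> HS2) + N(NH -> HS1))`. Invariant under scaling all
#' counts by a constant.
#'
#' @param stats A `transition_stats` whose state names include the three
#'   states, or a plain named counts matrix.
#' @param from,near,far State labels (defaults `"NH"`, `"HS2"`, `"HS1"`).
#' @return Recognition efficiency in `[0, 1]`.
#' @export
recognition_efficiency <- function(stats, from = "NH", near = "HS2",
                                   far = "HS1") {
  counts <- if (inherits(stats, "transition_stats")) stats$counts else stats
  if (!all(c(from, near, far) %in% rownames(counts)))
    stop("counts matrix must carry the state names ",
         paste(c(from, near, far), collapse = ", "))
  n_near <- counts[from, near]
  n_far <- counts[from, far]
  if (n_near + n_far == 0) stop("no exits from ", from, " observed")
  n_near / (n_near + n_far)
}
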