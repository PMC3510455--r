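#' Build a cross-correlation calibration table by simulation
#'
#' For every (diffusion coefficient, filament length) cell, simulates
#' `n_reps` molecules with [simulate_slide()], averages their donor/acceptor
#' cross-correlations and fits a single exponential to obtain the mean
#' cross-correlation time tau for that cell (the averaged-CC fit mirrors how
#' measured curves are analyzed). The cell standard error is obtained by
#' refitting three molecule-subgroup averages. The resulting surface is
#' checked to be monotone: tau decreasing in D within each length, increasing
#' in length within each D.
#'
#' @param d_grid Diffusion coefficients, um^2/s (sorted internally); the
#'   classic grid spans two decades, `c(0.09, 0.9, 9) * 1e-3`.
#' @param lengths Filament lengths in nt, e.g. `c(21, 39, 69, 99)`.
#' @param config A [slide_sim_config()] supplying step size, frames, photon
#'   budget and noise; its `d_um2` is overridden cell by cell.
#' @param duplex_length Duplex length in bp (default 39).
#' @param coupling Donor-acceptor [fret_coupling()].
#' @param n_reps Molecules per cell (default 30).
#' @param max_lag Lag window for the CC fit, seconds (default 2).
#' @param seed Optional root seed.
#' @return A `calibration_table`: list with `table` (data frame `d_um2`,
#'   `length`, `tau`, `se`, `n_reps`), `d_grid`, `lengths`, and the config
#'   snapshot.
#' @export
build_calibration_table <- function(d_grid, lengths,
                                    config = slide_sim_config(),
                                    duplex_length = 39,
                                    coupling = fret_coupling(56),
                                    n_reps = 30, max_lag = 2, seed = NULL) {
  stopifnot(length(d_grid) >= 2, all(d_grid > 0), length(lengths) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  d_grid <- sort(d_grid)
  lengths <- sort(lengths)
  cells <- expand.grid(d_um2 = d_grid, length = lengths)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$d_um2[i]; L <- cells$length[i]
    cfg <- config; cfg$d_um2 <- d; cfg$d_bp2 <- NULL
    geom <- filament_geometry(L, duplex_length)
    traces <- simulate_slide(cfg, geom, coupling, n_molecules = n_reps,
                             seed = NULL)
    tau_cell <- cell_tau(traces, max_lag)
    data.frame(d_um2 = d, length = L, tau = tau_cell$tau, se = tau_cell$se,
               n_reps = n_reps)
  })
  tab <- do.call(rbind, rows)
  bad <- !is.finite(tab$tau)
  if (any(bad)) {
    # cells whose relaxation is far below the frame time have no resolvable
    # CC decay; they are reported and dropped rather than extrapolated
    warning("cross-correlation fit failed; dropping cell(s): ",
            paste(sprintf("(D=%g, L=%g)", tab$d_um2[bad], tab$length[bad]),
                  collapse = ", "))
    tab <- tab[!bad, ]
  }
  if (nrow(tab) == 0) stop("all calibration cells failed")
  out <- structure(list(table = tab, d_grid = d_grid, lengths = lengths,
                        config = config, duplex_length = duplex_length,
                        max_lag = max_lag),
                   class = "calibration_table")
  check_monotone(out)
  out
}

# Fit tau for one cell: exponential fit of the molecule-averaged CC; SE from
# refitting three molecule-subgroup averages.
cell_tau <- function(traces, max_lag) {
  ccs <- lapply(traces, function(tr)
    cross_correlate(tr$channels$donor, tr$channels$acceptor1,
                    max_lag = max_lag, frame_interval = tr$frame_interval))
  tau <- tryCatch(fit_cc_exponential(average_cc(ccs))$tau,
                  error = function(e) NA_real_)
  groups <- split(ccs, rep_len(1:3, length(ccs)))
  sub <- vapply(groups, function(g)
    tryCatch(fit_cc_exponential(average_cc(g))$tau,
             error = function(e) NA_real_), numeric(1))
  list(tau = tau, se = sd(sub, na.rm = TRUE) / sqrt(sum(is.finite(sub))))
}

check_monotone <- function(table) {
  tab <- table$table
  for (L in table$lengths) {
    tt <- tab$tau[tab$length == L][order(tab$d_um2[tab$length == L])]
    if (any(diff(tt) >= 0))
      warning("tau not strictly decreasing in D at length ", L)
  }
  for (d in table$d_grid) {
    tt <- tab$tau[tab$d_um2 == d][order(tab$length[tab$d_um2 == d])]
    if (any(diff(tt) <= 0))
      warning("tau not strictly increasing in length at D = ", d)
  }
  invisible(table)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d D x %d lengths, %d molecules/cell\n",
              length(x$d_grid), length(x$lengths), x$table$n_reps[1]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Estimate the sliding diffusion coefficient from observed CC times
#'
#' Matches observed cross-correlation times against the simulated surface
#' tau(L; D) by least squares in log tau, with log-linear interpolation in
#' log D between grid points (tau is approximately inversely proportional to
#' D, which log-log space linearizes). All supplied lengths are fitted
#' jointly. An observed time well outside the simulated tau range for its
#' length is dropped from the fit with a warning rather than extrapolated;
#' if every observation is out of range the estimate is refused.
#'
#' @param observed Data frame with columns `length` (nt) and `tau` (s); the
#'   lengths must be a subset of `table$lengths`.
#' @param table A `calibration_table` from [build_calibration_table()].
#' @param tolerance Observed times up to this factor outside the simulated tau
#'   range for their length are still accepted (the prediction is clamped to
#'   the grid edge, never extrapolated beyond it); farther out, the estimate
#'   is refused. Default 2, covering the sampling noise of edge cells.
#' @return List with `d_hat` (um^2/s), `d_hat_bp2` (B-form bp^2/s, rise
#'   0.34 nm), `bracket` (the grid interval containing the estimate) and
#'   `sse_log` (residual sum of squares in log tau).
#' @export
estimate_D <- function(observed, table, tolerance = 2) {
  stopifnot(inherits(table, "calibration_table"),
            all(c("length", "tau") %in% names(observed)))
  if (!all(observed$length %in% table$lengths))
    stop("observed lengths must be a subset of the table lengths")
  tab <- table$table
  logd_grid <- log(table$d_grid)
  # per length: available (log D, log tau) support points (cells whose CC
  # decay was unresolvable may have been dropped from the table)
  support <- lapply(observed$length, function(L) {
    sub <- tab[tab$length == L, ]
    sub <- sub[order(sub$d_um2), ]
    if (nrow(sub) < 2)
      stop("fewer than 2 calibration cells available for length ", L)
    list(ld = log(sub$d_um2), lt = log(sub$tau))
  })
  in_range <- vapply(seq_len(nrow(observed)), function(j) {
    rng <- range(exp(support[[j]]$lt))
    observed$tau[j] >= rng[1] / tolerance &&
      observed$tau[j] <= rng[2] * tolerance
  }, logical(1))
  if (!any(in_range))
    stop("all observed tau lie outside the simulated range; ",
         "extrapolation refused")
  if (any(!in_range)) {
    warning("dropping observed tau outside the simulated range for ",
            "length(s) ", paste(observed$length[!in_range], collapse = ", "))
    observed <- observed[in_range, , drop = FALSE]
    support <- support[in_range]
  }
  obs_log <- log(observed$tau)
  sse <- function(ld) {
    pred <- vapply(support, function(s)
      stats::approx(s$ld, s$lt, xout = ld, rule = 2)$y, numeric(1))
    sum((pred - obs_log)^2)
  }
  # candidates: every grid point plus the interior optimum of each bracket
  cand <- data.frame(ld = logd_grid, sse = vapply(logd_grid, sse, numeric(1)))
  for (i in seq_len(length(logd_grid) - 1)) {
    o <- optimize(sse, lower = logd_grid[i], upper = logd_grid[i + 1],
                  tol = 1e-10)
    cand <- rbind(cand, data.frame(ld = o$minimum, sse = o$objective))
  }
  best <- cand[which.min(cand$sse), ]
  d_hat <- exp(best$ld)
  i_lo <- max(which(logd_grid <= best$ld + 1e-12))
  i_hi <- min(which(logd_grid >= best$ld - 1e-12))
  list(d_hat = d_hat,
       d_hat_bp2 = diffusion_um2_to_bp2(d_hat),
       bracket = c(table$d_grid[i_lo], table$d_grid[i_hi]),
       sse_log = best$sse)
}
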