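#' 1D sliding length per binding event
#'
#' Root-mean-square distance scanned by 1D diffusion during an encounter of
#' duration `t`: `sqrt(D * t)`. With D = 7700 bp^2/s and encounter lifetimes
#' of 0.5-10 s this spans roughly 60-300 bp. (The sqrt(D t) convention, rather
#' than sqrt(2 D t), is the one that reproduces that reported range; see
#' the methods vignette.)
#'
#' @param d_bp2 Diffusion coefficient, bp^2/s (`>= 0`).
#' @param t Encounter duration, s (`>= 0`). Vectorized over both arguments.
#' @return Sliding length in bp; scales as `sqrt(t)`.
#' @export
sliding_length <- function(d_bp2, t) {
  stopifnot(all(d_bp2 >= 0), all(t >= 0))
  sqrt(d_bp2 * t)
}

#' Facilitated-search rate enhancement from sliding
#'
#' Ratio of the target-association rate with sliding to the rate without
#' sliding (D = 0, non-specific binding only), for a filament that scans `s`
#' sites to either side per binding event and recognizes the target with
#' probability `p_bind` per non-specific encounter:
#'
#' \deqn{k_a^{slide}/k_a^{D=0} = \frac{1 + 2s}{1 + 2s(1 - p)/(1 + 2 s^2 p)}}
#'
#' Limits: 1 at `s = 0` (no sliding, no enhancement) and `1 + 2s` at
#' `p_bind = 1` (perfect recognition scans `2s + 1` sites per encounter);
#' always `>= 1` and monotone non-decreasing in both arguments.
#'
#' @param s Sliding distance in bp (sites scanned to one side), `>= 0`.
#' @param p_bind Recognition probability per encounter, in `(0, 1]`.
#' @return Fold enhancement (`>= 1`). Vectorized.
#' @export
rate_enhancement <- function(s, p_bind) {
  stopifnot(all(s >= 0))
  if (any(p_bind <= 0) || any(p_bind > 1))
    stop("p_bind must lie in (0, 1]")
  (1 + 2 * s) / (1 + 2 * s * (1 - p_bind) / (1 + 2 * s^2 * p_bind))
}
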