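#' Filament/duplex geometry for sliding simulations
#'
#' Describes the RecA nucleoprotein filament and the double-stranded DNA that
#' slides along it, in stretched "register" coordinates: one register unit is
#' one nucleotide of the RecA-bound single strand, with an axial rise of
#' 5.1 Angstrom per nucleotide (B-form 3.4 Angstrom stretched 1.5-fold by the
#' filament). Register 0 is the ssDNA/dsDNA junction of the immobilized
#' construct; positive registers run toward the free filament end.
#'
#' @param filament_length Filament length in nucleotides (the ssDNA the
#'   filament is assembled on).
#' @param duplex_length Length of the incoming double-stranded DNA in base
#'   pairs. One base pair spans one register unit while bound to the filament.
#' @param rise_per_nt Axial rise per register unit, Angstrom (default 5.1).
#' @param acceptor_positions Register coordinates (nt from the junction) of the
#'   acceptor dye(s) fixed on the filament. One value for two-color
#'   experiments, two for three-color.
#' @param donor_position Offset (bp) of the donor within the duplex, measured
#'   from the tracked duplex end; 0 means the donor sits at that end.
#' @param lateral_offset Perpendicular donor-acceptor offset r in Angstrom:
#'   the closest approach when donor and acceptor share a register. Default 20,
#'   motivated by the filament radius plus dye linkers.
#' @return A `filament_geometry` object.
#' @export
filament_geometry <- function(filament_length, duplex_length,
                              rise_per_nt = 5.1, acceptor_positions = 0,
                              donor_position = 0, lateral_offset = 20) {
  stopifnot(filament_length > 0, duplex_length > 0, rise_per_nt > 0,
            lateral_offset >= 0, donor_position >= 0)
  if (any(acceptor_positions < 0 | acceptor_positions > filament_length))
    stop("acceptor positions must lie within [0, filament_length]")
  structure(list(filament_length = filament_length,
                 duplex_length = duplex_length,
                 rise_per_nt = rise_per_nt,
                 acceptor_positions = as.numeric(acceptor_positions),
                 donor_position = donor_position,
                 lateral_offset = lateral_offset),
            class = "filament_geometry")
}

#' Foerster coupling between a donor-acceptor pair
#'
#' @param forster_radius Foerster radius R0 in Angstrom (distance of 50%
#'   transfer efficiency). Defaults: 56 for a Cy3/Cy5-like pair; use ~38 for a
#'   far-red Cy3/Cy7-like pair.
#' @return A `fret_coupling` object.
#' @export
fret_coupling <- function(forster_radius = 56) {
  stopifnot(forster_radius > 0)
  structure(list(forster_radius = forster_radius), class = "fret_coupling")
}

#' Donor-acceptor distance from register coordinates
#'
#' The dyes are separated axially by `|x - x0|` register units (rise `d` each)
#' and laterally by the fixed offset `r`, so the 3D separation is
#' `sqrt(r^2 + (d * |x - x0|)^2)`.
#'
#' @param x,x0 Register coordinates (nt) of the two dyes. Symmetric in its
#'   two arguments; either may be a vector.
#' @param geometry A [filament_geometry()].
#' @return Distance(s) in Angstrom, always `>= geometry$lateral_offset`.
#' @export
register_to_distance <- function(x, x0, geometry) {
  stopifnot(inherits(geometry, "filament_geometry"))
  sqrt(geometry$lateral_offset^2 + (geometry$rise_per_nt * abs(x - x0))^2)
}

#' FRET efficiency at a given distance
#'
#' Standard Foerster relation `E = 1 / (1 + (L/R0)^6)`.
#'
#' @param distance Donor-acceptor distance(s), Angstrom, `>= 0`.
#' @param coupling A [fret_coupling()].
#' @return Efficiency in (0, 1]; strictly decreasing in distance.
#' @export
fret_from_distance <- function(distance, coupling) {
  stopifnot(inherits(coupling, "fret_coupling"))
  if (any(distance < 0)) stop("negative distance: invalid geometry")
  1 / (1 + (distance / coupling$forster_radius)^6)
}

# Foerster "rate" ratio k = (R0/L)^6; used to partition donor excitations
# among several acceptors: E_i = k_i / (1 + sum_j k_j).
foerster_rate_ratio <- function(distance, coupling) {
  (coupling$forster_radius / pmax(distance, .Machine$double.eps))^6
}

#' Convert a diffusion coefficient between um^2/s and bp^2/s
#'
#' `diffusion_um2_to_bp2()` returns `D * 1e6 / rise_nm^2`; with the B-form
#' rise of 0.34 nm/bp this is the conversion that turns 0.9e-3 um^2/s into
#' ~7785 bp^2/s. Using the stretched filament register rise (0.51 nm) instead
#' yields the register-lattice diffusion coefficient used internally by the
#' simulator; the choice of rise is a convention the caller controls.
#'
#' @param d_um2 Diffusion coefficient in um^2/s (`>= 0`).
#' @param d_bp2 Diffusion coefficient in bp^2/s (`>= 0`).
#' @param rise_nm Rise per base pair in nm (`> 0`), default 0.34.
#' @return The converted diffusion coefficient.
#' @export
diffusion_um2_to_bp2 <- function(d_um2, rise_nm = 0.34) {
  stopifnot(all(d_um2 >= 0), rise_nm > 0)
  d_um2 * 1e6 / rise_nm^2
}

#' @rdname diffusion_um2_to_bp2
#' @export
diffusion_bp2_to_um2 <- function(d_bp2, rise_nm = 0.34) {
  stopifnot(all(d_bp2 >= 0), rise_nm > 0)
  d_bp2 * rise_nm^2 / 1e6
}

#' Axial span of a stretch of nucleotides in a stretched filament
#'
#' `n * b_rise * stretch`: n nucleotides at the B-form rise, extended by the
#' filament stretching factor. With the defaults, one nucleotide spans
#' 3.4 x 1.5 = 5.1 Angstrom, the filament register rise.
#'
#' @param n Number of nucleotides (`>= 0`).
#' @param b_rise B-form rise per nucleotide, Angstrom (default 3.4).
#' @param stretch Filament extension factor (default 1.5).
#' @return Span in Angstrom.
#' @export
stretched_span <- function(n, b_rise = 3.4, stretch = 1.5) {
  stopifnot(all(n >= 0))
  n * b_rise * stretch
}
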