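#' Dihedral time series
#'
#' Container for a per-frame, per-residue (phi, psi) ensemble, the
#' substrate of all analytics in the package. Angles live on the periodic
#' domain (-180, 180] in degrees. Terminal residues of a finite chain have
#' one undefined angle; such entries are `NA` and are excluded from
#' analytics rather than imputed.
#'
#' @param phi,psi Numeric matrices, frames x residues, in degrees.
#' @param residue_numbers Optional integer residue labels (default 1..n).
#' @param temperature Temperature in kelvin associated with the series.
#' @param source Free-text provenance tag.
#' @param strict Logical; reject (rather than wrap) angles outside
#'   (-180, 180].
#' @return Object of class `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, residue_numbers = NULL,
                            temperature = NA_real_, source = "",
                            strict = TRUE) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  if (!all(dim(phi) == dim(psi)))
    stop("phi and psi must have identical dimensions")
  if (nrow(phi) < 1) stop("a dihedral series needs at least one frame")
  out <- function(x) any(!is.na(x) & (x <= -180 | x > 180))
  if (out(phi) || out(psi)) {
    if (strict) stop("angles outside (-180, 180]; wrap first or use strict = FALSE")
    warning("wrapping angles outside (-180, 180]")
    phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  }
  if (is.null(residue_numbers)) residue_numbers <- seq_len(ncol(phi))
  stopifnot(length(residue_numbers) == ncol(phi))
  structure(list(phi = phi, psi = psi,
                 residue_numbers = as.integer(residue_numbers),
                 temperature = temperature, source = source),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("Dihedral series: %d frames x %d residues%s%s\n",
              nrow(x$phi), ncol(x$phi),
              if (is.finite(x$temperature))
                sprintf(" at %.1f K", x$temperature) else "",
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' @export
dim.dihedral_series <- function(x) dim(x$phi)

#' Number of frames in a dihedral series
#' @param series A [dihedral_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) nrow(series$phi)

#' Subset the frames of a dihedral series
#'
#' @param series A [dihedral_series()].
#' @param frames Integer or logical index over frames.
#' @return A [dihedral_series()] with the selected frames.
#' @export
subset_frames <- function(series, frames) {
  dihedral_series(series$phi[frames, , drop = FALSE],
                  series$psi[frames, , drop = FALSE],
                  residue_numbers = series$residue_numbers,
                  temperature = series$temperature, source = series$source)
}

#' @export
as.data.frame.dihedral_series <- function(x, ...) {
  nf <- nrow(x$phi); nr <- ncol(x$phi)
  data.frame(frame = rep(seq_len(nf), times = nr),
             residue = rep(x$residue_numbers, each = nf),
             phi = as.vector(x$phi),
             psi = as.vector(x$psi))
}
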