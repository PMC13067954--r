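#' Write a dihedral series to CSV
#'
#' Long-format CSV with columns `frame`, `residue`, `phi`, `psi` and
#' optionally `energy`; angles in degrees, full precision.
#'
#' @param series A [dihedral_series()].
#' @param path Output file path.
#' @param energy Optional per-frame energy vector written alongside.
#' @return Invisibly, `path`.
#' @export
write_dihedral_csv <- function(series, path, energy = NULL) {
  stopifnot(inherits(series, "dihedral_series"))
  d <- as.data.frame(series)
  if (!is.null(energy)) {
    stopifnot(length(energy) == nrow(series$phi))
    d$energy <- rep(energy, times = ncol(series$phi))
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dihedral series from CSV
#'
#' Expects the format of [write_dihedral_csv()]: columns `frame`,
#' `residue`, `phi`, `psi` (extra columns ignored). In strict mode angles
#' outside (-180, 180] are rejected; in lenient mode they are wrapped
#' with a warning. Malformed rows are reported with their line number.
#'
#' @param path CSV file path.
#' @param strict Logical; reject out-of-domain angles instead of
#'   wrapping.
#' @param temperature,source Metadata attached to the returned series.
#' @return A [dihedral_series()].
#' @export
read_dihedral_csv <- function(path, strict = TRUE,
                              temperature = NA_real_, source = path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty dihedral file: ", path)
  need <- c("frame", "residue", "phi", "psi")
  if (!all(need %in% names(d)))
    stop("dihedral CSV must have columns frame, residue, phi, psi")
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, bad[1] + 1L, path))
    d[[col]] <- v
  }
  frames <- sort(unique(d$frame))
  residues <- sort(unique(d$residue))
  phi <- psi <- matrix(NA_real_, length(frames), length(residues))
  i <- match(d$frame, frames)
  j <- match(d$residue, residues)
  phi[cbind(i, j)] <- d$phi
  psi[cbind(i, j)] <- d$psi
  dihedral_series(phi, psi, residue_numbers = residues,
                  temperature = temperature, source = source,
                  strict = strict)
}

aa1to3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Write backbone conformations as a (multi-model) PDB file
#'
#' Emits ATOM records for the N/CA/C backbone atoms of one or more
#' conformations, framed by MODEL/ENDMDL records when more than one model
#' is written. Only this minimal dialect is produced — the idealised
#' backbones built by this package have no side chains to write.
#'
#' @param x A `backbone_conformation` or a list of them (all sharing one
#'   sequence).
#' @param path Output file path.
#' @param first_residue_number Residue numbering offset.
#' @return Invisibly, `path`.
#' @export
write_pdb_models <- function(x, path, first_residue_number = 1L) {
  if (inherits(x, "backbone_conformation")) x <- list(x)
  stopifnot(length(x) >= 1,
            all(vapply(x, inherits, logical(1), "backbone_conformation")))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    conf <- x[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    aa <- residue_letters(conf$sequence)
    serial <- 0L
    lines <- character(0)
    for (i in seq_along(aa)) {
      for (atom in c("N", "CA", "C")) {
        serial <- serial + 1L
        p <- conf$coords[i, atom, ]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atom, aa1to3[[aa[i]]],
          first_residue_number + i - 1L, p[1], p[2], p[3], 1, 0,
          substr(atom, 1, 1)))
      }
    }
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  invisible(path)
}

#' Read a multi-model backbone PDB file
#'
#' Reads MODEL/ENDMDL-framed ATOM records and assembles, per model, the
#' N/CA/C coordinates of every residue by atom-name lookup (so atom order
#' within a residue is irrelevant). A residue missing one of its backbone
#' atoms keeps `NA` coordinates for that atom — it is flagged, never
#' fabricated.
#'
#' @param path PDB file path.
#' @return Object of class `backbone_trajectory`: list with `coords`
#'   (array frames x residues x 3 atoms x 3 xyz), `residue_numbers` and
#'   `sequence` (one-letter, `X` for unknown residue names).
#' @export
read_multimodel_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$elety %in% c("N", "CA", "C")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  residues <- sort(unique(at$resno[keep]))
  nf <- nrow(xyz)
  nr <- length(residues)
  coords <- array(NA_real_, c(nf, nr, 3, 3),
                  dimnames = list(NULL, NULL, c("N", "CA", "C"),
                                  c("x", "y", "z")))
  seq1 <- rep("X", nr)
  rev3 <- stats::setNames(names(aa1to3), aa1to3)
  for (a in which(keep)) {
    j <- match(at$resno[a], residues)
    k <- match(at$elety[a], c("N", "CA", "C"))
    cols <- (3 * (a - 1) + 1):(3 * a)
    coords[, j, k, ] <- xyz[, cols, drop = FALSE]
    if (at$resid[a] %in% names(rev3)) seq1[j] <- rev3[[at$resid[a]]]
  }
  structure(list(coords = coords, residue_numbers = residues,
                 sequence = paste(seq1, collapse = "")),
            class = "backbone_trajectory")
}

#' Backbone dihedrals of a coordinate trajectory
#'
#' Computes phi = C(i-1)-N(i)-CA(i)-C(i) and psi =
#' N(i)-CA(i)-C(i)-N(i+1) for every frame of a coordinate trajectory.
#' Terminal angles, and any angle whose defining atoms are missing, are
#' `NA`.
#'
#' @param traj A `backbone_trajectory` from [read_multimodel_pdb()].
#' @param temperature,source Metadata for the returned series.
#' @return A [dihedral_series()].
#' @export
dihedrals_from_coordinates <- function(traj, temperature = NA_real_,
                                       source = "") {
  stopifnot(inherits(traj, "backbone_trajectory"))
  nf <- dim(traj$coords)[1]
  nr <- dim(traj$coords)[2]
  phi <- psi <- matrix(NA_real_, nf, nr)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , , drop = TRUE]
    dim(xyz) <- c(nr, 3, 3)
    dimnames(xyz) <- list(NULL, c("N", "CA", "C"), c("x", "y", "z"))
    d <- backbone_dihedrals(xyz)
    phi[f, ] <- d$phi
    psi[f, ] <- d$psi
  }
  dihedral_series(phi, psi, residue_numbers = traj$residue_numbers,
                  temperature = temperature, source = source)
}

#' Write a free-energy surface as gridded text
#'
#' Long-format CSV with bin centers and values, readable back by any
#' table reader.
#'
#' @param fes A `free_energy_surface` with bin edges.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_surface_csv <- function(fes, path) {
  stopifnot(inherits(fes, "free_energy_surface"), !is.null(fes$phi_edges))
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  pm <- mids(fes$phi_edges); sm <- mids(fes$psi_edges)
  d <- data.frame(phi = rep(pm, times = length(sm)),
                  psi = rep(sm, each = length(pm)),
                  probability = as.vector(fes$prob),
                  delta_g = as.vector(fes$delta_g))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
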