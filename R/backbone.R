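#' Idealized peptide backbone geometry
#'
#' Bond lengths and angles used for all forward kinematics. The backbone is
#' modeled with three atoms per residue (N, CA, C); side chains, hydrogens
#' and the carbonyl oxygen are outside the degrees of freedom. Defaults are
#' standard idealized peptide values; any fixed, self-consistent set works,
#' which is why they are exposed here rather than hard-coded.
#'
#' @param b_n_ca,b_ca_c,b_c_n Bond lengths N-CA, CA-C, C-N in Angstrom.
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca Bond angles in degrees.
#' @param omega Peptide-bond torsion in degrees, held fixed (trans = 180).
#' @return An object of class `ideal_geometry`.
#' @export
ideal_geometry <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                           a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                           a_c_n_ca = 121.7, omega = 180) {
  lens <- c(b_n_ca, b_ca_c, b_c_n)
  angs <- c(a_n_ca_c, a_ca_c_n, a_c_n_ca)
  if (any(!is.finite(lens)) || any(lens <= 0)) stop("bond lengths must be > 0")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    stop("bond angles must lie in (0, 180)")
  }
  structure(list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
                 a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n,
                 a_c_n_ca = a_c_n_ca, omega = wrap_angle(omega)),
            class = "ideal_geometry")
}

#' A backbone conformation
#'
#' Bundles a residue sequence, the phi/psi dihedral vector (degrees,
#' `NA` for the undefined phi of residue 1 and psi of the last residue),
#' Cartesian N/CA/C coordinates (Angstrom, one row per atom in chain
#' order N1, CA1, C1, N2, ...), and an optional cached energy.
#'
#' @param sequence Character: either a single string of one-letter residue
#'   codes or a character vector with one code per residue.
#' @param phi,psi Numeric vectors of backbone dihedrals in degrees, one per
#'   residue; `phi[1]` and `psi[n]` must be `NA`.
#' @param xyz Numeric matrix (3 * n residues) x 3, or `NULL`.
#' @param energy Optional cached scalar energy.
#' @param geometry The `ideal_geometry` the coordinates were built under.
#' @return Object of class `conformation`.
#' @export
conformation <- function(sequence, phi, psi, xyz = NULL, energy = NULL,
                         geometry = ideal_geometry()) {
  if (length(sequence) == 1L && nchar(sequence[1L]) != 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  n <- length(sequence)
  if (n < 1L) stop("empty sequence")
  if (length(phi) != n || length(psi) != n) {
    stop("phi/psi length must equal residue count (", n, ")")
  }
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  if (!is.na(phi[1L])) stop("phi of residue 1 is undefined; use NA")
  if (!is.na(psi[n])) stop("psi of the last residue is undefined; use NA")
  if (n > 1L && (anyNA(phi[-1L]) || anyNA(psi[-n]))) {
    stop("interior dihedrals must be defined")
  }
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != 3L * n || ncol(xyz) != 3L) {
      stop("xyz must be (3 * residues) x 3")
    }
    dimnames(xyz) <- list(atom_labels(n), c("x", "y", "z"))
  }
  structure(list(sequence = sequence, phi = phi, psi = psi, xyz = xyz,
                 energy = energy, geometry = geometry),
            class = "conformation")
}

atom_labels <- function(n) paste0(rep(c("N", "CA", "C"), n),
                                  rep(seq_len(n), each = 3L))

#' Number of residues in a conformation
#' @param conf A `conformation`.
#' @export
n_residues <- function(conf) length(conf$sequence)

#' Number of defined dihedral angles (the planner's n)
#' @param conf A `conformation`.
#' @export
n_dihedrals <- function(conf) sum(!is.na(conf$phi)) + sum(!is.na(conf$psi))

# flat atom index of atom k (1=N, 2=CA, 3=C) of residue i
a_idx <- function(i, k) 3L * (i - 1L) + k

#' CA coordinates of a conformation
#' @param conf A `conformation` with coordinates.
#' @return n x 3 matrix of CA positions.
#' @export
ca_coords <- function(conf) {
  if (is.null(conf$xyz)) stop("conformation has no coordinates")
  conf$xyz[a_idx(seq_len(n_residues(conf)), 2L), , drop = FALSE]
}

#' Defined dihedrals as a flat vector in fixed residue order
#'
#' Order is phi then psi within each residue, skipping the undefined
#' terminal angles; this is the ordering the planner's projection uses.
#' @param conf A `conformation`.
#' @export
flat_dihedrals <- function(conf) {
  v <- as.vector(rbind(conf$phi, conf$psi))
  v[!is.na(v)]
}

#' Mean wrapped absolute dihedral distance between two conformations
#' @param a,b Conformations with identical residue counts.
#' @return Mean of |wrapped difference| over defined angles, degrees.
#' @export
dihedral_distance <- function(a, b) {
  da <- flat_dihedrals(a); db <- flat_dihedrals(b)
  if (length(da) != length(db)) stop("dihedral counts differ")
  mean(abs(angle_diff(da, db)))
}

# NeRF placement: position atom d bonded to c, with bond length L,
# bond angle theta = angle(b, c, d) and torsion chi = torsion(a, b, c, d).
place_atom <- function(a, b, c, L, theta, chi) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- deg2rad(theta); ch <- deg2rad(chi)
  d2 <- c(-L * cos(th), L * sin(th) * cos(ch), L * sin(th) * sin(ch))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build backbone coordinates from dihedrals (forward kinematics)
#'
#' Places N, CA, C sequentially: each atom is positioned from the previous
#' three via its ideal bond length, bond angle and the governing torsion
#' (psi places the next N, the fixed omega places the next CA, phi places
#' that residue's C). Residue 1 starts at a canonical pose with N at the
#' origin.
#'
#' @inheritParams conformation
#' @param geometry An [ideal_geometry()].
#' @return A `conformation` with coordinates.
#' @examples
#' conf <- build_backbone("AAA", phi = c(NA, 180, 180), psi = c(180, 180, NA))
#' dist(ca_coords(conf))  # consecutive CA-CA close to 3.8 A
#' @export
build_backbone <- function(sequence, phi, psi, geometry = ideal_geometry()) {
  conf <- conformation(sequence, phi, psi, geometry = geometry)
  n <- n_residues(conf)
  g <- geometry
  xyz <- matrix(NA_real_, 3L * n, 3L)
  xyz[1L, ] <- c(0, 0, 0)
  xyz[2L, ] <- c(g$b_n_ca, 0, 0)
  tau <- deg2rad(g$a_n_ca_c)
  xyz[3L, ] <- xyz[2L, ] + g$b_ca_c * c(-cos(tau), sin(tau), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      iN <- a_idx(i, 1L); iCA <- a_idx(i, 2L); iC <- a_idx(i, 3L)
      xyz[iC + 1L, ] <- place_atom(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                                   g$b_c_n, g$a_ca_c_n, conf$psi[i])
      xyz[iC + 2L, ] <- place_atom(xyz[iCA, ], xyz[iC, ], xyz[iC + 1L, ],
                                   g$b_n_ca, g$a_c_n_ca, g$omega)
      xyz[iC + 3L, ] <- place_atom(xyz[iC, ], xyz[iC + 1L, ], xyz[iC + 2L, ],
                                   g$b_ca_c, g$a_n_ca_c, conf$phi[i + 1L])
    }
  }
  conf$xyz <- xyz
  dimnames(conf$xyz) <- list(atom_labels(n), c("x", "y", "z"))
  conf
}

#' Extract phi/psi dihedrals from coordinates (inverse kinematics)
#'
#' Standard torsion computation over C(i-1)-N(i)-CA(i)-C(i) for phi and
#' N(i)-CA(i)-C(i)-N(i+1) for psi; the terminal phi(1) and psi(n) are
#' reported as `NA`.
#'
#' @param conf A `conformation` with coordinates.
#' @return A list with numeric vectors `phi` and `psi` (degrees).
#' @export
extract_dihedrals <- function(conf) {
  if (is.null(conf$xyz)) stop("conformation has no coordinates")
  n <- n_residues(conf)
  xyz <- conf$xyz
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      phi[i] <- tryCatch(
        torsion4(xyz[a_idx(i - 1L, 3L), ], xyz[a_idx(i, 1L), ],
                 xyz[a_idx(i, 2L), ], xyz[a_idx(i, 3L), ]),
        error = function(e) stop("residue ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
    }
    if (i < n) {
      psi[i] <- tryCatch(
        torsion4(xyz[a_idx(i, 1L), ], xyz[a_idx(i, 2L), ],
                 xyz[a_idx(i, 3L), ], xyz[a_idx(i + 1L, 1L), ]),
        error = function(e) stop("residue ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
    }
  }
  list(phi = phi, psi = psi)
}

# Rotate a dihedral in place by delta degrees: downstream atoms move
# rigidly about the bond axis, the global frame of upstream atoms is
# untouched. Used by all move operators so that moves compose in world
# coordinates.
rotate_dihedral <- function(conf, residue, which = c("phi", "psi"), delta) {
  which <- match.arg(which)
  n <- n_residues(conf)
  if (residue < 1L || residue > n) stop("residue out of range")
  if (delta == 0) return(conf)
  if (which == "phi") {
    if (is.na(conf$phi[residue])) stop("phi undefined for residue ", residue)
    from <- conf$xyz[a_idx(residue, 1L), ]
    to <- conf$xyz[a_idx(residue, 2L), ]
    first_moving <- a_idx(residue, 3L)
    conf$phi[residue] <- wrap_angle(conf$phi[residue] + delta)
  } else {
    if (is.na(conf$psi[residue])) stop("psi undefined for residue ", residue)
    from <- conf$xyz[a_idx(residue, 2L), ]
    to <- conf$xyz[a_idx(residue, 3L), ]
    first_moving <- a_idx(residue + 1L, 1L)
    conf$psi[residue] <- wrap_angle(conf$psi[residue] + delta)
  }
  conf$xyz <- cpp_rotate_block(conf$xyz, first_moving - 1L, from,
                               to - from, delta)
  conf$energy <- NULL
  conf
}

# Set a dihedral to an absolute value (degrees) via rotation in place
set_dihedral <- function(conf, residue, which, value) {
  cur <- if (which == "phi") conf$phi[residue] else conf$psi[residue]
  rotate_dihedral(conf, residue, which, angle_diff(value, cur))
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", n_residues(x), " residues, ",
      n_dihedrals(x), " dihedrals",
      if (!is.null(x$energy)) sprintf(", energy %.4g", x$energy) else "",
      if (is.null(x$xyz)) ", no coordinates" else "", "\n", sep = "")
  cat("  sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
format.ideal_geometry <- function(x, ...) {
  sprintf("N-CA %.3f, CA-C %.3f, C-N %.3f A; angles %.1f/%.1f/%.1f; omega %g",
          x$b_n_ca, x$b_ca_c, x$b_c_n, x$a_n_ca_c, x$a_ca_c_n, x$a_c_n_ca,
          x$omega)
}

#' @export
print.ideal_geometry <- function(x, ...) {
  cat("<ideal_geometry> ", format(x), "\n", sep = "")
  invisible(x)
}
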