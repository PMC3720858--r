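#' Per-residue cumulative torsional activity along a path
#'
#' For a transition path (an ordered list of conformations) the activity
#' of residue i is
#' D_i = sum_k |wrap(phi_{i,k+1} - phi_{i,k})| + |wrap(psi_{i,k+1} - psi_{i,k})|
#' over consecutive path steps k; undefined terminal angles contribute 0.
#' Large D_i marks "active" residues: those that must change for the
#' transition to happen.
#'
#' @param path A `conformation_path` (see [extract_path()]) or a plain
#'   list of conformations with equal residue counts.
#' @return Object of class `torsional_activity`: numeric vector D of
#'   length n residues (degrees).
#' @export
torsional_activity <- function(path) {
  if (length(path) < 1L) stop("empty path")
  n <- n_residues(path[[1L]])
  if (any(vapply(path, n_residues, integer(1L)) != n)) {
    stop("inconsistent residue counts along the path")
  }
  d <- numeric(n)
  if (length(path) > 1L) {
    for (k in seq_len(length(path) - 1L)) {
      a <- path[[k]]; b <- path[[k + 1L]]
      dphi <- abs(angle_diff(b$phi, a$phi)); dphi[is.na(dphi)] <- 0
      dpsi <- abs(angle_diff(b$psi, a$psi)); dpsi[is.na(dpsi)] <- 0
      d <- d + dphi + dpsi
    }
  }
  structure(d, class = "torsional_activity")
}

#' @export
plot.torsional_activity <- function(x, ...) {
  graphics::barplot(unclass(x), names.arg = seq_along(x),
                    xlab = "residue", ylab = "cumulative torsional change (deg)",
                    ...)
  invisible(x)
}

#' 2D PCA embedding of a conformation ensemble
#'
#' Each conformation is rigidly superposed onto the reference (Kabsch on
#' CA atoms), the superposed backbone coordinates are flattened and
#' mean-centered, and the ensemble is projected onto its top two
#' principal axes. Superposition first makes the embedding invariant to
#' global rigid transforms of the inputs.
#'
#' @param conformations List of >= 2 conformations with equal atom counts.
#' @param reference Reference `conformation` (defaults to the first).
#' @param atoms Atoms entering the embedding: `"all"` backbone atoms
#'   (default) or `"CA"` only. Superposition always uses CA.
#' @return Object of class `embedding2d`: list with `points` (m x 2),
#'   `explained` (variance fractions of the two components, 0 for a
#'   degenerate ensemble), and `energies` when cached on the inputs.
#' @export
pca_embed <- function(conformations, reference = conformations[[1L]],
                      atoms = c("all", "CA")) {
  atoms <- match.arg(atoms)
  if (length(conformations) < 2L) stop("need at least 2 conformations")
  nat <- nrow(reference$xyz)
  X <- t(vapply(conformations, function(cf) {
    if (is.null(cf$xyz) || nrow(cf$xyz) != nat) {
      stop("conformations must share the reference's atom count")
    }
    fit <- superpose_rmsd(cf, reference, atoms = "CA")
    full <- sweep(cf$xyz %*% fit$rotation, 2L, fit$translation, "+")
    if (atoms == "CA") full <- full[a_idx(seq_len(nat / 3L), 2L), ]
    as.vector(t(full))
  }, numeric(if (atoms == "CA") nat else 3L * nat)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  tot <- sum(Xc^2)
  if (tot < 1e-12) {
    return(structure(list(points = matrix(0, length(conformations), 2L),
                          explained = c(0, 0),
                          energies = ensemble_energies(conformations)),
                     class = "embedding2d"))
  }
  s <- svd(Xc, nu = 2L, nv = 2L)
  pts <- s$u[, 1L:2L, drop = FALSE] %*% diag(s$d[1L:2L], 2L)
  structure(list(points = pts, explained = s$d[1L:2L]^2 / tot,
                 energies = ensemble_energies(conformations)),
            class = "embedding2d")
}

ensemble_energies <- function(conformations) {
  e <- vapply(conformations, function(cf) {
    if (is.null(cf$energy)) NA_real_ else cf$energy
  }, numeric(1L))
  if (all(is.na(e))) NULL else e
}

#' @export
print.embedding2d <- function(x, ...) {
  cat("<embedding2d> ", nrow(x$points), " conformations; explained ",
      sprintf("%.1f%% + %.1f%%", 100 * x$explained[1L],
              100 * x$explained[2L]), "\n", sep = "")
  invisible(x)
}

#' @export
plot.embedding2d <- function(x, ...) {
  col <- if (!is.null(x$energies)) {
    pal <- grDevices::hcl.colors(100L, "viridis", rev = TRUE)
    pal[cut(x$energies, 100L, labels = FALSE)]
  } else "black"
  graphics::plot(x$points, xlab = "PC1", ylab = "PC2", pch = 16L,
                 col = col, ...)
  invisible(x)
}

#' CA-RMSD of each path conformation to a goal
#'
#' @param path A `conformation_path` or list of conformations.
#' @param goal Goal `conformation`.
#' @return Numeric vector of per-step CA RMSD (Angstrom) after optimal
#'   superposition.
#' @export
goal_distance_trace <- function(path, goal) {
  if (length(path) < 1L) stop("empty path")
  vapply(path, function(cf) ca_rmsd(cf, goal), numeric(1L))
}

#' Centroid conformation of a low-energy basin
#'
#' Selects the conformations within the energy window and builds the
#' conformation whose dihedrals are the per-angle circular means of the
#' selection — the dihedral-space centroid — rebuilt through the forward
#' kinematics so the result has ideal geometry. Cartesian averaging is
#' deliberately avoided: it breaks bond geometry.
#'
#' @param conformations List of conformations with cached or computable
#'   energies.
#' @param energy_window Numeric: keep conformations with energy <= this
#'   value (`Inf` keeps all).
#' @param energy_fn Used to score conformations lacking a cached energy.
#' @return A `conformation`.
#' @export
basin_centroid <- function(conformations, energy_window = Inf,
                           energy_fn = clash_energy) {
  if (length(conformations) < 1L) stop("no conformations")
  e <- vapply(conformations, function(cf) {
    if (is.null(cf$energy)) energy_fn(cf) else cf$energy
  }, numeric(1L))
  keep <- conformations[e <= energy_window]
  if (length(keep) == 0L) stop("no conformations within the energy window")
  n <- n_residues(keep[[1L]])
  phim <- vapply(seq_len(n), function(i) {
    circular_mean(vapply(keep, function(cf) cf$phi[i], numeric(1L)))
  }, numeric(1L))
  psim <- vapply(seq_len(n), function(i) {
    circular_mean(vapply(keep, function(cf) cf$psi[i], numeric(1L)))
  }, numeric(1L))
  build_backbone(keep[[1L]]$sequence, phim, psim,
                 geometry = keep[[1L]]$geometry)
}

#' Write a path as a multi-model PDB and an activity profile as TSV
#'
#' Small report helpers used by the command-line interface.
#'
#' @param path A `conformation_path`.
#' @param file Output file.
#' @return `file`, invisibly.
#' @export
write_path_pdb <- function(path, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (k in seq_along(path)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    tmp <- tempfile(fileext = ".pdb")
    write_pdb(path[[k]], tmp)
    atoms <- grep("^ATOM", readLines(tmp), value = TRUE)
    unlink(tmp)
    writeLines(atoms, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
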