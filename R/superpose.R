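#' Optimal rigid superposition and RMSD (Kabsch)
#'
#' Finds the proper rotation (no reflection) and translation minimizing the
#' RMSD of the selected atoms of `a` onto those of `b`, via SVD of the
#' cross-covariance matrix.
#'
#' @param a,b Conformations with coordinates, or bare n x 3 coordinate
#'   matrices.
#' @param atoms Atom selection: `"CA"` (default), `"all"` (N, CA, C), or an
#'   integer vector of flat atom indices. Ignored for bare matrices.
#' @return A list with `rmsd` (Angstrom), `rotation` (3 x 3, applied to
#'   row-vectors of `a` on the right), `translation` (length-3), and
#'   `xyz` — the coordinates of the selection of `a` after superposition.
#'   `x %*% rotation + translation` maps `a`'s frame onto `b`'s.
#' @export
superpose_rmsd <- function(a, b, atoms = "CA") {
  P <- sel_xyz(a, atoms)
  Q <- sel_xyz(b, atoms)
  if (!all(dim(P) == dim(Q))) stop("atom selections differ in size")
  if (nrow(P) < 1L) stop("empty atom selection")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc); Q0 <- sweep(Q, 2L, qc)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((fit - Q0)^2)))
  list(rmsd = rmsd, rotation = R, translation = qc - as.vector(pc %*% R),
       xyz = sweep(fit, 2L, qc, "+"))
}

sel_xyz <- function(x, atoms) {
  if (is.matrix(x)) return(x)
  if (!inherits(x, "conformation")) stop("expected a conformation or matrix")
  if (is.null(x$xyz)) stop("conformation has no coordinates")
  if (is.numeric(atoms)) return(x$xyz[atoms, , drop = FALSE])
  switch(atoms,
         CA = ca_coords(x),
         all = x$xyz,
         stop("unknown atom selection '", atoms, "'"))
}

#' CA RMSD between two conformations after optimal superposition
#' @inheritParams superpose_rmsd
#' @export
ca_rmsd <- function(a, b) superpose_rmsd(a, b, atoms = "CA")$rmsd
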