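#' Move results
#'
#' Every perturbation operator returns a `move_result`: the new
#' conformation, the move kind, the acted-on subset, a success flag and
#' diagnostics. On failure the returned conformation is the unmodified
#' input, so a planner can treat a failed move as a rejected iteration.
#'
#' @param conf Resulting `conformation`.
#' @param kind Move kind tag.
#' @param subset_id Identifier of the residue subset acted on.
#' @param success Logical.
#' @param diagnostics Named list (e.g. closure sweeps, anchor deviation).
#' @return Object of class `move_result`.
#' @keywords internal
move_result <- function(conf, kind, subset_id = NA_character_,
                        success = TRUE, diagnostics = list()) {
  structure(list(conformation = conf, kind = kind, subset_id = subset_id,
                 success = success, diagnostics = diagnostics),
            class = "move_result")
}

#' @export
print.move_result <- function(x, ...) {
  cat("<move_result> ", x$kind,
      if (!is.na(x$subset_id)) paste0(" on '", x$subset_id, "'"),
      ": ", if (x$success) "success" else "failure", "\n", sep = "")
  invisible(x)
}

#' Uniform random dihedral perturbation of a residue subset
#'
#' Each defined phi/psi of the subset's residues is shifted by an
#' independent uniform draw from \[-max_delta, +max_delta\] and wrapped;
#' every other dihedral is untouched. Draws consume the R session RNG
#' (seed with [set.seed()] for reproducibility).
#'
#' @param conf A `conformation` with coordinates.
#' @param subset Integer vector of residue indices.
#' @param max_delta Maximum perturbation magnitude, degrees.
#' @param subset_id Optional label recorded on the result.
#' @return A `move_result`.
#' @export
dihedral_perturbation <- function(conf, subset, max_delta = 10,
                                  subset_id = NA_character_) {
  if (max_delta < 0) stop("max_delta must be >= 0")
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) {
    return(move_result(conf, "dihedral", subset_id, success = FALSE,
                       diagnostics = list(reason = "empty subset")))
  }
  if (any(subset < 1L | subset > n_residues(conf))) {
    stop("subset contains residues outside the chain")
  }
  for (i in subset) {
    if (!is.na(conf$phi[i])) {
      conf <- rotate_dihedral(conf, i, "phi",
                              stats::runif(1L, -max_delta, max_delta))
    }
    if (!is.na(conf$psi[i])) {
      conf <- rotate_dihedral(conf, i, "psi",
                              stats::runif(1L, -max_delta, max_delta))
    }
  }
  move_result(conf, "dihedral", subset_id)
}

# anchor atoms of the residue closing a loop [start, end]: N, CA, C of
# residue end + 1
anchor_indices <- function(end) a_idx(end + 1L, 1L:3L)

anchor_rms <- function(conf, end, targets) {
  dev <- conf$xyz[anchor_indices(end), , drop = FALSE] - targets
  sqrt(mean(rowSums(dev^2)))
}

#' Cyclic coordinate descent loop closure
#'
#' Iteratively sweeps the loop's phi/psi dihedrals; each is rotated by the
#' closed-form angle minimizing the summed squared distance of the three
#' C-terminal anchor atoms (N, CA, C of the residue just after the loop)
#' to their targets. Stops when the RMS anchor deviation drops to `tol`
#' or after `max_iter` sweeps. Dihedrals outside the loop are unchanged;
#' atoms downstream of the anchors ride rigidly with the anchor frame.
#'
#' @param conf A `conformation` with coordinates.
#' @param loop Integer pair `c(start, end)` of the loop residue range;
#'   residue `end + 1` must exist (it carries the anchors).
#' @param targets 3 x 3 matrix of target coordinates for the anchor N,
#'   CA, C (rows in that order).
#' @param tol RMS anchor deviation defining success, Angstrom.
#' @param max_iter Maximum number of CCD sweeps.
#' @param subset_id Optional label recorded on the result.
#' @return A `move_result`; diagnostics hold `sweeps` and `deviation`.
#' @export
ccd_close <- function(conf, loop, targets, tol = 0.08, max_iter = 200L,
                      subset_id = NA_character_) {
  n <- n_residues(conf)
  start <- as.integer(loop[1L]); end <- as.integer(loop[2L])
  if (start < 1L || end < start || end + 1L > n) {
    stop("loop [", start, ", ", end, "] outside chain of ", n, " residues")
  }
  targets <- as.matrix(targets)
  if (!all(dim(targets) == c(3L, 3L)) || any(!is.finite(targets))) {
    stop("targets must be a finite 3 x 3 matrix")
  }
  res <- cpp_ccd(conf$xyz, start, end, targets, tol, as.integer(max_iter))
  ok <- res$deviation <= tol
  if (ok) {
    conf$xyz <- res$xyz
    idx <- start:end
    conf$phi[idx] <- wrap_angle(conf$phi[idx] + res$dphi)
    conf$psi[idx] <- wrap_angle(conf$psi[idx] + res$dpsi)
    conf$energy <- NULL
  }
  move_result(conf, "ccd", subset_id, success = ok,
              diagnostics = list(sweeps = res$sweeps,
                                 deviation = res$deviation))
}

# Closed-form optimal rotation angle (degrees) about the axis through
# `origin` with direction `axis` that minimizes the summed squared
# distance of `moving` (rows) to `targets` (rows).
ccd_optimal_angle <- function(moving, targets, origin, axis) {
  u <- unitv(axis)
  a <- 0; b <- 0
  for (j in seq_len(nrow(moving))) {
    p <- moving[j, ] - origin
    o <- sum(p * u) * u
    r <- p - o
    s <- vnorm(r)
    if (s < 1e-9) next
    rh <- r / s
    th <- cross3(u, rh)
    f <- (targets[j, ] - origin) - o
    a <- a + s * sum(f * rh)
    b <- b + s * sum(f * th)
  }
  if (a == 0 && b == 0) return(0)
  rad2deg(atan2(b, a))
}

#' Endpoint-constrained random loop sampling
#'
#' Records the loop's current C-terminal anchor positions, randomizes the
#' loop dihedrals uniformly over (-180, 180], then closes back onto the
#' recorded anchors with [ccd_close()]. On success all dihedrals outside
#' the loop are unchanged and every downstream atom has moved by at most
#' the residual anchor deviation; on closure failure the input is
#' returned untouched.
#'
#' @inheritParams ccd_close
#' @param tol,max_iter Closure tolerance (Angstrom) and sweep budget.
#' @return A `move_result`.
#' @export
loop_sample <- function(conf, loop, tol = 0.08, max_iter = 200L,
                        subset_id = NA_character_) {
  start <- as.integer(loop[1L]); end <- as.integer(loop[2L])
  if (end - start + 1L < 3L) {
    return(move_result(conf, "loop", subset_id, success = FALSE,
                       diagnostics = list(reason = "loop shorter than 3 residues")))
  }
  if (end + 1L > n_residues(conf)) {
    return(move_result(conf, "loop", subset_id, success = FALSE,
                       diagnostics = list(reason = "no anchor residue after loop")))
  }
  targets <- conf$xyz[anchor_indices(end), , drop = FALSE]
  trial <- conf
  for (i in start:end) {
    if (!is.na(trial$phi[i])) {
      trial <- set_dihedral(trial, i, "phi", stats::runif(1L, -180, 180))
    }
    if (!is.na(trial$psi[i])) {
      trial <- set_dihedral(trial, i, "psi", stats::runif(1L, -180, 180))
    }
  }
  closed <- ccd_close(trial, c(start, end), targets, tol = tol,
                      max_iter = max_iter, subset_id = subset_id)
  if (!closed$success) {
    return(move_result(conf, "loop", subset_id, success = FALSE,
                       diagnostics = closed$diagnostics))
  }
  move_result(closed$conformation, "loop", subset_id,
              diagnostics = closed$diagnostics)
}

#' Rigid-body displacement of the domain downstream of a loop
#'
#' Samples a small rigid transform (rotation up to `max_rot` about a
#' random axis through the anchor centroid, translation up to
#' `max_disp`), applies it to the loop's anchor targets, and closes the
#' loop onto the transformed targets. On success the downstream domain is
#' carried rigidly by (up to the closure tolerance) exactly the sampled
#' transform while upstream atoms are untouched.
#'
#' @inheritParams loop_sample
#' @param max_disp Maximum translation, Angstrom.
#' @param max_rot Maximum rotation, degrees.
#' @return A `move_result`; diagnostics record the sampled transform.
#' @export
rigid_body_move <- function(conf, loop, max_disp = 1.0, max_rot = 5,
                            tol = 0.08, max_iter = 200L,
                            subset_id = NA_character_) {
  start <- as.integer(loop[1L]); end <- as.integer(loop[2L])
  if (end - start + 1L < 3L) {
    return(move_result(conf, "rigid", subset_id, success = FALSE,
                       diagnostics = list(reason = "loop shorter than 3 residues")))
  }
  if (end + 1L > n_residues(conf)) {
    return(move_result(conf, "rigid", subset_id, success = FALSE,
                       diagnostics = list(reason = "no anchor residue after loop")))
  }
  anchors <- conf$xyz[anchor_indices(end), , drop = FALSE]
  axis <- random_unit_vector()
  angle <- stats::runif(1L, 0, max_rot)
  shift <- random_unit_vector() * stats::runif(1L, 0, max_disp)
  center <- colMeans(anchors)
  targets <- rotate_points(anchors, center, axis, angle)
  targets <- sweep(targets, 2L, shift, "+")
  closed <- ccd_close(conf, c(start, end), targets, tol = tol,
                      max_iter = max_iter, subset_id = subset_id)
  diag <- c(closed$diagnostics,
            list(axis = axis, angle = angle, translation = shift))
  move_result(closed$conformation, "rigid", subset_id,
              success = closed$success, diagnostics = diag)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

#' Whole-protein energy minimization as a move
#'
#' Wraps [minimize_energy()] over the given subset (default: all
#' residues) with a modest iteration budget; always succeeds and never
#' increases the energy.
#'
#' @param conf A `conformation` with coordinates.
#' @param energy_fn Scoring function.
#' @param subset Residue indices (default all).
#' @param max_iters Pass budget handed to [minimize_energy()].
#' @param subset_id Optional label recorded on the result.
#' @return A `move_result` with `success = TRUE`.
#' @export
minimization_move <- function(conf, energy_fn = clash_energy,
                              subset = seq_len(n_residues(conf)),
                              max_iters = 10L, subset_id = NA_character_) {
  out <- minimize_energy(conf, energy_fn, subset = subset,
                         max_iters = max_iters)
  move_result(out, "minimize", subset_id,
              diagnostics = list(energy = out$energy))
}

# maximal contiguous runs of a sorted residue index set, as a list of
# c(start, end) pairs
contiguous_runs <- function(residues) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L) return(list())
  breaks <- which(diff(residues) > 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(residues))
  Map(function(s, e) c(residues[s], residues[e]), starts, ends)
}

#' Coordinated loop sampling over a residue subset
#'
#' Interprets a (possibly non-contiguous) subset as a collection of loop
#' regions: each maximal contiguous run is loop-sampled in random order
#' within one move, and the move succeeds only if every closure succeeds.
#'
#' @inheritParams loop_sample
#' @param subset Integer vector of residue indices.
#' @return A `move_result`.
#' @export
multi_loop_sample <- function(conf, subset, tol = 0.08, max_iter = 200L,
                              subset_id = NA_character_) {
  runs <- contiguous_runs(subset)
  if (length(runs) == 0L) {
    return(move_result(conf, "loop", subset_id, success = FALSE,
                       diagnostics = list(reason = "empty subset")))
  }
  order <- sample.int(length(runs))
  trial <- conf
  for (r in runs[order]) {
    res <- loop_sample(trial, r, tol = tol, max_iter = max_iter,
                       subset_id = subset_id)
    if (!res$success) {
      return(move_result(conf, "loop", subset_id, success = FALSE,
                         diagnostics = res$diagnostics))
    }
    trial <- res$conformation
  }
  move_result(trial, "loop", subset_id)
}
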