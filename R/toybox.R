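#' Synthetic toy transition problems
#'
#' Self-contained start/goal conformation pairs with known mechanisms,
#' so the whole pipeline (moves, planner, analysis) can be exercised
#' without external structure files. `start` and `goal` share sequence
#' and annotation, both are clash-free under the suggested threshold,
#' and they differ by more than a typical goal tolerance.
#'
#' @name toy_problems
#' @keywords internal
NULL

toy_problem <- function(start, goal, ss, active, threshold, mechanism) {
  structure(list(start = start, goal = goal, ss = ss, active = active,
                 threshold = threshold, mechanism = mechanism),
            class = "toy_problem")
}

#' @export
print.toy_problem <- function(x, ...) {
  cat("<toy_problem> ", x$mechanism, ", ", n_residues(x$start),
      " residues\n", sep = "")
  cat("  annotation: ", paste(x$ss, collapse = ""), "\n", sep = "")
  cat("  active residues: ", format_ranges(x$active), "\n", sep = "")
  cat(sprintf("  dihedral distance start-goal: %.1f deg; threshold %.3g\n",
              dihedral_distance(x$start, x$goal), x$threshold))
  invisible(x)
}

# helix basin (-57, -47); loop seeds near (-120, 120), jittered
toy_angles <- function(ss, jitter = 5) {
  n <- length(ss)
  phi <- ifelse(ss == "H", -57, -120) + stats::runif(n, -jitter, jitter)
  psi <- ifelse(ss == "H", -47, 120) + stats::runif(n, -jitter, jitter)
  phi[1L] <- NA
  psi[n] <- NA
  list(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

#' Hinge toy system: helix-loop-helix with a torsional hinge
#'
#' Two helices joined by a central loop; the goal differs from the start
#' only by a fixed shift of the loop residues' dihedrals, swinging the
#' second helix about the hinge. Mirrors the classic single-hinge
#' two-domain transition problem.
#'
#' @param helix_len Residues per helix (>= 3).
#' @param loop_len Loop residues (>= 3).
#' @param hinge_delta Dihedral shift (degrees) applied to the loop in
#'   the goal state.
#' @param seed Integer seed; the problem is deterministic per seed.
#' @param threshold Suggested planner energy threshold.
#' @return A `toy_problem`.
#' @export
make_hinge_toy <- function(helix_len = 8L, loop_len = 5L, hinge_delta = 40,
                           seed = 1L, threshold = 1.0) {
  if (helix_len < 3L || loop_len < 3L) stop("lengths must be >= 3")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ss <- c(rep("H", helix_len), rep("L", loop_len), rep("H", helix_len))
  n <- length(ss)
  seq1 <- paste(rep("A", n), collapse = "")
  loop <- helix_len + seq_len(loop_len)
  for (attempt in seq_len(10L)) {
    ang <- toy_angles(ss)
    start <- build_backbone(seq1, ang$phi, ang$psi)
    phi_g <- ang$phi; psi_g <- ang$psi
    phi_g[loop] <- wrap_angle(phi_g[loop] + hinge_delta)
    psi_g[loop] <- wrap_angle(psi_g[loop] + hinge_delta)
    goal <- build_backbone(seq1, phi_g, psi_g)
    if (clash_energy(start) == 0 && clash_energy(goal) == 0) {
      start$energy <- 0
      goal$energy <- 0
      return(toy_problem(start, goal, ss, active = loop,
                         threshold = threshold, mechanism = "hinge"))
    }
  }
  stop("could not generate a clash-free hinge problem in 10 attempts; ",
       "try another seed or a smaller hinge_delta")
}

#' Tri-loop toy system: two domains coupled through three loops
#'
#' A chain of four helical blocks separated by three loops. The goal is
#' built from the start by passing the same small rigid displacement
#' through each loop in turn with a rigid-body closure move, so start
#' and goal differ only in loop dihedrals while the blocks keep their
#' internal geometry — relative domain motion requires coordinated
#' changes in all the loops, since any single closed loop perturbation
#' (anchors held) leaves the downstream domain pose unchanged.
#'
#' @param block_len Residues per helical block (>= 3).
#' @param loop_len Residues per loop (>= 3).
#' @param rot Rigid rotation (degrees) passed through each loop when
#'   building the goal.
#' @param disp Rigid translation (Angstrom) per loop.
#' @param seed Integer seed.
#' @param threshold Suggested planner energy threshold.
#' @param max_attempts Regeneration attempts before giving up.
#' @return A `toy_problem`.
#' @export
make_triloop_toy <- function(block_len = 4L, loop_len = 4L, rot = 8,
                             disp = 0.3, seed = 1L, threshold = 1.0,
                             max_attempts = 20L) {
  if (block_len < 3L || loop_len < 3L) stop("lengths must be >= 3")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  block <- rep("H", block_len)
  lp <- rep("L", loop_len)
  ss <- c(block, lp, block, lp, block, lp, block)
  n <- length(ss)
  seq1 <- paste(rep("A", n), collapse = "")
  loop_starts <- block_len + (0L:2L) * (block_len + loop_len) + 1L
  loops <- lapply(loop_starts, function(s) c(s, s + loop_len - 1L))
  for (attempt in seq_len(max_attempts)) {
    ang <- toy_angles(ss)
    start <- build_backbone(seq1, ang$phi, ang$psi)
    if (clash_energy(start) > threshold) next
    goal <- start
    ok <- TRUE
    for (l in loops) {
      res <- rigid_body_move(goal, l, max_disp = disp, max_rot = rot)
      if (!res$success) { ok <- FALSE; break }
      goal <- res$conformation
    }
    if (!ok) next
    if (clash_energy(goal) > threshold) next
    active <- unlist(lapply(loops, function(l) l[1L]:l[2L]))
    if (dihedral_distance(start, goal) < 1) next
    start$energy <- clash_energy(start)
    goal$energy <- clash_energy(goal)
    return(toy_problem(start, goal, ss, active = active,
                       threshold = threshold, mechanism = "triloop"))
  }
  stop("could not generate a feasible tri-loop problem in ", max_attempts,
       " attempts")
}

#' Decoy ensemble around a conformation
#'
#' n copies with independent Gaussian dihedral noise of scale `sigma`
#' (degrees), wrapped and rebuilt through the kinematics. Used as
#' fixtures for embedding and density tests.
#'
#' @param conf A `conformation`.
#' @param n Number of decoys (>= 1).
#' @param sigma Noise scale in degrees (>= 0).
#' @param seed Integer seed.
#' @return List of `n` conformations.
#' @export
make_decoys <- function(conf, n, sigma, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nres <- n_residues(conf)
  lapply(seq_len(n), function(i) {
    phi <- wrap_angle(conf$phi + stats::rnorm(nres, 0, sigma))
    psi <- wrap_angle(conf$psi + stats::rnorm(nres, 0, sigma))
    phi[1L] <- NA; psi[nres] <- NA
    build_backbone(conf$sequence, phi, psi, geometry = conf$geometry)
  })
}
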