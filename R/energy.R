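#' Parameters of the built-in soft-sphere clash energy
#'
#' The package's default energy is a purely steric, dimensionless score:
#' overlapping atom pairs are penalized quadratically, and nothing else
#' contributes. It is deliberately simple — the planner accepts any
#' deterministic scoring function of a conformation — but it gives the
#' feasibility test real teeth on backbone-only models.
#'
#' @param sigma Contact radius per atom, Angstrom. The default 1.5 is a
#'   deliberately soft backbone radius: an ideal alpha-helix brings
#'   C(i) and N(i+2) to about 3.27 A (hydrogen-bond range), which must
#'   not count as a clash for a backbone-only model.
#' @param k Clash stiffness, score units per Angstrom squared.
#' @param exclude_bonds Pairs within this many bonds along the chain are
#'   excluded (covalently forced contacts must not dominate).
#' @param cutoff Distance beyond which pairs are ignored, Angstrom.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(sigma = 1.5, k = 1.0, exclude_bonds = 3L,
                          cutoff = 8) {
  if (sigma <= 0 || k <= 0) stop("sigma and k must be > 0")
  if (cutoff < 2 * sigma) stop("cutoff must be at least 2 * sigma")
  structure(list(sigma = sigma, k = k,
                 exclude_bonds = as.integer(exclude_bonds), cutoff = cutoff),
            class = "energy_params")
}

#' Soft-sphere steric clash energy
#'
#' E = sum over non-excluded atom pairs with distance d < sigma_i + sigma_j
#' of k * (sigma_i + sigma_j - d)^2. The backbone is a linear chain
#' (N-CA-C-N-...), so the bonded separation of two atoms is the difference
#' of their flat indices; pairs within `exclude_bonds` bonds contribute 0.
#'
#' @param conf A `conformation` with coordinates.
#' @param params An [energy_params()].
#' @return Nonnegative scalar score.
#' @export
clash_energy <- function(conf, params = energy_params()) {
  if (is.null(conf$xyz)) stop("conformation has no coordinates")
  if (nrow(conf$xyz) < 2L) return(0)
  cpp_clash_energy(conf$xyz, params$sigma, params$k, params$exclude_bonds,
                   params$cutoff)
}

#' Energy-threshold feasibility test
#'
#' A conformation is feasible when its energy does not exceed the
#' threshold (boundary included). The evaluated energy is cached on the
#' conformation when the caller keeps the attribute-carrying result.
#'
#' @param conf A `conformation`.
#' @param energy_fn A function `conformation -> scalar`; lower is better.
#' @param threshold Feasibility cutoff in score units.
#' @return Logical scalar; attribute `"conformation"` holds `conf` with
#'   `$energy` filled in.
#' @export
is_feasible <- function(conf, energy_fn = clash_energy, threshold) {
  e <- if (is.null(conf$energy)) energy_fn(conf) else conf$energy
  conf$energy <- e
  structure(e <= threshold, conformation = conf)
}

#' Greedy dihedral-space energy minimization
#'
#' Derivative-free coordinate descent: for each defined dihedral of the
#' subset, in order, try +step and -step and keep the best non-worsening
#' change; after a full pass with no strict improvement the step is
#' halved. Stops when the iteration budget is spent or the step drops
#' below `min_step`. Angles outside the subset are untouched, the energy
#' never increases, and the procedure is deterministic.
#'
#' @param conf A `conformation` with coordinates.
#' @param energy_fn Scoring function, `conformation -> scalar`.
#' @param subset Integer vector of residue indices (default: all).
#' @param max_iters Maximum number of full passes.
#' @param step Initial trial step, degrees.
#' @param min_step Terminate once the shrinking step falls below this.
#' @return The minimized `conformation` with `$energy` cached.
#' @export
minimize_energy <- function(conf, energy_fn = clash_energy,
                            subset = seq_len(n_residues(conf)),
                            max_iters = 20L, step = 5, min_step = 0.1) {
  if (max_iters < 0L) stop("max_iters must be >= 0")
  e <- if (is.null(conf$energy)) energy_fn(conf) else conf$energy
  conf$energy <- e
  if (max_iters == 0L) return(conf)
  targets <- list()
  for (i in sort(unique(as.integer(subset)))) {
    if (!is.na(conf$phi[i])) targets[[length(targets) + 1L]] <- c(i, 1L)
    if (!is.na(conf$psi[i])) targets[[length(targets) + 1L]] <- c(i, 2L)
  }
  if (length(targets) == 0L) return(conf)
  for (pass in seq_len(max_iters)) {
    improved <- FALSE
    for (t in targets) {
      which <- if (t[2L] == 1L) "phi" else "psi"
      best <- conf; best_e <- e
      for (s in c(step, -step)) {
        cand <- rotate_dihedral(conf, t[1L], which, s)
        ce <- energy_fn(cand)
        if (ce < best_e) { best <- cand; best_e <- ce }
      }
      if (best_e < e) {
        conf <- best; conf$energy <- best_e
        improved <- TRUE
        e <- best_e
      }
      if (e == 0) break
    }
    if (e == 0) break
    if (!improved) {
      step <- step / 2
      if (step < min_step) break
    }
  }
  conf$energy <- e
  conf
}
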