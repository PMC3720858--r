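#' Random orthonormal 2D projection of dihedral space
#'
#' The planner estimates sampling density in two dimensions. A
#' conformation with n defined dihedrals is encoded as the length-2n
#' vector of cosines and sines of its angles; that vector is mapped to a
#' 2D point by a 2 x 2n matrix whose entries are drawn from a standard
#' normal, after which row 1 is normalized and row 2 is made orthogonal
#' to row 1 (Gram-Schmidt) and normalized. A random projection is used
#' because no natural choice exists in general and random projections
#' capture sample density well.
#'
#' @param n Number of defined dihedral angles.
#' @param seed Integer seed; the construction is deterministic per seed.
#' @return Object of class `projection_matrix` (fields `m`, `n`, `seed`).
#' @export
make_projection <- function(n, seed) {
  if (n < 1L) stop("n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  repeat {
    m <- matrix(stats::rnorm(4L * n), nrow = 2L)
    n1 <- sqrt(sum(m[1L, ]^2))
    if (n1 < 1e-12) next
    m[1L, ] <- m[1L, ] / n1
    m[2L, ] <- m[2L, ] - sum(m[2L, ] * m[1L, ]) * m[1L, ]
    n2 <- sqrt(sum(m[2L, ]^2))
    if (n2 < 1e-12) next
    m[2L, ] <- m[2L, ] / n2
    break
  }
  structure(list(m = m, n = as.integer(n), seed = seed),
            class = "projection_matrix")
}

#' Project dihedrals to a 2D point
#'
#' Encodes the defined angles (fixed residue order, phi before psi) as
#' (cos t1, sin t1, ..., cos tn, sin tn) and applies the projection.
#'
#' @param proj A [make_projection()] result.
#' @param x A `conformation`, or a numeric vector of n defined dihedrals
#'   in degrees.
#' @return Numeric length-2 point.
#' @export
project_point <- function(proj, x) {
  ang <- if (inherits(x, "conformation")) flat_dihedrals(x) else x
  if (length(ang) != proj$n) {
    stop("expected ", proj$n, " dihedrals, got ", length(ang))
  }
  r <- deg2rad(ang)
  v <- as.vector(rbind(cos(r), sin(r)))
  as.vector(proj$m %*% v)
}

#' Grid cell index of a projected point
#'
#' Half-open cells: `floor(point / size)` per axis, so a boundary point
#' belongs to the upper cell.
#'
#' @param point Numeric length-2.
#' @param size Cell edge length (> 0), projection units.
#' @return Integer pair.
#' @export
cell_index <- function(point, size) {
  if (size <= 0) stop("cell size must be > 0")
  as.integer(floor(point / size))
}

# --- density grid -----------------------------------------------------------
# Mutable store (environment) mapping "i_j" keys to node-id lists, with
# per-cell counts and interior/exterior flags kept incrementally: a
# non-empty cell is exterior iff at least one of its 8 neighbors is empty.

new_density_grid <- function(size) {
  g <- new.env(parent = emptyenv())
  g$size <- size
  g$cells <- new.env(parent = emptyenv())   # key -> integer node ids
  g$pos <- new.env(parent = emptyenv())     # key -> position in vectors
  g$keys <- character(0L)
  g$coords <- matrix(integer(0L), 0L, 2L)
  g$counts <- integer(0L)
  g$ext <- logical(0L)
  class(g) <- "density_grid"
  g
}

grid_key <- function(cc) paste0(cc[1L], "_", cc[2L])

neighbor_keys <- function(cc) {
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  paste0(cc[1L] + dx, "_", cc[2L] + dy)
}

cell_is_exterior <- function(grid, cc) {
  for (k in neighbor_keys(cc)) {
    if (is.null(grid$cells[[k]])) return(TRUE)
  }
  FALSE
}

grid_insert <- function(grid, point, id) {
  cc <- cell_index(point, grid$size)
  key <- grid_key(cc)
  p <- grid$pos[[key]]
  if (is.null(p)) {
    grid$cells[[key]] <- as.integer(id)
    p <- length(grid$keys) + 1L
    grid$pos[[key]] <- p
    grid$keys <- c(grid$keys, key)
    grid$coords <- rbind(grid$coords, cc)
    grid$counts <- c(grid$counts, 1L)
    grid$ext <- c(grid$ext, cell_is_exterior(grid, cc))
    # a newly occupied cell can flip its occupied neighbors to interior
    for (nk in neighbor_keys(cc)) {
      np <- grid$pos[[nk]]
      if (!is.null(np)) {
        grid$ext[np] <- cell_is_exterior(grid, grid$coords[np, ])
      }
    }
  } else {
    grid$cells[[key]] <- c(grid$cells[[key]], as.integer(id))
    grid$counts[p] <- grid$counts[p] + 1L
  }
  cc
}

grid_cell_counts <- function(grid) stats::setNames(grid$counts, grid$keys)

grid_exterior_flags <- function(grid) stats::setNames(grid$ext, grid$keys)

#' Inverse-density, exterior-biased cell selection
#'
#' With probability `p_ext` the draw is made among exterior cells
#' (non-empty cells with at least one empty 8-neighbor), otherwise among
#' interior cells; if the chosen class is empty the other is used.
#' Within a class, a cell's weight is inversely proportional to the
#' number of tree nodes it holds.
#'
#' @param grid A planner density grid.
#' @param p_ext Probability of drawing from the exterior class.
#' @return The selected cell's key (character).
#' @export
select_cell <- function(grid, p_ext = 0.75) {
  keys <- grid$keys
  if (length(keys) == 0L) stop("empty grid")
  pick_ext <- stats::runif(1L) < p_ext
  idx <- if (pick_ext) which(grid$ext) else which(!grid$ext)
  if (length(idx) == 0L) idx <- seq_along(keys)
  keys[idx][sample.int(length(idx), 1L, prob = 1 / grid$counts[idx])]
}

#' Planner configuration
#'
#' @param threshold Energy-threshold for accepting conformations (score
#'   units); sampled conformations above it are discarded.
#' @param cell_size Grid cell edge length in projection units, or `NULL`
#'   to calibrate from the start conformation (the projected spread of
#'   100 random dihedral perturbations, divided by 10 per axis).
#' @param p_ext Exterior-cell bias probability.
#' @param goal Optional goal `conformation` (directed search).
#' @param goal_bias Probability of replacing the schema move with a
#'   bounded interpolation step of all dihedrals toward the goal.
#' @param goal_tol Mean wrapped absolute dihedral distance (degrees)
#'   below which the goal counts as reached.
#' @param budget Iteration budget (> 0).
#' @param seed Integer master seed for the run (projection, moves).
#' @param max_delta Per-angle cap (degrees) for dihedral perturbations
#'   and goal-interpolation steps.
#' @return Object of class `planner_config`.
#' @export
planner_config <- function(threshold, cell_size = NULL, p_ext = 0.75,
                           goal = NULL, goal_bias = 0.05, goal_tol = 5,
                           budget = 1000L, seed = 1L, max_delta = 10) {
  if (budget < 0L) stop("budget must be >= 0")
  stopifnot(p_ext >= 0, p_ext <= 1, goal_bias >= 0, goal_bias <= 1)
  structure(list(threshold = threshold, cell_size = cell_size,
                 p_ext = p_ext, goal = goal, goal_bias = goal_bias,
                 goal_tol = goal_tol, budget = as.integer(budget),
                 seed = as.integer(seed), max_delta = max_delta),
            class = "planner_config")
}

# spread-based default cell size: project the start and 100 small random
# perturbations, take range/10 per axis (max over axes, isotropic cells)
calibrate_cell_size <- function(start, proj, max_delta) {
  pts <- matrix(NA_real_, 101L, 2L)
  pts[1L, ] <- project_point(proj, start)
  base <- flat_dihedrals(start)
  for (i in 2L:101L) {
    pts[i, ] <- project_point(
      proj, wrap_angle(base + stats::runif(length(base), -max_delta, max_delta)))
  }
  spread <- max(apply(pts, 2L, function(x) diff(range(x))))
  if (spread < 1e-9) spread <- 0.1
  spread / 10
}

#' Expansive conformational tree search
#'
#' Grows a tree of energetically feasible conformations from `start`.
#' Each iteration (1) samples a grid cell inversely proportional to its
#' density with a heavy bias towards exterior cells, (2) samples a tree
#' node uniformly from that cell, (3) applies a random move drawn from
#' the schema (or, in directed mode with probability `goal_bias`, a
#' bounded interpolation step of all dihedrals toward the goal along the
#' shortest angular arc), and (4) accepts the resulting conformation if
#' its energy does not exceed the threshold, connecting it to its parent
#' and inserting it into the grid. The search stops when the budget is
#' exhausted or, in directed mode, when a node comes within `goal_tol`
#' mean dihedral distance of the goal.
#'
#' @param start Feasible starting `conformation`.
#' @param sch A `schema` over the chain's residues.
#' @param energy_fn Scoring function, `conformation -> scalar`.
#' @param config A [planner_config()].
#' @return An `exploration_tree`.
#' @export
explore <- function(start, sch, energy_fn = clash_energy, config) {
  validate_schema(sch, n_residues(start))
  e0 <- energy_fn(start)
  if (e0 > config$threshold) {
    stop("infeasible start: energy ", format(e0), " exceeds threshold ",
         format(config$threshold))
  }
  set.seed(config$seed)
  proj <- make_projection(n_dihedrals(start), seed = config$seed)
  cell_size <- if (is.null(config$cell_size)) {
    calibrate_cell_size(start, proj, config$max_delta)
  } else config$cell_size
  grid <- new_density_grid(cell_size)

  start$energy <- e0
  nodes <- vector("list", config$budget + 1L)
  pt <- project_point(proj, start)
  cc <- grid_insert(grid, pt, 1L)
  nodes[[1L]] <- list(id = 1L, parent = NA_integer_, conformation = start,
                      kind = "root", subset_id = NA_character_, energy = e0,
                      point = pt, cell = cc)
  n_nodes <- 1L
  goal_flat <- if (!is.null(config$goal)) flat_dihedrals(config$goal)
  solution <- NA_integer_
  iters <- 0L

  for (iter in seq_len(config$budget)) {
    iters <- iter
    key <- select_cell(grid, config$p_ext)
    ids <- grid$cells[[key]]
    node <- nodes[[ids[sample.int(length(ids), 1L)]]]
    conf <- node$conformation

    use_goal <- !is.null(config$goal) && stats::runif(1L) < config$goal_bias
    if (use_goal) {
      res <- goal_step(conf, goal_flat, config$max_delta)
    } else {
      pick <- sample_move(sch)
      res <- apply_schema_move(conf, sch$subsets[[pick$subset_id]],
                               pick$kind, energy_fn)
    }
    if (!res$success) next
    feas <- is_feasible(res$conformation, energy_fn, config$threshold)
    if (!feas) next
    cand <- attr(feas, "conformation")
    n_nodes <- n_nodes + 1L
    pt <- project_point(proj, cand)
    cc <- grid_insert(grid, pt, n_nodes)
    nodes[[n_nodes]] <- list(id = n_nodes, parent = node$id,
                             conformation = cand, kind = res$kind,
                             subset_id = res$subset_id, energy = cand$energy,
                             point = pt, cell = cc)
    if (!is.null(config$goal) &&
        mean(abs(angle_diff(flat_dihedrals(cand), goal_flat))) <=
          config$goal_tol) {
      solution <- n_nodes
      break
    }
  }
  structure(list(nodes = nodes[seq_len(n_nodes)], grid = grid,
                 projection = proj, config = config, solution = solution,
                 iterations = iters),
            class = "exploration_tree")
}

# bounded interpolation of all defined dihedrals toward the goal along
# the shortest angular arc (per-angle step capped at max_delta)
goal_step <- function(conf, goal_flat, max_delta) {
  cur <- flat_dihedrals(conf)
  delta <- angle_diff(goal_flat, cur)
  delta <- pmax(pmin(delta, max_delta), -max_delta)
  k <- 0L
  for (i in seq_len(n_residues(conf))) {
    if (!is.na(conf$phi[i])) {
      k <- k + 1L
      if (delta[k] != 0) conf <- rotate_dihedral(conf, i, "phi", delta[k])
    }
    if (!is.na(conf$psi[i])) {
      k <- k + 1L
      if (delta[k] != 0) conf <- rotate_dihedral(conf, i, "psi", delta[k])
    }
  }
  move_result(conf, "goal_step")
}

# dispatch a schema-sampled move kind onto a subset
apply_schema_move <- function(conf, subset, kind, energy_fn) {
  p <- subset$params
  get_par <- function(name, default) {
    if (!is.null(p[[name]])) p[[name]] else default
  }
  switch(kind,
    dihedral = dihedral_perturbation(conf, subset$residues,
                                     max_delta = get_par("max_delta", 10),
                                     subset_id = subset$id),
    loop = multi_loop_sample(conf, subset$residues,
                             tol = get_par("tol", 0.08),
                             max_iter = get_par("max_iter", 200L),
                             subset_id = subset$id),
    rigid = {
      runs <- contiguous_runs(subset$residues)
      run <- runs[[sample.int(length(runs), 1L)]]
      rigid_body_move(conf, run,
                      max_disp = get_par("max_disp", 1.0),
                      max_rot = get_par("max_rot", 5),
                      tol = get_par("tol", 0.08),
                      max_iter = get_par("max_iter", 200L),
                      subset_id = subset$id)
    },
    minimize = minimization_move(conf, energy_fn, subset = subset$residues,
                                 max_iters = get_par("max_iters", 10L),
                                 subset_id = subset$id),
    stop("unknown move kind '", kind, "'")
  )
}

#' Extract the root-to-node path from an exploration tree
#'
#' @param tree An `exploration_tree`.
#' @param id Node id (defaults to the solution node if the run was
#'   directed and reached the goal, else the last node).
#' @return Object of class `conformation_path`: a list of conformations
#'   from root to node, with node ids and move kinds as attributes.
#' @export
extract_path <- function(tree, id = NULL) {
  if (is.null(id)) {
    id <- if (!is.na(tree$solution)) tree$solution else length(tree$nodes)
  }
  if (id < 1L || id > length(tree$nodes)) stop("unknown node id ", id)
  ids <- integer(0L)
  cur <- id
  while (!is.na(cur)) {
    ids <- c(cur, ids)
    cur <- tree$nodes[[cur]]$parent
  }
  structure(lapply(ids, function(i) tree$nodes[[i]]$conformation),
            ids = ids,
            kinds = vapply(ids, function(i) tree$nodes[[i]]$kind,
                           character(1L)),
            class = "conformation_path")
}

#' @export
print.exploration_tree <- function(x, ...) {
  cat("<exploration_tree> ", length(x$nodes), " nodes, ",
      length(x$grid$keys), " non-empty cells, ", x$iterations,
      " iterations\n", sep = "")
  if (!is.null(x$config$goal)) {
    cat("  directed search: ",
        if (!is.na(x$solution)) paste0("goal reached at node ", x$solution)
        else "goal not reached", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.exploration_tree <- function(object, ...) {
  e <- vapply(object$nodes, `[[`, numeric(1L), "energy")
  kinds <- vapply(object$nodes, `[[`, character(1L), "kind")
  out <- list(n_nodes = length(object$nodes),
              n_cells = length(object$grid$keys),
              n_exterior = sum(grid_exterior_flags(object$grid)),
              energy = summary(e), moves = table(kinds),
              iterations = object$iterations, solution = object$solution)
  class(out) <- "summary.exploration_tree"
  out
}

#' @export
print.summary.exploration_tree <- function(x, ...) {
  cat("Exploration tree: ", x$n_nodes, " nodes over ", x$iterations,
      " iterations\n", sep = "")
  cat("Grid: ", x$n_cells, " cells (", x$n_exterior, " exterior)\n",
      sep = "")
  cat("Node energies:\n"); print(x$energy)
  cat("Generating moves:\n"); print(x$moves)
  invisible(x)
}

#' Plot the projected footprint of an exploration tree
#'
#' Scatter of node projections in the planner's 2D projection space,
#' colored by energy; parent-child edges drawn in grey.
#'
#' @param x An `exploration_tree`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.exploration_tree <- function(x, ...) {
  pts <- do.call(rbind, lapply(x$nodes, `[[`, "point"))
  e <- vapply(x$nodes, `[[`, numeric(1L), "energy")
  graphics::plot(pts, xlab = "projection 1", ylab = "projection 2",
                 type = "n", ...)
  for (nd in x$nodes) {
    if (!is.na(nd$parent)) {
      p <- x$nodes[[nd$parent]]$point
      graphics::segments(p[1L], p[2L], nd$point[1L], nd$point[2L],
                         col = "grey80")
    }
  }
  pal <- grDevices::hcl.colors(100L, "viridis")
  col <- pal[cut(e, 100L, labels = FALSE)]
  if (all(!is.finite(e)) || diff(range(e)) < 1e-12) col <- pal[1L]
  graphics::points(pts, pch = 16L, cex = 0.6, col = col)
  invisible(x)
}

#' Write / read a tree archive as JSON lines
#'
#' One node per line: id, parent, move kind, subset id, energy, dihedral
#' vector, projected point. The sequence and geometry ride on a header
#' line so a tree can be rebuilt without the originating session.
#'
#' @param tree An `exploration_tree`.
#' @param path Output file.
#' @return `path` invisibly (write); a list with `header` and `nodes`
#'   data (read).
#' @export
write_tree <- function(tree, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  root <- tree$nodes[[1L]]$conformation
  header <- list(type = "header",
                 sequence = paste(root$sequence, collapse = ""),
                 cell_size = tree$grid$size,
                 projection_seed = tree$projection$seed,
                 solution = tree$solution)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              na = "null"), con)
  for (nd in tree$nodes) {
    rec <- list(id = nd$id, parent = nd$parent, kind = nd$kind,
                subset_id = nd$subset_id, energy = nd$energy,
                phi = nd$conformation$phi, psi = nd$conformation$psi,
                point = nd$point)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  nodes <- lapply(lines[-1L], jsonlite::fromJSON)
  list(header = header, nodes = nodes)
}
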