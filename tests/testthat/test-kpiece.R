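test_that("projection construction is orthonormal and seed-deterministic", {
  for (n in c(1L, 10L, 500L)) {
    p <- make_projection(n, seed = 5)
    expect_equal(dim(p$m), c(2L, 2L * n))
    expect_lt(abs(sum(p$m[1L, ]^2) - 1), 1e-10)
    expect_lt(abs(sum(p$m[2L, ]^2) - 1), 1e-10)
    expect_lt(abs(sum(p$m[1L, ] * p$m[2L, ])), 1e-10)
  }
  expect_identical(make_projection(10L, 5)$m, make_projection(10L, 5)$m)
  expect_false(identical(make_projection(10L, 5)$m,
                         make_projection(10L, 6)$m))
  expect_error(make_projection(0L, 1), ">= 1")
})

test_that("projection maps the cos/sin encoding linearly", {
  p <- make_projection(4L, seed = 9)
  # all angles zero: v = (1, 0, 1, 0, ...)
  v0 <- rep(c(1, 0), 4L)
  expect_equal(project_point(p, rep(0, 4L)), as.vector(p$m %*% v0))
  # equal conformations project equally
  conf <- random_chain(3L, seed = 10)  # 4 defined dihedrals
  expect_identical(project_point(p, conf), project_point(p, conf))
  expect_error(project_point(p, rep(0, 5L)), "expected 4")
  # orthonormal rows make the map non-expansive in the encoded space
  set.seed(11)
  for (i in 1:20) {
    a <- runif(4L, -180, 180); b <- runif(4L, -180, 180)
    va <- as.vector(rbind(cospi(a / 180), sinpi(a / 180)))
    vb <- as.vector(rbind(cospi(b / 180), sinpi(b / 180)))
    d_proj <- sqrt(sum((project_point(p, a) - project_point(p, b))^2))
    expect_lte(d_proj, sqrt(sum((va - vb)^2)) + 1e-12)
  }
})

test_that("cell indexing uses half-open floor cells", {
  expect_identical(cell_index(c(0, 0), 1), c(0L, 0L))
  expect_identical(cell_index(c(-0.5, 0.5), 1), c(-1L, 0L))
  expect_identical(cell_index(c(1, 1), 1), c(1L, 1L))
  expect_error(cell_index(c(0, 0), 0), "> 0")
})

test_that("cell selection is inverse-density weighted with exterior bias", {
  # two isolated cells (both exterior), holding 1 and 3 nodes
  g <- confexplore:::new_density_grid(1)
  confexplore:::grid_insert(g, c(0.5, 0.5), 1L)
  for (id in 2:4) confexplore:::grid_insert(g, c(10.5, 0.5), id)
  set.seed(42)
  picks <- replicate(20000L, select_cell(g))
  counts <- table(picks)
  chi <- chisq.test(counts[c("0_0", "10_0")], p = c(0.75, 0.25))
  expect_gt(chi$p.value, 0.01)

  # single cell: always that cell
  g1 <- confexplore:::new_density_grid(1)
  confexplore:::grid_insert(g1, c(0, 0), 1L)
  expect_true(all(replicate(50L, select_cell(g1)) == "0_0"))
  expect_error(select_cell(confexplore:::new_density_grid(1)), "empty")

  # with both classes present, the exterior class is drawn with p_ext
  g2 <- confexplore:::new_density_grid(1)
  id <- 0L
  for (i in 0:2) for (j in 0:2) {
    id <- id + 1L
    confexplore:::grid_insert(g2, c(i + 0.5, j + 0.5), id)
  }
  flags <- confexplore:::grid_exterior_flags(g2)
  expect_identical(sum(!flags), 1L)  # the center cell is interior
  set.seed(43)
  picks2 <- replicate(20000L, select_cell(g2, p_ext = 0.6))
  ext_freq <- mean(flags[picks2])
  chi2 <- chisq.test(table(flags[picks2]), p = c(0.4, 0.6))
  expect_gt(chi2$p.value, 0.01)
})

test_that("interior/exterior bookkeeping matches brute-force recount", {
  set.seed(44)
  g <- confexplore:::new_density_grid(0.5)
  pts <- matrix(rnorm(400, sd = 1.2), ncol = 2L)
  for (i in seq_len(nrow(pts))) confexplore:::grid_insert(g, pts[i, ], i)
  counts <- confexplore:::grid_cell_counts(g)
  expect_identical(sum(counts), nrow(pts))
  # recount from scratch
  keys <- apply(floor(pts / 0.5), 1L, function(cc) paste0(cc[1], "_", cc[2]))
  expect_identical(unname(counts[names(counts)]),
                   unname(as.integer(table(keys)[names(counts)])))
  # brute-force 8-neighbor reclassification
  flags <- confexplore:::grid_exterior_flags(g)
  for (k in names(flags)) {
    cc <- as.integer(strsplit(k, "_")[[1L]])
    nbr <- expand.grid(dx = -1:1, dy = -1:1)
    nbr <- nbr[!(nbr$dx == 0 & nbr$dy == 0), ]
    nkeys <- paste0(cc[1L] + nbr$dx, "_", cc[2L] + nbr$dy)
    expect_identical(unname(flags[k]), any(!nkeys %in% names(counts)))
  }
})

test_that("planner honors the energy threshold and records provenance", {
  toy <- make_hinge_toy()
  sch <- auto_schema(toy$ss)
  cfg <- planner_config(threshold = toy$threshold, budget = 400L, seed = 3L)
  tree <- explore(toy$start, sch, clash_energy, cfg)
  e <- vapply(tree$nodes, `[[`, numeric(1L), "energy")
  expect_true(all(e <= toy$threshold))
  # recomputed energies agree with the cached ones
  for (nd in tree$nodes[seq(1L, length(tree$nodes), by = 7L)]) {
    expect_equal(clash_energy(nd$conformation), nd$energy)
  }
  # parent links are well-formed and each node's cell matches its point
  for (nd in tree$nodes) {
    if (nd$kind == "root") expect_true(is.na(nd$parent))
    else expect_true(nd$parent >= 1L && nd$parent < nd$id)
    expect_identical(nd$cell, cell_index(nd$point, tree$grid$size))
  }
  # grid bookkeeping equals a recount over nodes
  counts <- confexplore:::grid_cell_counts(tree$grid)
  expect_identical(sum(counts), length(tree$nodes))

  # budget 0 gives a root-only tree
  cfg0 <- planner_config(threshold = toy$threshold, budget = 0L, seed = 3L)
  expect_length(explore(toy$start, sch, clash_energy, cfg0)$nodes, 1L)

  # infeasible start is rejected with the offending energy
  strict <- planner_config(threshold = -1, budget = 10L, seed = 1L)
  expect_error(explore(toy$start, sch, clash_energy, strict), "threshold")
})

test_that("identical seeds reproduce the tree node for node", {
  toy <- make_hinge_toy()
  sch <- auto_schema(toy$ss)
  cfg <- planner_config(threshold = toy$threshold, budget = 250L, seed = 11L)
  t1 <- explore(toy$start, sch, clash_energy, cfg)
  t2 <- explore(toy$start, sch, clash_energy, cfg)
  expect_identical(length(t1$nodes), length(t2$nodes))
  for (i in seq_along(t1$nodes)) {
    expect_identical(t1$nodes[[i]]$conformation$xyz,
                     t2$nodes[[i]]$conformation$xyz)
    expect_identical(t1$nodes[[i]]$kind, t2$nodes[[i]]$kind)
    expect_identical(t1$nodes[[i]]$parent, t2$nodes[[i]]$parent)
  }
})

test_that("coverage grows with iterations on the undirected toy search", {
  toy <- make_hinge_toy()
  sch <- auto_schema(toy$ss)
  c500 <- planner_config(threshold = toy$threshold, budget = 500L, seed = 5L)
  c5000 <- planner_config(threshold = toy$threshold, budget = 5000L,
                          seed = 5L)
  n500 <- length(explore(toy$start, sch, clash_energy, c500)$grid$keys)
  n5000 <- length(explore(toy$start, sch, clash_energy, c5000)$grid$keys)
  expect_gt(n5000, n500)
})

test_that("paths follow parent links with recorded moves", {
  toy <- make_hinge_toy()
  sch <- auto_schema(toy$ss)
  cfg <- planner_config(threshold = toy$threshold, budget = 300L, seed = 13L)
  tree <- explore(toy$start, sch, clash_energy, cfg)
  p <- extract_path(tree, 1L)
  expect_length(p, 1L)
  last <- length(tree$nodes)
  path <- extract_path(tree, last)
  ids <- attr(path, "ids")
  expect_identical(ids[length(ids)], last)
  expect_identical(ids[1L], 1L)
  # depth + 1 equals path length
  depth <- 0L; cur <- last
  while (!is.na(tree$nodes[[cur]]$parent)) {
    depth <- depth + 1L; cur <- tree$nodes[[cur]]$parent
  }
  expect_length(path, depth + 1L)
  expect_error(extract_path(tree, 10 * last), "unknown")
})

test_that("tree archives round trip through JSON lines", {
  toy <- make_hinge_toy()
  cfg <- planner_config(threshold = toy$threshold, budget = 60L, seed = 2L)
  tree <- explore(toy$start, auto_schema(toy$ss), clash_energy, cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_identical(back$header$sequence,
                   paste(toy$start$sequence, collapse = ""))
  expect_length(back$nodes, length(tree$nodes))
  nd <- back$nodes[[length(back$nodes)]]
  orig <- tree$nodes[[length(tree$nodes)]]
  expect_equal(nd$energy, orig$energy)
  expect_equal(nd$phi[-1L], orig$conformation$phi[-1L])
})
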