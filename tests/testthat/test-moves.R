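test_that("dihedral perturbation touches only the declared subset", {
  conf <- random_chain(10L, seed = 71)
  set.seed(1)
  res <- dihedral_perturbation(conf, subset = 5L, max_delta = 20)
  expect_true(res$success)
  out <- res$conformation
  expect_identical(out$phi[-5L], conf$phi[-5L])
  expect_identical(out$psi[-5L], conf$psi[-5L])
  expect_false(out$phi[5L] == conf$phi[5L])
  # upstream coordinates are bit-identical (edits are in-place rotations)
  expect_identical(out$xyz[1:13, ], conf$xyz[1:13, ])

  # max_delta = 0 is the identity
  id <- dihedral_perturbation(conf, subset = 1:10, max_delta = 0)
  expect_equal(id$conformation$xyz, conf$xyz)
  # empty subset fails gracefully
  expect_false(dihedral_perturbation(conf, integer(0))$success)
})

test_that("perturbation deltas are uniform on [-max_delta, max_delta]", {
  conf <- random_chain(10L, seed = 72)
  set.seed(42)
  deltas <- replicate(10000L, {
    r <- dihedral_perturbation(conf, subset = 5L, max_delta = 15)
    wrap_angle(r$conformation$phi[5L] - conf$phi[5L])
  })
  ks <- suppressWarnings(ks.test(deltas, "punif", -15, 15))
  expect_gt(ks$p.value, 0.01)
})

test_that("moves preserve ideal bond geometry and kinematic consistency", {
  conf <- random_chain(12L, seed = 73)
  g <- ideal_geometry()
  set.seed(2)
  results <- list(
    dihedral_perturbation(conf, 3:6, max_delta = 30),
    loop_sample(conf, c(4L, 8L)),
    rigid_body_move(conf, c(4L, 8L))
  )
  for (res in results) {
    out <- res$conformation
    bl <- sqrt(rowSums((out$xyz[-1L, ] - out$xyz[-nrow(out$xyz), ])^2))
    expect_lt(max(abs(bl - rep_len(c(g$b_n_ca, g$b_ca_c, g$b_c_n),
                                   length(bl)))), 1e-6)
    # stored dihedrals match the coordinates, and rebuilding reproduces
    # the structure up to a rigid transform
    d <- extract_dihedrals(out)
    expect_lt(max(wrapdiff(d$phi[-1L], out$phi[-1L])), 1e-5)
    rebuilt <- build_backbone(out$sequence, d$phi, d$psi)
    expect_lt(superpose_rmsd(rebuilt, out, atoms = "all")$rmsd, 1e-6)
  }
})

test_that("CCD closes back to recorded anchors and reports diagnostics", {
  conf <- random_chain(15L, seed = 74)
  targets <- conf$xyz[confexplore:::anchor_indices(10L), ]
  # anchors already on target: success in zero sweeps, untouched
  res0 <- ccd_close(conf, c(5L, 10L), targets)
  expect_true(res0$success)
  expect_identical(res0$diagnostics$sweeps, 0L)
  expect_identical(res0$conformation$xyz, conf$xyz)

  # a solvable problem: perturb the loop, close back
  set.seed(3)
  trial <- conf
  for (i in 5:10) {
    trial <- confexplore:::set_dihedral(trial, i, "phi", runif(1, -180, 180))
    trial <- confexplore:::set_dihedral(trial, i, "psi", runif(1, -180, 180))
  }
  res <- ccd_close(trial, c(5L, 10L), targets, max_iter = 2000L)
  expect_true(res$success)
  expect_lte(res$diagnostics$deviation, 0.08)
  # dihedral bookkeeping stays consistent with coordinates
  d <- extract_dihedrals(res$conformation)
  expect_lt(max(wrapdiff(d$phi[-1L], res$conformation$phi[-1L])), 1e-5)

  # unreachable targets: graceful failure, input returned
  far <- targets + 100
  bad <- ccd_close(trial, c(5L, 10L), far, max_iter = 50L)
  expect_false(bad$success)
  expect_identical(bad$conformation$xyz, trial$xyz)

  expect_error(ccd_close(conf, c(12L, 15L), targets), "outside")
})

test_that("loop sampling keeps endpoints and everything outside fixed", {
  conf <- random_chain(15L, seed = 75)
  anchors <- conf$xyz[confexplore:::anchor_indices(9L), ]
  set.seed(4)
  got <- NULL
  for (k in 1:20) { # closure of a random loop can fail; take first success
    res <- loop_sample(conf, c(5L, 9L))
    if (res$success) { got <- res; break }
  }
  expect_false(is.null(got))
  out <- got$conformation
  expect_identical(out$phi[-(5:9)], conf$phi[-(5:9)])
  expect_identical(out$psi[-(5:9)], conf$psi[-(5:9)])
  expect_lte(confexplore:::anchor_rms(out, 9L, anchors), 0.08)
  # upstream atoms bit-identical
  expect_identical(out$xyz[1:12, ], conf$xyz[1:12, ])
  # downstream atoms ride rigidly with the anchor frame: displacement is
  # bounded by the residual deviation amplified by the lever arm from the
  # anchors (far below the ~10 A an unconstrained random loop would give)
  down <- 31:45
  lever <- max(sqrt(rowSums(sweep(conf$xyz[down, ], 2L,
                                  colMeans(anchors))^2)))
  r_anc <- sqrt(mean(rowSums(sweep(anchors, 2L, colMeans(anchors))^2)))
  expect_lt(max(abs(out$xyz[down, ] - conf$xyz[down, ])),
            0.08 * (1 + lever / r_anc))
  # internal geometry of the downstream segment is untouched
  expect_equal(as.vector(dist(out$xyz[down, ])),
               as.vector(dist(conf$xyz[down, ])), tolerance = 1e-6)

  # different draws give different loops
  set.seed(5)
  r1 <- loop_sample(conf, c(5L, 9L))
  set.seed(6)
  r2 <- loop_sample(conf, c(5L, 9L))
  expect_false(identical(r1$conformation$phi, r2$conformation$phi))

  # too-short loop and terminal loop fail gracefully
  expect_false(loop_sample(conf, c(5L, 6L))$success)
  expect_false(loop_sample(conf, c(13L, 15L))$success)
})

test_that("rigid-body moves transport the downstream domain rigidly", {
  conf <- random_chain(15L, seed = 76)
  set.seed(7)
  got <- NULL
  for (k in 1:20) {
    res <- rigid_body_move(conf, c(5L, 9L), max_disp = 0.5, max_rot = 4)
    if (res$success) { got <- res; break }
  }
  expect_false(is.null(got))
  out <- got$conformation
  # upstream untouched
  expect_identical(out$xyz[1:12, ], conf$xyz[1:12, ])
  # downstream displaced by the recorded transform within tolerance
  dg <- got$diagnostics
  anchors <- conf$xyz[confexplore:::anchor_indices(9L), ]
  center <- colMeans(anchors)
  down <- 31:45
  expected <- confexplore:::rotate_points(conf$xyz[down, ], center, dg$axis,
                                          dg$angle)
  expected <- sweep(expected, 2L, dg$translation, "+")
  lever <- max(sqrt(rowSums(sweep(conf$xyz[down, ], 2L, center)^2)))
  r_anc <- sqrt(mean(rowSums(sweep(anchors, 2L, center)^2)))
  expect_lt(max(abs(out$xyz[down, ] - expected)), 0.08 * (1 + lever / r_anc))

  # zero transform: success, conformation unchanged
  null_res <- rigid_body_move(conf, c(5L, 9L), max_disp = 0, max_rot = 0)
  expect_true(null_res$success)
  expect_equal(null_res$conformation$xyz, conf$xyz, tolerance = 1e-9)
})

test_that("minimization move always succeeds and never raises energy", {
  conf <- random_chain(10L, seed = 77)
  e0 <- clash_energy(conf)
  res <- minimization_move(conf)
  expect_true(res$success)
  expect_lte(res$conformation$energy, e0)
  # an already perfect conformation is left alone
  flat <- extended_chain(8L)
  res2 <- minimization_move(flat)
  expect_identical(res2$conformation$xyz, flat$xyz)
})

test_that("multi-loop sampling closes every region or rolls back", {
  conf <- random_chain(24L, seed = 78)
  set.seed(8)
  got <- NULL
  for (k in 1:30) {
    res <- multi_loop_sample(conf, c(4:7, 14:17))
    if (res$success) { got <- res; break }
  }
  expect_false(is.null(got))
  out <- got$conformation
  outside <- setdiff(seq_len(24L), c(4:7, 14:17))
  expect_identical(out$phi[outside], conf$phi[outside])
  expect_identical(out$psi[outside], conf$psi[outside])
})
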