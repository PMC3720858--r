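# shared fixture builders: everything is generated in code at test time

# random chain with uniform dihedrals; terminal angles NA
random_chain <- function(nres, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- c(NA, runif(nres - 1L, -180, 180))
  psi <- c(runif(nres - 1L, -180, 180), NA)
  build_backbone(paste(rep("A", nres), collapse = ""), phi, psi)
}

extended_chain <- function(nres) {
  build_backbone(paste(rep("A", nres), collapse = ""),
                 phi = c(NA, rep(180, nres - 1L)),
                 psi = c(rep(180, nres - 1L), NA))
}

# brute-force O(n^2) clash energy, independent of the compiled kernel
clash_energy_bruteforce <- function(conf, params = energy_params()) {
  xyz <- conf$xyz
  m <- nrow(xyz)
  contact <- 2 * params$sigma
  e <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (j - i <= params$exclude_bonds) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < contact && d <= params$cutoff) e <- e + params$k * (contact - d)^2
    }
  }
  e
}

# mean absolute wrapped angular difference helper used across tests
wrapdiff <- function(a, b) {
  d <- (a - b) %% 360
  d <- ifelse(!is.na(d) & d > 180, d - 360, d)
  abs(d)
}

rigid_transform <- function(conf, axis = c(1, 1, 0), angle = 35,
                            shift = c(3, -2, 7)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  conf$xyz <- sweep(conf$xyz %*% R, 2L, shift, "+")
  conf
}
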