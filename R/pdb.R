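#' Read a backbone conformation from a PDB file
#'
#' Parses ATOM records (via bio3d), keeps the first model of the first
#' chain, requires exactly one N, CA and C per residue in chain order, and
#' populates both coordinates and extracted dihedrals. Insertion codes and
#' alternate locations beyond 'A' are rejected as an unsupported dialect.
#'
#' @param path Path to a PDB file.
#' @return A `conformation`.
#' @export
read_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported")
  }
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  ch <- at$chain[1L]
  at <- at[is.na(at$chain) | at$chain == ch, , drop = FALSE]
  resnos <- unique(at$resno)
  n <- length(resnos)
  xyz <- matrix(NA_real_, 3L * n, 3L)
  seq1 <- character(n)
  for (i in seq_len(n)) {
    ri <- at[at$resno == resnos[i], , drop = FALSE]
    for (k in seq_along(c("N", "CA", "C"))) {
      nm <- c("N", "CA", "C")[k]
      row <- ri[ri$elety == nm, , drop = FALSE]
      if (nrow(row) < 1L) {
        stop("residue ", resnos[i], " is missing backbone atom ", nm)
      }
      xyz[a_idx(i, k), ] <- as.numeric(row[1L, c("x", "y", "z")])
    }
    seq1[i] <- bio3d::aa321(ri$resid[1L])
  }
  shell <- structure(list(sequence = seq1, xyz = xyz), class = "conformation")
  d <- extract_dihedrals(shell)
  conformation(seq1, phi = d$phi, psi = d$psi, xyz = xyz)
}

#' Write a conformation as PDB ATOM records
#'
#' One chain, serial numbers from 1, residues numbered from 1. A
#' write-then-read round trip reproduces coordinates to the PDB format
#' precision (1e-3 Angstrom).
#'
#' @param conf A `conformation` with coordinates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conf, path) {
  if (is.null(conf$xyz)) stop("conformation has no coordinates")
  n <- n_residues(conf)
  resid3 <- bio3d::aa123(conf$sequence)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(conf$xyz)),
                   type = rep("ATOM", 3L * n),
                   resno = rep(seq_len(n), each = 3L),
                   resid = rep(resid3, each = 3L),
                   eleno = seq_len(3L * n),
                   elety = rep(c("N", "CA", "C"), n),
                   chain = rep("A", 3L * n))
  invisible(path)
}
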