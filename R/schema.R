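#' A residue subset with a selection weight and a move distribution
#'
#' Subsets are the units a move is addressed to: a named, possibly
#' non-contiguous set of residue indices, a nonnegative selection weight,
#' a probability distribution over move kinds, and optional per-move
#' parameter overrides (e.g. `max_delta`, `max_disp`, `max_rot`).
#'
#' @param id Character label, unique within a schema.
#' @param residues Integer vector of 1-based residue indices.
#' @param weight Nonnegative selection weight.
#' @param moves Named numeric vector of move-kind probabilities over
#'   `"dihedral"`, `"loop"`, `"rigid"`, `"minimize"`; must sum to 1.
#' @param params Named list of move parameter overrides.
#' @return Object of class `residue_subset`.
#' @export
residue_subset <- function(id, residues, weight = 1,
                           moves = c(dihedral = 1/3, loop = 1/3, rigid = 1/3),
                           params = list()) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L) stop("subset '", id, "' has no residues")
  if (!is.numeric(weight) || weight < 0) stop("weight must be >= 0")
  known <- c("dihedral", "loop", "rigid", "minimize")
  if (is.null(names(moves)) || !all(names(moves) %in% known)) {
    stop("move kinds must be among: ", paste(known, collapse = ", "))
  }
  if (any(moves < 0) || abs(sum(moves) - 1) > 1e-8) {
    stop("move distribution of subset '", id, "' must sum to 1")
  }
  structure(list(id = as.character(id), residues = residues,
                 weight = weight, moves = moves, params = params),
            class = "residue_subset")
}

#' A schema: weighted residue subsets with per-subset move distributions
#'
#' @param subsets List of [residue_subset()] objects.
#' @param probabilities Optional numeric vector of subset-selection
#'   probabilities (one per subset). If omitted, weights are normalized.
#'   Probabilities not summing to 1 are renormalized with a warning.
#' @return Object of class `schema`.
#' @export
schema <- function(subsets, probabilities = NULL) {
  if (length(subsets) == 0L) stop("a schema needs at least one subset")
  if (!all(vapply(subsets, inherits, logical(1L), "residue_subset"))) {
    stop("all subsets must be residue_subset objects")
  }
  ids <- vapply(subsets, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate subset ids")
  if (is.null(probabilities)) {
    w <- vapply(subsets, `[[`, numeric(1L), "weight")
    if (sum(w) <= 0) stop("all subset weights are zero")
    probabilities <- w / sum(w)
  } else {
    if (length(probabilities) != length(subsets)) {
      stop("one probability per subset required")
    }
    if (any(probabilities < 0)) stop("negative subset probability")
    s <- sum(probabilities)
    if (s <= 0) stop("subset probabilities sum to zero")
    if (abs(s - 1) > 1e-8) {
      warning("subset probabilities sum to ", format(s),
              "; renormalizing")
      probabilities <- probabilities / s
    }
  }
  names(probabilities) <- ids
  structure(list(subsets = stats::setNames(subsets, ids),
                 probabilities = probabilities), class = "schema")
}

#' @export
print.schema <- function(x, ...) {
  cat("<schema> ", length(x$subsets), " subsets\n", sep = "")
  for (i in seq_along(x$subsets)) {
    s <- x$subsets[[i]]
    cat(sprintf("  %-12s p=%.4f  %d residues  moves: %s\n", s$id,
                x$probabilities[i], length(s$residues),
                paste(sprintf("%s=%.3f", names(s$moves), s$moves),
                      collapse = " ")))
  }
  invisible(x)
}

#' Automatic schema from a secondary-structure annotation
#'
#' One subset per maximal run of the same secondary-structure label, with
#' sampling weight 1.0 for loops (L), 0.2 for sheets (E) and 0.1 for
#' helices (H), plus the all-residue subset selected with fixed
#' probability 0.09; the remaining 0.91 is split over the element subsets
#' proportional to weight. Element subsets draw dihedral, loop and
#' rigid-body moves with equal probability. The all-residue subset's
#' internal distribution is \{minimize 1/9, dihedral 8/27, loop 8/27,
#' rigid 8/27\}, so that the unconditional whole-protein minimization
#' frequency is exactly 1% while whole-protein perturbations remain
#' available.
#'
#' @param ss Character: per-residue labels in \{H, E, L\}, as a single
#'   string or a character vector.
#' @param all_prob Selection probability of the all-residue subset.
#' @param weights Named weights per label.
#' @return A `schema`.
#' @examples
#' auto_schema("LLLLHHHHEEEE")
#' @export
auto_schema <- function(ss, all_prob = 0.09,
                        weights = c(L = 1.0, E = 0.2, H = 0.1)) {
  if (length(ss) == 1L && nchar(ss[1L]) != 1L) {
    ss <- strsplit(ss, "", fixed = TRUE)[[1L]]
  }
  n <- length(ss)
  if (n < 1L) stop("empty annotation")
  if (!all(ss %in% c("H", "E", "L"))) {
    stop("annotation labels must be H, E or L")
  }
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  subsets <- vector("list", length(r$values))
  w <- numeric(length(r$values))
  for (k in seq_along(r$values)) {
    lab <- r$values[k]
    subsets[[k]] <- residue_subset(
      id = sprintf("%s%d_%d-%d", lab, k, starts[k], ends[k]),
      residues = starts[k]:ends[k], weight = weights[[lab]])
    w[k] <- weights[[lab]]
  }
  all_moves <- c(dihedral = 8 / 27, loop = 8 / 27, rigid = 8 / 27,
                 minimize = 1 / 9)
  subsets[[length(subsets) + 1L]] <- residue_subset(
    id = "all", residues = seq_len(n), weight = 0, moves = all_moves)
  probs <- c((1 - all_prob) * w / sum(w), all_prob)
  schema(subsets, probabilities = probs)
}

#' Sample a (subset, move kind) pair from a schema
#'
#' Draws a subset by its selection probability, then a move kind from
#' that subset's distribution. Consumes the session RNG; fix a seed for
#' a reproducible sequence.
#'
#' @param sch A `schema`.
#' @return List with `subset_id` and `kind`.
#' @export
sample_move <- function(sch) {
  i <- sample.int(length(sch$subsets), 1L, prob = sch$probabilities)
  s <- sch$subsets[[i]]
  kind <- sample(names(s$moves), 1L, prob = s$moves)
  list(subset_id = s$id, kind = kind)
}

#' Load a schema from a YAML or JSON config file
#'
#' The file holds a list of subset entries:
#' `{id, residues: "45-55,87-91", weight or probability, moves: {kind: prob},
#' params: {...}}`. Residue ranges are 1-based inclusive. If any entry
#' carries `probability`, all must; probabilities not summing to 1 are
#' renormalized with a warning.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `schema`.
#' @export
load_schema <- function(path) {
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    stop("cannot parse schema config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  entries <- if (!is.null(raw$subsets)) raw$subsets else raw
  if (length(entries) == 0L) stop("schema config '", path, "' has no subsets")
  has_prob <- vapply(entries, function(e) !is.null(e$probability), logical(1L))
  if (any(has_prob) && !all(has_prob)) {
    stop("either all or none of the subsets may carry 'probability'")
  }
  subsets <- lapply(entries, function(e) {
    if (is.null(e$id)) stop("schema entry without an id")
    if (is.null(e$residues)) stop("subset '", e$id, "' has no residues")
    moves <- if (is.null(e$moves)) {
      c(dihedral = 1 / 3, loop = 1 / 3, rigid = 1 / 3)
    } else {
      unlist(e$moves)
    }
    residue_subset(e$id, parse_ranges(e$residues),
                   weight = if (is.null(e$weight)) 1 else e$weight,
                   moves = moves / sum(moves),
                   params = if (is.null(e$params)) list() else e$params)
  })
  probs <- if (all(has_prob)) {
    vapply(entries, function(e) as.numeric(e$probability), numeric(1L))
  } else NULL
  schema(subsets, probabilities = probs)
}

#' Save a schema to a YAML config file
#' @param sch A `schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_schema <- function(sch, path) {
  entries <- lapply(seq_along(sch$subsets), function(i) {
    s <- sch$subsets[[i]]
    list(id = s$id, residues = format_ranges(s$residues),
         probability = unname(sch$probabilities[i]),
         moves = as.list(s$moves), params = s$params)
  })
  yaml::write_yaml(list(subsets = entries), path, precision = 15L)
  invisible(path)
}

#' Validate a schema against a chain length
#'
#' Flags residues outside `1..n_residues` and degenerate distributions.
#'
#' @param sch A `schema`.
#' @param n_residues Residue count of the protein the schema targets.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_schema <- function(sch, n_residues) {
  for (s in sch$subsets) {
    bad <- s$residues[s$residues < 1L | s$residues > n_residues]
    if (length(bad) > 0L) {
      stop("subset '", s$id, "' references residues outside 1..",
           n_residues, ": ", paste(bad, collapse = ", "))
    }
  }
  if (abs(sum(sch$probabilities) - 1) > 1e-8) {
    stop("subset probabilities do not sum to 1")
  }
  invisible(TRUE)
}

# "45-55,87-91" or list/vector of ranges -> integer vector
parse_ranges <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- paste(unlist(x), collapse = ",")
  parts <- strsplit(gsub("[[:space:]]", "", x), ",", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty residue range")
  out <- integer(0L)
  for (p in parts) {
    if (grepl("^\\d+-\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (ab[2L] < ab[1L]) stop("descending residue range: ", p)
      out <- c(out, ab[1L]:ab[2L])
    } else if (grepl("^\\d+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("malformed residue range: '", p, "'")
    }
  }
  out
}

format_ranges <- function(residues) {
  runs <- contiguous_runs(residues)
  paste(vapply(runs, function(r) {
    if (r[1L] == r[2L]) as.character(r[1L]) else paste0(r[1L], "-", r[2L])
  }, character(1L)), collapse = ",")
}
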