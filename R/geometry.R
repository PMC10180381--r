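#' Construct a molecular structure
#'
#' A `xyz_structure` is one cluster configuration: an ordered set of atoms
#' with chemical symbols and Cartesian coordinates in Angstrom.
#'
#' @param elements Character vector of chemical symbols (e.g. `"O"`, `"H"`).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param id Opaque structure label.
#' @param comment Free-text comment (retained verbatim in XYZ files).
#' @return An object of class `xyz_structure` with fields `id`, `elements`,
#'   `xyz`, `comment`.
#' @export
xyz_structure <- function(elements, xyz, id = "structure", comment = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(elements) < 1L)
    d4_abort("a structure needs at least one atom", "d4tune_domain_error")
  if (nrow(xyz) != length(elements))
    d4_abort("coordinate rows must match number of elements", "d4tune_domain_error")
  unknown <- setdiff(unique(elements), names(.atomic_masses))
  if (length(unknown))
    d4_abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")),
             "d4tune_format_error")
  if (!all(is.finite(xyz)))
    d4_abort("coordinates must be finite", "d4tune_domain_error")
  structure(list(id = as.character(id), elements = as.character(elements),
                 xyz = xyz, comment = as.character(comment)),
            class = "xyz_structure")
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure '%s': %d atoms (%s)>\n", x$id, length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " ")))
  invisible(x)
}

n_atoms <- function(s) length(s$elements)

# "id=foo rg=1.2" style comment tokens; unknown tokens are ignored.
.parse_comment_tokens <- function(comment) {
  toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1L))
}

#' Read structures from an XYZ file
#'
#' Parses plain or multi-frame XYZ: an atom-count line, a comment line, then
#' one `element x y z` record per atom. The comment line is retained
#' verbatim; a `id=<label>` token in it sets the structure id, otherwise ids
#' default to `frame_<k>` (0-based).
#'
#' @param file Path to an XYZ file, or a character vector of lines.
#' @return A list of [xyz_structure()] objects, one per frame.
#' @examples
#' s <- read_xyz(c("1", "id=lone", "O 0 0 0"))
#' s[[1]]$id
#' @export
read_xyz <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  # drop trailing blank lines only; blanks inside a frame are records
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      d4_abort(sprintf("frame %d: expected an atom count on line %d, got '%s'",
                       frame, i, lines[i]), "d4tune_format_error")
    if (i + 1L + nat > length(lines))
      d4_abort(sprintf(
        "frame %d: malformed file, %d atom records declared but only %d lines remain",
        frame, nat, length(lines) - i - 1L), "d4tune_format_error")
    comment <- lines[i + 1L]
    rec <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(fields, length, 0L) < 4L)
    if (length(bad))
      d4_abort(sprintf("frame %d: malformed atom record '%s'", frame, rec[bad[1L]]),
               "d4tune_format_error")
    el <- vapply(fields, `[[`, "", 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      d4_abort(sprintf("frame %d: non-numeric coordinates", frame),
               "d4tune_format_error")
    toks <- .parse_comment_tokens(comment)
    id <- if (!is.null(toks$id)) toks$id else sprintf("frame_%d", frame)
    out[[length(out) + 1L]] <- xyz_structure(el, xyz, id = id, comment = comment)
    i <- i + 2L + nat
    frame <- frame + 1L
  }
  out
}

#' Write structures to an XYZ file
#'
#' Emits multi-frame XYZ. If a structure's comment does not already carry an
#' `id=` token, one is prepended so that [read_xyz()] round-trips the id.
#'
#' @param structures A single [xyz_structure()] or a list of them.
#' @param file Output path.
#' @param digits Coordinate decimals printed (default 8).
#' @return `file`, invisibly.
#' @export
write_xyz <- function(structures, file, digits = 8) {
  if (inherits(structures, "xyz_structure")) structures <- list(structures)
  fmt <- sprintf("%%-2s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  con <- file(file, "w")
  on.exit(close(con))
  for (s in structures) {
    comment <- s$comment
    if (is.null(.parse_comment_tokens(comment)$id))
      comment <- trimws(paste(sprintf("id=%s", s$id), comment))
    writeLines(as.character(n_atoms(s)), con)
    writeLines(comment, con)
    writeLines(sprintf(fmt, s$elements, s$xyz[, 1], s$xyz[, 2], s$xyz[, 3]), con)
  }
  invisible(file)
}

#' Partition a water cluster into monomers
#'
#' Assigns every hydrogen to its nearest oxygen. A valid water cluster yields
#' exactly two hydrogens per oxygen, each within `oh_cutoff` of its oxygen;
#' anything else is an error naming the offending atoms. The cutoff default
#' (1.3 A) covers strongly distorted covalent O-H bonds (~0.96 A at
#' equilibrium) while staying well below the shortest hydrogen-bonded
#' H...O contacts (~1.6 A).
#'
#' @param s An [xyz_structure()] containing only O and H atoms.
#' @param oh_cutoff Maximum accepted O-H assignment distance, Angstrom.
#' @return An object of class `monomer_partition`: a list of integer vectors
#'   `c(O, H, H)` of atom indices, one per monomer.
#' @export
partition_monomers <- function(s, oh_cutoff = 1.3) {
  io <- which(s$elements == "O")
  ih <- which(s$elements == "H")
  if (length(io) + length(ih) != n_atoms(s))
    d4_abort("structure contains elements other than O and H",
             "d4tune_composition_error")
  if (length(ih) != 2L * length(io))
    d4_abort(sprintf("composition error: %d H for %d O (need exactly 2 H per O)",
                     length(ih), length(io)), "d4tune_composition_error")
  # nearest O for each H
  d2 <- outer(rowSums(s$xyz[ih, , drop = FALSE]^2),
              rowSums(s$xyz[io, , drop = FALSE]^2), `+`) -
    2 * s$xyz[ih, , drop = FALSE] %*% t(s$xyz[io, , drop = FALSE])
  nearest <- max.col(-d2, ties.method = "first")
  dist_oh <- sqrt(pmax(d2[cbind(seq_along(ih), nearest)], 0))
  too_far <- dist_oh > oh_cutoff
  if (any(too_far))
    d4_abort(sprintf(
      "partition failure: H atom(s) %s farther than %.3g A from any O",
      paste(ih[too_far], collapse = ", "), oh_cutoff), "d4tune_partition_error")
  counts <- tabulate(nearest, nbins = length(io))
  if (any(counts != 2L))
    d4_abort(sprintf(
      "partition failure: O atom(s) %s received %s H assignments (need 2)",
      paste(io[counts != 2L], collapse = ", "),
      paste(counts[counts != 2L], collapse = ", ")), "d4tune_partition_error")
  groups <- lapply(seq_along(io), function(k) {
    hs <- sort(ih[nearest == k])
    c(io[k], hs)
  })
  structure(groups, class = "monomer_partition")
}

#' Internal coordinates of one water monomer
#'
#' @param s An [xyz_structure()].
#' @param group Integer vector `c(O, H, H)` of atom indices.
#' @return Named numeric vector `r1`, `r2` (Angstrom) and `theta` (degrees).
#' @export
monomer_internals <- function(s, group) {
  o <- s$xyz[group[1L], ]
  h1 <- s$xyz[group[2L], ] - o
  h2 <- s$xyz[group[3L], ] - o
  r1 <- sqrt(sum(h1^2))
  r2 <- sqrt(sum(h2^2))
  ct <- sum(h1 * h2) / (r1 * r2)
  ct <- min(1, max(-1, ct))
  c(r1 = r1, r2 = r2, theta = acos(ct) * 180 / pi)
}

#' Radius of gyration of a structure
#'
#' Root-mean-square distance of the atoms from their (weighted) centroid,
#' used as a compactness proxy to order cluster configurations. The default
#' weighting is by standard atomic mass; `"oxygen"` uses the oxygen atoms
#' only (unweighted) and `"uniform"` weights all atoms equally.
#'
#' @param s An [xyz_structure()].
#' @param weighting One of `"mass"`, `"oxygen"`, `"uniform"`.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(s, weighting = c("mass", "oxygen", "uniform")) {
  weighting <- match.arg(weighting)
  if (weighting == "oxygen") {
    keep <- s$elements == "O"
    if (!any(keep)) keep <- rep(TRUE, n_atoms(s))
    xyz <- s$xyz[keep, , drop = FALSE]
    w <- rep(1, nrow(xyz))
  } else {
    xyz <- s$xyz
    w <- if (weighting == "mass") unname(.atomic_masses[s$elements])
         else rep(1, n_atoms(s))
  }
  com <- colSums(xyz * w) / sum(w)
  sq <- sweep(xyz, 2L, com)
  sqrt(sum(w * rowSums(sq^2)) / sum(w))
}

#' Order structures by radius of gyration
#'
#' Ascending (compact first), stable for ties: the sequencing used when
#' deviation profiles are reported configuration-by-configuration.
#'
#' @inheritParams radius_of_gyration
#' @param structures List of [xyz_structure()] objects.
#' @return The input list reordered.
#' @export
sort_by_gyration <- function(structures, weighting = "mass") {
  if (!length(structures)) return(structures)
  rg <- vapply(structures, radius_of_gyration, 0, weighting = weighting)
  structures[order(rg)]
}
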