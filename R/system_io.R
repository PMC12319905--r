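#' A single trajectory frame
#'
#' @param coordinates N x 3 numeric matrix, Angstrom. Coordinates may lie
#'   outside `[0, L)`; distance kernels wrap them internally.
#' @param box_lengths Length-3 positive numeric vector (orthorhombic box),
#'   Angstrom.
#' @param frame_index Integer index of the frame in its source trajectory.
#' @return An object of class `frame`.
#' @export
make_frame <- function(coordinates, box_lengths, frame_index = 1L) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  stopifnot(ncol(coordinates) == 3L)
  box_lengths <- as.numeric(box_lengths)
  if (length(box_lengths) != 3L || any(!is.finite(box_lengths)) ||
      any(box_lengths <= 0))
    stop("box_lengths must be 3 positive numbers (orthorhombic box)",
         call. = FALSE)
  structure(list(coordinates = coordinates, box_lengths = box_lengths,
                 frame_index = as.integer(frame_index)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("Frame %d: %d atoms, box %.4g x %.4g x %.4g A\n",
              x$frame_index, nrow(x$coordinates),
              x$box_lengths[1], x$box_lengths[2], x$box_lengths[3]))
  invisible(x)
}

parse_xyz_lattice <- function(comment) {
  # extended-XYZ: Lattice="ax ay az bx by bz cx cy cz"
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(m) == 0L) return(NULL)
  vals <- as.numeric(strsplit(trimws(gsub('^Lattice="|"$', "", m)), "\\s+")[[1L]])
  if (length(vals) != 9L || any(!is.finite(vals)))
    stop("malformed Lattice entry in XYZ comment line", call. = FALSE)
  M <- matrix(vals, 3, 3, byrow = TRUE)
  off <- M[row(M) != col(M)]
  if (any(abs(off) > 1e-9))
    stop("triclinic cells are not supported; Lattice must be diagonal (orthorhombic)",
         call. = FALSE)
  diag(M)
}

#' Read an (extended-)XYZ trajectory
#'
#' Plain multi-frame XYZ: each frame is an atom-count line, a comment line
#' (which in extended XYZ carries `Lattice="..."`), then one line per atom
#' `species x y z`. An orthorhombic (diagonal) lattice populates the frame
#' box; without a lattice entry, `box_lengths` must be supplied. Blank lines
#' between frames and trailing whitespace are tolerated.
#'
#' @param path Path to the trajectory file.
#' @param stride Keep every `stride`-th frame, starting from the first.
#' @param box_lengths Fallback box (length-3, Angstrom) for files whose
#'   comment lines carry no lattice.
#' @return A list of [make_frame()] objects (class `trajectory`). The species
#'   column of the file is attached to each frame as attribute
#'   `xyz_species` for cross-checking against a topology.
#' @export
read_xyz_trajectory <- function(path, stride = 1L, box_lengths = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0L)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]),
           call. = FALSE)
    if (i + 1L + nat > n_lines)
      stop(sprintf("line %d: frame truncated (%d atoms declared)", i, nat),
           call. = FALSE)
    comment <- lines[i + 1L]
    box <- parse_xyz_lattice(comment)
    if (is.null(box)) {
      if (is.null(box_lengths))
        stop("no Lattice in XYZ comment line and no box_lengths supplied",
             call. = FALSE)
      box <- box_lengths
    }
    frame_no <- frame_no + 1L
    keep <- ((frame_no - 1L) %% stride) == 0L
    if (keep) {
      atom_lines <- lines[(i + 2L):(i + 1L + nat)]
      tok <- strsplit(trimws(atom_lines), "\\s+")
      nt <- lengths(tok)
      if (any(nt < 4L))
        stop(sprintf("line %d: malformed atom line", i + 1L + which(nt < 4L)[1L]),
             call. = FALSE)
      sp <- vapply(tok, `[[`, "", 1L)
      xyz <- matrix(as.numeric(vapply(tok, function(t) t[2:4], character(3))),
                    ncol = 3L, byrow = TRUE)
      if (any(!is.finite(xyz)))
        stop(sprintf("non-numeric coordinate in frame %d", frame_no), call. = FALSE)
      fr <- make_frame(xyz, box, frame_no)
      attr(fr, "xyz_species") <- sp
      frames[[length(frames) + 1L]] <- fr
    }
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("no frames read from ", path, call. = FALSE)
  structure(frames, class = "trajectory")
}

#' Write frames as an extended-XYZ trajectory
#'
#' @param frames A `trajectory` (list of frames) or a single frame.
#' @param path Output path.
#' @param species Character vector of per-atom species labels (recycled
#'   across frames); defaults to each frame's `xyz_species` attribute.
#' @export
write_xyz_trajectory <- function(frames, path, species = NULL) {
  if (inherits(frames, "frame")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    sp <- species
    if (is.null(sp)) sp <- attr(fr, "xyz_species")
    n <- nrow(fr$coordinates)
    if (is.null(sp)) sp <- rep("X", n)
    stopifnot(length(sp) == n)
    b <- fr$box_lengths
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
      b[1], b[2], b[3]), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", sp,
                       fr$coordinates[, 1], fr$coordinates[, 2],
                       fr$coordinates[, 3]), con)
  }
  invisible(path)
}

#' Build a topology from per-atom vectors
#'
#' A topology assigns every atom a species label, a molecule id, a molecule
#' type and a partial charge. Atoms sharing a `molecule_id` must share one
#' `molecule_type`.
#'
#' @param species_label Character vector, one entry per atom.
#' @param molecule_id Integer vector; atoms of one molecule share an id.
#' @param molecule_type Character vector of molecule-type names.
#' @param charge Numeric partial charges (e); default 0.
#' @return A data.frame of class `topology` with columns `atom` (0-based
#'   index), `species_label`, `molecule_type`, `molecule_id`, `charge`.
#' @export
make_topology <- function(species_label, molecule_id, molecule_type,
                          charge = 0) {
  n <- length(species_label)
  stopifnot(length(molecule_id) == n, length(molecule_type) == n)
  charge <- rep_len(charge, n)
  top <- data.frame(atom = seq_len(n) - 1L,
                    species_label = as.character(species_label),
                    molecule_type = as.character(molecule_type),
                    molecule_id = as.integer(molecule_id),
                    charge = as.numeric(charge),
                    stringsAsFactors = FALSE)
  validate_topology(top)
  class(top) <- c("topology", "data.frame")
  top
}

validate_topology <- function(top) {
  if (anyDuplicated(top$atom))
    stop("duplicate atom index in topology", call. = FALSE)
  bad <- tapply(top$molecule_type, top$molecule_id,
                function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop("molecule_id spanning two molecule_types: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  invisible(top)
}

#' Read a topology file
#'
#' Structured text, one record per atom:
#' `index species_label molecule_type molecule_id charge`, `#` comments and
#' blank lines ignored. Indices are 0-based by default; pass
#' `one_based = TRUE` for 1-based files.
#'
#' @param path Path to the topology file.
#' @param one_based Are atom indices in the file 1-based?
#' @return A `topology` data.frame (see [make_topology()]).
#' @export
read_topology <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty topology file: ", path, call. = FALSE)
  tok <- strsplit(lines, "\\s+")
  if (any(lengths(tok) != 5L))
    stop("malformed topology record (need: index species molecule_type molecule_id charge)",
         call. = FALSE)
  m <- do.call(rbind, tok)
  idx <- as.integer(m[, 1L])
  if (one_based) idx <- idx - 1L
  if (anyDuplicated(idx)) stop("duplicate atom index in topology", call. = FALSE)
  ord <- order(idx)
  if (!identical(sort(idx), seq_along(idx) - 1L))
    stop("topology atom indices must be contiguous from ",
         if (one_based) "1" else "0", call. = FALSE)
  make_topology(species_label = m[ord, 2L],
                molecule_type = m[ord, 3L],
                molecule_id = as.integer(m[ord, 4L]),
                charge = as.numeric(m[ord, 5L]))
}

#' Write a topology file in the format of [read_topology()]
#'
#' @param top A `topology`.
#' @param path Output path.
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "topology"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# atom species_label molecule_type molecule_id charge_e (0-based indices)",
             con)
  writeLines(sprintf("%d %s %s %d %.10g", top$atom, top$species_label,
                     top$molecule_type, top$molecule_id, top$charge), con)
  invisible(path)
}

check_frame_topology <- function(frame, top) {
  if (nrow(frame$coordinates) != nrow(top))
    stop(sprintf("atom count mismatch: frame has %d atoms, topology %d",
                 nrow(frame$coordinates), nrow(top)), call. = FALSE)
  invisible(TRUE)
}

#' System composition of one frame under a topology
#'
#' @param topology A `topology`.
#' @param frame A `frame` with matching atom count.
#' @return An object of class `system_composition`: per-species atom counts
#'   `N`, per-molecule-type molecule counts, molecule-type mole fractions
#'   `x`, and box volume `V` (A^3).
#' @export
composition <- function(topology, frame) {
  stopifnot(inherits(topology, "topology"), inherits(frame, "frame"))
  check_frame_topology(frame, topology)
  N <- table(topology$species_label)
  mol <- unique(topology[, c("molecule_id", "molecule_type")])
  n_mol <- table(mol$molecule_type)
  structure(list(
    N = stats::setNames(as.integer(N), names(N)),
    molecules = stats::setNames(as.integer(n_mol), names(n_mol)),
    x = stats::setNames(as.numeric(n_mol) / sum(n_mol), names(n_mol)),
    V = prod(frame$box_lengths)),
    class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  cat("System composition\n")
  cat("  atoms per species:  ",
      paste(sprintf("%s=%d", names(x$N), x$N), collapse = ", "), "\n")
  cat("  molecules per type: ",
      paste(sprintf("%s=%d (x=%.4g)", names(x$molecules), x$molecules, x$x),
            collapse = ", "), "\n")
  cat(sprintf("  volume: %.6g A^3\n", x$V))
  invisible(x)
}
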