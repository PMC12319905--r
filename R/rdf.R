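#' Minimum-image distance in an orthorhombic periodic box
#'
#' The displacement between two points is wrapped component-wise to the
#' nearest periodic image before taking the Euclidean norm, so the result
#' lies in `[0, |box|/2 * sqrt(3)]`.
#'
#' @param x_i,x_j Length-3 coordinate vectors, Angstrom.
#' @param box Length-3 positive box vector, Angstrom.
#' @return Distance in Angstrom.
#' @export
minimum_image_distance <- function(x_i, x_j, box) {
  stopifnot(length(x_i) == 3L, length(x_j) == 3L, length(box) == 3L,
            all(box > 0))
  d <- x_i - x_j
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

as_frames <- function(x) {
  if (inherits(x, "toy_trajectory")) return(x$frames)
  if (inherits(x, "frame")) return(list(x))
  x
}

#' Partial radial distribution function between two species
#'
#' Histograms the minimum-image distances of all distinct atom pairs of the
#' requested species combination, averaged over frames, and normalises by
#' exact spherical-shell volumes:
#' \deqn{g_{ab}(r_k) = \bar n_k \, V / (f_{ab} N_a N_b \, V_{shell,k})}
#' where \eqn{\bar n_k} is the mean pair count in bin k per frame and
#' \eqn{f_{ab} = 1/2} for \eqn{a = b}, 1 otherwise, so each unordered pair is
#' counted exactly once. Bins are half-open `[lo, hi)`; a distance exactly on
#' an edge falls in the bin that edge opens.
#'
#' With `exact_self_counting = TRUE` the self-pair normalisation uses the
#' exact distinct-pair count \eqn{N_a(N_a-1)/2} instead of
#' \eqn{N_a^2/2}; the default convention carries an \eqn{O(1/N_a)} bias for
#' self pairs but cancels exactly against the downstream density prefactor.
#'
#' @param frames A `trajectory` (list of frames), a single `frame`, or a
#'   `toy_trajectory`. All frames must share one box.
#' @param topology Matching `topology`.
#' @param species_a,species_b Species labels.
#' @param bin_width Bin width, Angstrom. Default 0.05.
#' @param r_max Histogram range, Angstrom; at most half the minimum box
#'   length (the default).
#' @param exclude_intramolecular Skip pairs sharing a `molecule_id`?
#'   Default `TRUE`: the descriptor targets intermolecular structure.
#' @param exact_self_counting Use \eqn{N_a(N_a-1)/2} normalisation for self
#'   pairs (see Details)? Default `FALSE`.
#' @return An object of class `rdf` with fields `species_a`, `species_b`,
#'   `bin_edges`, `bin_centers`, `g`, `mean_pair_counts`, `n_frames`,
#'   `N_a`, `N_b`, `volume`, `f_ab`, `pair_norm` (the pair count used in the
#'   normalisation), `exclude_intramolecular`, `exact_self_counting`.
#' @export
compute_partial_rdf <- function(frames, topology, species_a, species_b,
                                bin_width = 0.05, r_max = NULL,
                                exclude_intramolecular = TRUE,
                                exact_self_counting = FALSE) {
  frames <- as_frames(frames)
  stopifnot(length(frames) >= 1L, inherits(topology, "topology"),
            bin_width > 0)
  box <- frames[[1L]]$box_lengths
  for (fr in frames) {
    check_frame_topology(fr, topology)
    if (max(abs(fr$box_lengths - box)) > 1e-9 * max(box))
      stop("all frames must share one box for RDF averaging", call. = FALSE)
  }
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop(sprintf("r_max = %g exceeds half the minimum box length (%g)",
                 r_max, min(box) / 2), call. = FALSE)
  labels <- unique(topology$species_label)
  for (s in c(species_a, species_b))
    if (!s %in% labels)
      stop("species '", s, "' not present in topology", call. = FALSE)

  idx_a <- which(topology$species_label == species_a) - 1L
  idx_b <- which(topology$species_label == species_b) - 1L
  same <- identical(species_a, species_b)
  N_a <- length(idx_a); N_b <- length(idx_b)
  if (same && N_a < 2L)
    stop("need at least 2 atoms of species '", species_a,
         "' for a self RDF", call. = FALSE)

  nbins <- max(1L, floor(r_max / bin_width + 1e-9))
  edges <- bin_width * (0:nbins)
  counts <- numeric(nbins)
  for (fr in frames)
    counts <- counts + cpp_pair_hist(fr$coordinates, box, idx_a, idx_b,
                                     same, topology$molecule_id,
                                     exclude_intramolecular,
                                     bin_width, nbins)
  n_frames <- length(frames)
  mean_counts <- counts / n_frames

  f_ab <- if (same) 0.5 else 1.0
  pair_norm <- if (same) {
    if (exact_self_counting) N_a * (N_a - 1) / 2 else f_ab * N_a * N_b
  } else f_ab * N_a * N_b
  V <- prod(box)
  shell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-(nbins + 1L)]^3)
  g <- mean_counts * V / (pair_norm * shell)

  structure(list(species_a = species_a, species_b = species_b,
                 bin_edges = edges,
                 bin_centers = (edges[-1L] + edges[-(nbins + 1L)]) / 2,
                 g = g, mean_pair_counts = mean_counts,
                 n_frames = n_frames, N_a = N_a, N_b = N_b,
                 volume = V, f_ab = f_ab, pair_norm = pair_norm,
                 r_max = edges[nbins + 1L],
                 exclude_intramolecular = exclude_intramolecular,
                 exact_self_counting = exact_self_counting),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("Partial RDF g_%s,%s(r): %d bins of %.4g A up to %.4g A, %d frame(s)\n",
              x$species_a, x$species_b, length(x$g),
              diff(x$bin_edges[1:2]), x$r_max, x$n_frames))
  cat(sprintf("  N_%s = %d, N_%s = %d, V = %.6g A^3, f_ab = %g%s%s\n",
              x$species_a, x$N_a, x$species_b, x$N_b, x$volume, x$f_ab,
              if (x$exclude_intramolecular) ", intramolecular excluded" else "",
              if (x$exact_self_counting) ", exact self counting" else ""))
  invisible(x)
}

#' Construct an RDF object from given g values
#'
#' Builds an `rdf` object from an explicit histogram instead of a
#' trajectory — for closed-form checks (e.g. a step-function g against the
#' analytic LJ integral) and for replaying externally computed RDFs through
#' [effective_interaction_strength()].
#'
#' @param bin_edges Strictly increasing numeric vector of bin edges, A,
#'   starting at 0 or above.
#' @param g Dimensionless g value per bin (length `length(bin_edges) - 1`).
#' @param species_a,species_b Species labels.
#' @param N_a,N_b Species counts entering the prefactor.
#' @param volume Box volume, A^3.
#' @param exact_self_counting Use \eqn{N_a(N_a-1)/2} for a self pair?
#' @return An `rdf` object; `mean_pair_counts` are back-computed from `g`.
#' @export
synthetic_rdf <- function(bin_edges, g, species_a, species_b,
                          N_a, N_b, volume,
                          exact_self_counting = FALSE) {
  stopifnot(all(diff(bin_edges) > 0), bin_edges[1] >= 0,
            length(g) == length(bin_edges) - 1L, all(g >= 0),
            N_a >= 1, N_b >= 1, volume > 0)
  same <- identical(species_a, species_b)
  f_ab <- if (same) 0.5 else 1.0
  pair_norm <- if (same && exact_self_counting) N_a * (N_a - 1) / 2
               else f_ab * N_a * N_b
  n <- length(g)
  shell <- 4 / 3 * pi * (bin_edges[-1L]^3 - bin_edges[-(n + 1L)]^3)
  structure(list(species_a = species_a, species_b = species_b,
                 bin_edges = bin_edges,
                 bin_centers = (bin_edges[-1L] + bin_edges[-(n + 1L)]) / 2,
                 g = g, mean_pair_counts = g * pair_norm * shell / volume,
                 n_frames = 1L, N_a = N_a, N_b = N_b, volume = volume,
                 f_ab = f_ab, pair_norm = pair_norm,
                 r_max = bin_edges[n + 1L],
                 exclude_intramolecular = TRUE,
                 exact_self_counting = exact_self_counting),
            class = "rdf")
}

#' Write an RDF as CSV with a metadata header
#'
#' Columns `bin_center_A, g, mean_pair_count`; `#`-prefixed header lines
#' record the species pair, counts, volume, counting factor and flags.
#'
#' @param rdf An `rdf` object.
#' @param path Output path.
#' @export
write_rdf_csv <- function(rdf, path) {
  stopifnot(inherits(rdf, "rdf"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# species_a=%s species_b=%s", rdf$species_a, rdf$species_b),
    sprintf("# N_a=%d N_b=%d V_A3=%.10g f_ab=%g pair_norm=%.10g n_frames=%d",
            rdf$N_a, rdf$N_b, rdf$volume, rdf$f_ab, rdf$pair_norm,
            rdf$n_frames),
    sprintf("# exclude_intramolecular=%s exact_self_counting=%s r_max_A=%.10g",
            rdf$exclude_intramolecular, rdf$exact_self_counting, rdf$r_max),
    "bin_center_A,g,mean_pair_count"), con)
  writeLines(sprintf("%.10g,%.10g,%.10g", rdf$bin_centers, rdf$g,
                     rdf$mean_pair_counts), con)
  invisible(path)
}
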