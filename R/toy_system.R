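#' Configuration of the toy binary Lennard-Jones Monte Carlo sampler
#'
#' Defines a binary mixture of LJ point particles (species `S1`, `S2`) in a
#' cubic periodic box, sampled by Metropolis single-particle-displacement
#' Monte Carlo on the truncated (unshifted) LJ energy.
#'
#' @param N1,N2 Particle counts per species.
#' @param box_length Cubic box edge, Angstrom.
#' @param temperature Kelvin.
#' @param epsilon_11,epsilon_22 Like-species LJ well depths, kcal/mol.
#' @param epsilon_12 Cross well depth, kcal/mol; default geometric mean.
#' @param sigma Common LJ size parameter, Angstrom.
#' @param r_cut Interaction cutoff, Angstrom; at most `box_length/2`.
#' @param n_sweeps Number of MC sweeps (one sweep = N1+N2 attempted moves).
#' @param max_displacement Maximum trial displacement per Cartesian
#'   component, Angstrom. Fixed during the run (no adaptation, preserving
#'   detailed balance); the default ~0.3 sigma gives acceptance near 40%
#'   at liquid-like densities.
#' @param seed Integer RNG seed (R's Mersenne-Twister drives the whole run).
#' @param snapshot_interval Record a snapshot every this many sweeps after
#'   burn-in.
#' @param burn_in_fraction Fraction of `n_sweeps` discarded before the first
#'   snapshot; default 0.2.
#' @return An object of class `toy_sim_config`.
#' @export
toy_sim_config <- function(N1, N2, box_length, temperature,
                           epsilon_11 = 0.2, epsilon_22 = 0.2,
                           epsilon_12 = sqrt(epsilon_11 * epsilon_22),
                           sigma = 3.0, r_cut = box_length / 2,
                           n_sweeps = 100L, max_displacement = 0.3 * sigma,
                           seed = 1L, snapshot_interval = 1L,
                           burn_in_fraction = 0.2) {
  stopifnot(N1 >= 0, N2 >= 0, N1 + N2 >= 1,
            box_length > 0, temperature >= 0,
            epsilon_11 >= 0, epsilon_22 >= 0, epsilon_12 >= 0,
            sigma > 0, r_cut > 0, n_sweeps >= 0,
            max_displacement > 0, snapshot_interval >= 1,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  if (r_cut > box_length / 2 + 1e-9)
    stop("r_cut must not exceed box_length/2", call. = FALSE)
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2),
                 box_length = box_length, temperature = temperature,
                 epsilon_11 = epsilon_11, epsilon_22 = epsilon_22,
                 epsilon_12 = epsilon_12, sigma = sigma, r_cut = r_cut,
                 n_sweeps = as.integer(n_sweeps),
                 max_displacement = max_displacement,
                 seed = as.integer(seed),
                 snapshot_interval = as.integer(snapshot_interval),
                 burn_in_fraction = burn_in_fraction),
            class = "toy_sim_config")
}

toy_species_labels <- c("S1", "S2")

toy_topology <- function(N1, N2) {
  n <- N1 + N2
  sp <- rep(toy_species_labels, c(N1, N2))
  make_topology(species_label = sp, molecule_id = seq_len(n),
                molecule_type = sp, charge = 0)
}

#' Force field matching a toy-system configuration
#'
#' Species `S1`, `S2` with the configured like-species parameters; the cross
#' pair is written as an explicit override so any `epsilon_12` (including
#' non-geometric choices used to drive demixing) flows through the standard
#' combination machinery.
#'
#' @param config A `toy_sim_config`.
#' @return A `forcefield` object.
#' @export
toy_forcefield <- function(config) {
  stopifnot(inherits(config, "toy_sim_config"))
  structure(list(
    species = list(
      S1 = species_params("S1", config$epsilon_11, config$sigma),
      S2 = species_params("S2", config$epsilon_22, config$sigma)),
    rules = mixing_rules("geometric", data.frame(
      species_a = "S1", species_b = "S2",
      epsilon = config$epsilon_12, sigma = config$sigma,
      stringsAsFactors = FALSE))),
    class = "forcefield")
}

#' Fully phase-separated slab configuration
#'
#' Species 1 occupies the half-box `x < L/2` and species 2 the half-box
#' `x >= L/2`, each on its own cubic sublattice — the completely demixed
#' reference state. Deterministic.
#'
#' @param N1,N2 Particle counts.
#' @param box_length Cubic box edge, Angstrom.
#' @param lattice_spacing Sublattice spacing, Angstrom; the default spreads
#'   the larger species count evenly over its half box.
#' @return A list with elements `frame` and `topology`.
#' @export
make_slab_configuration <- function(N1, N2, box_length,
                                    lattice_spacing =
                                      0.95 * (box_length^3 / 2 /
                                                max(N1, N2))^(1 / 3)) {
  half_lattice <- function(N, x_offset) {
    nx <- floor(box_length / 2 / lattice_spacing)
    nyz <- floor(box_length / lattice_spacing)
    if (nx * nyz * nyz < N)
      stop(sprintf("half-box overfilled: capacity %d < N = %d at spacing %g",
                   nx * nyz * nyz, N, lattice_spacing), call. = FALSE)
    g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(nyz) - 1L,
                     k = seq_len(nyz) - 1L)
    g <- g[seq_len(N), , drop = FALSE]
    cbind(x_offset + (g$i + 0.5) * lattice_spacing,
          (g$j + 0.5) * lattice_spacing,
          (g$k + 0.5) * lattice_spacing)
  }
  xyz <- rbind(half_lattice(N1, 0), half_lattice(N2, box_length / 2))
  fr <- make_frame(xyz, rep(box_length, 3))
  attr(fr, "xyz_species") <- rep(toy_species_labels, c(N1, N2))
  list(frame = fr, topology = toy_topology(N1, N2))
}

#' Random well-mixed configuration
#'
#' Uniform random insertion with rejection of placements closer than
#' `min_separation` (minimum image) to any previous particle; species
#' labels are assigned to positions at random so the mixture is spatially
#' uncorrelated. Reproducible by seed.
#'
#' @param N1,N2 Particle counts.
#' @param box_length Cubic box edge, Angstrom.
#' @param min_separation Minimum allowed pair distance, Angstrom.
#' @param seed Integer RNG seed.
#' @param max_tries Insertion attempts per particle before giving up.
#' @return A list with elements `frame` and `topology`.
#' @export
make_random_mixture <- function(N1, N2, box_length, min_separation = 0,
                                seed = 1L, max_tries = 20000L) {
  n <- N1 + N2
  stopifnot(n >= 1)
  # random sequential addition jams near a sphere packing fraction of ~0.38
  if (min_separation > 0 &&
      pi / 6 * n * min_separation^3 > 0.35 * box_length^3)
    stop("packing infeasible: minimum-separation spheres would exceed a packing fraction of 0.35",
         call. = FALSE)
  set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  box <- rep(box_length, 3)
  min2 <- min_separation^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, 0, box_length)
      if (i == 1L || min_separation <= 0) { ok <- TRUE } else {
        d <- sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2, p)
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        ok <- all(rowSums(d^2) >= min2)
      }
      if (ok) { xyz[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("packing error: could not place particle %d within %d tries",
                   i, max_tries), call. = FALSE)
  }
  sp <- sample(rep(toy_species_labels, c(N1, N2)))
  ord <- order(match(sp, toy_species_labels))  # species-1 block first
  fr <- make_frame(xyz[ord, , drop = FALSE], box)
  attr(fr, "xyz_species") <- sp[ord]
  list(frame = fr, topology = toy_topology(N1, N2))
}

#' Deterministic alternating-lattice mixture
#'
#' Particles on a single cubic lattice with species alternating in raster
#' order — a deterministic, perfectly interpenetrated mixed state.
#'
#' @inheritParams make_slab_configuration
#' @return A list with elements `frame` and `topology`.
#' @export
make_lattice_mixture <- function(N1, N2, box_length) {
  n <- N1 + N2
  m <- ceiling(n^(1/3))
  spacing <- box_length / m
  g <- expand.grid(i = seq_len(m) - 1L, j = seq_len(m) - 1L,
                   k = seq_len(m) - 1L)[seq_len(n), ]
  xyz <- cbind((g$i + 0.5) * spacing, (g$j + 0.5) * spacing,
               (g$k + 0.5) * spacing)
  # alternate species in raster order, then fix counts from the tail
  sp <- rep(toy_species_labels, length.out = n)
  n1 <- sum(sp == "S1")
  if (n1 != N1) {
    from <- if (n1 > N1) "S1" else "S2"
    to <- setdiff(toy_species_labels, from)
    idx <- rev(which(sp == from))[seq_len(abs(n1 - N1))]
    sp[idx] <- to
  }
  ord <- order(match(sp, toy_species_labels))
  fr <- make_frame(xyz[ord, , drop = FALSE], rep(box_length, 3))
  attr(fr, "xyz_species") <- sp[ord]
  list(frame = fr, topology = toy_topology(N1, N2))
}

toy_param_matrices <- function(config) {
  eps <- matrix(c(config$epsilon_11, config$epsilon_12,
                  config$epsilon_12, config$epsilon_22), 2, 2)
  sig <- matrix(config$sigma, 2, 2)
  list(eps = eps, sig = sig)
}

#' Run Metropolis Monte Carlo on a toy binary LJ mixture
#'
#' Single-particle displacement Metropolis sampling of the truncated
#' (unshifted) LJ energy at fixed N, V, T; the acceptance rule is
#' \eqn{\min(1, e^{-\Delta E / k_B T})}. The run is bit-reproducible given
#' the seed; the RNG is R's Mersenne-Twister and is recorded in the result.
#'
#' @param config A [toy_sim_config()].
#' @param initial Starting state: `"random"` (default; a
#'   [make_random_mixture()] at `0.9 sigma` minimum separation), `"slab"`,
#'   `"lattice"`, or a list with elements `frame` and `topology`.
#' @return An object of class `toy_trajectory`: `frames` (snapshots as a
#'   `trajectory`), `topology`, `config`, `acceptance_fraction`,
#'   `snapshot_energy` (tracked total energy per snapshot, kcal/mol),
#'   `energy_tracked`, `energy_recomputed` (end-of-run bookkeeping check),
#'   `rng` (generator name).
#' @export
run_metropolis <- function(config, initial = "random") {
  stopifnot(inherits(config, "toy_sim_config"))
  if (is.character(initial)) {
    initial <- switch(match.arg(initial, c("random", "slab", "lattice")),
      random = make_random_mixture(config$N1, config$N2, config$box_length,
                                   min_separation = 0.9 * config$sigma,
                                   seed = config$seed),
      slab = make_slab_configuration(config$N1, config$N2,
                                     config$box_length),
      lattice = make_lattice_mixture(config$N1, config$N2,
                                     config$box_length))
  }
  fr <- initial$frame; top <- initial$topology
  check_frame_topology(fr, top)
  pm <- toy_param_matrices(config)
  spi <- match(top$species_label, toy_species_labels) - 1L
  burn_in <- as.integer(floor(config$burn_in_fraction * config$n_sweeps))
  set.seed(config$seed)
  res <- cpp_run_metropolis(fr$coordinates, fr$box_lengths, spi, 2L,
                            pm$eps, pm$sig, config$r_cut,
                            config$temperature, effint_constants$k_B,
                            config$n_sweeps, config$max_displacement,
                            config$snapshot_interval, burn_in)
  snaps <- res$snapshots
  if (length(snaps) == 0L) {  # zero-sweep run: keep the initial state
    snaps <- list(fr$coordinates)
    res$snapshot_energy <- res$energy_recomputed
  }
  frames <- structure(lapply(seq_along(snaps), function(i) {
    f <- make_frame(snaps[[i]], fr$box_lengths, i)
    attr(f, "xyz_species") <- top$species_label
    f
  }), class = "trajectory")
  structure(list(frames = frames, topology = top, config = config,
                 acceptance_fraction = res$acceptance_fraction,
                 snapshot_energy = res$snapshot_energy,
                 energy_tracked = res$energy_tracked,
                 energy_recomputed = res$energy_recomputed,
                 burn_in_sweeps = burn_in,
                 rng = "Mersenne-Twister"),
            class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf(
    "Toy MC trajectory: %d snapshot(s) of %d particles (N1=%d, N2=%d), T=%g K\n",
    length(x$frames), x$config$N1 + x$config$N2, x$config$N1, x$config$N2,
    x$config$temperature))
  cat(sprintf("  acceptance %.3f, tracked energy %.6g kcal/mol (recomputed %.6g)\n",
              x$acceptance_fraction, x$energy_tracked, x$energy_recomputed))
  invisible(x)
}

#' Brute-force truncated pair-energy sums by species pair
#'
#' Exact sum of the pair potential over all distinct minimum-image pairs
#' with `r <= r_cut`, grouped by unordered species pair — the direct-route
#' oracle against which the RDF-integral route is validated.
#'
#' @param frame A `frame`.
#' @param topology Matching `topology`.
#' @param forcefield A `forcefield` covering all species present.
#' @param r_cut Cutoff, Angstrom.
#' @param exclude_intramolecular Skip pairs sharing a molecule id?
#' @param include_coulomb Add the point-charge Coulomb term?
#' @return An object of class `energy_report`: `total` (kcal/mol) and
#'   `per_pair`, a named vector of species-pair sums (names `"a|b"`) adding
#'   exactly to the total.
#' @export
total_pair_energy <- function(frame, topology, forcefield, r_cut,
                              exclude_intramolecular = TRUE,
                              include_coulomb = FALSE) {
  stopifnot(inherits(frame, "frame"), inherits(topology, "topology"),
            inherits(forcefield, "forcefield"))
  check_frame_topology(frame, topology)
  labels <- unique(topology$species_label)
  specs <- all_pair_specs(forcefield, labels)
  nsp <- length(labels)
  eps <- sig <- kqq <- matrix(0, nsp, nsp)
  for (i in seq_len(nsp)) for (j in i:nsp) {
    s <- specs[[paste(labels[i], labels[j], sep = "|")]]
    eps[i, j] <- eps[j, i] <- s$epsilon_ab
    sig[i, j] <- sig[j, i] <- s$sigma_ab
    kqq[i, j] <- kqq[j, i] <- effint_constants$k_e * s$q_a * s$q_b
  }
  spi <- match(topology$species_label, labels) - 1L
  u <- cpp_pair_energy_sums(frame$coordinates, frame$box_lengths, spi, nsp,
                            topology$molecule_id, exclude_intramolecular,
                            eps, sig, kqq, include_coulomb, r_cut)
  per <- numeric(0)
  for (i in seq_len(nsp)) for (j in i:nsp)
    per[pair_key(labels[i], labels[j])] <- u[i, j]
  structure(list(total = sum(per), per_pair = per), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("Total truncated pair energy: %.8g kcal/mol\n", x$total))
  for (k in names(x$per_pair))
    cat(sprintf("  %-12s %.8g\n", k, x$per_pair[[k]]))
  invisible(x)
}

#' Trajectory-averaged brute-force pair-energy sums
#'
#' [total_pair_energy()] averaged over the frames of a trajectory.
#'
#' @inheritParams total_pair_energy
#' @param frames A `trajectory`, single `frame`, or `toy_trajectory` (its
#'   topology is then used when `topology` is missing).
#' @param topology Matching `topology`.
#' @return An `energy_report` of per-frame means.
#' @export
mean_pair_energy <- function(frames, topology = NULL, forcefield, r_cut,
                             exclude_intramolecular = TRUE,
                             include_coulomb = FALSE) {
  if (inherits(frames, "toy_trajectory") && is.null(topology))
    topology <- frames$topology
  frames <- as_frames(frames)
  reps <- lapply(frames, total_pair_energy, topology = topology,
                 forcefield = forcefield, r_cut = r_cut,
                 exclude_intramolecular = exclude_intramolecular,
                 include_coulomb = include_coulomb)
  per <- Reduce(`+`, lapply(reps, `[[`, "per_pair")) / length(reps)
  structure(list(total = sum(per), per_pair = per), class = "energy_report")
}
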