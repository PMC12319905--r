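# Fixtures shared across test files. Everything is generated in code.

# Single frame holding two atoms of species A and B at distance d along x,
# centred in a cubic box of edge L; one molecule each.
dimer_system <- function(d, L = 100) {
  fr <- make_frame(rbind(c(L / 2 - d / 2, L / 2, L / 2),
                         c(L / 2 + d / 2, L / 2, L / 2)),
                   rep(L, 3))
  top <- make_topology(species_label = c("A", "B"),
                       molecule_id = c(1L, 2L),
                       molecule_type = c("A", "B"))
  list(frame = fr, topology = top)
}

# A two-species force field with unit-free round numbers.
simple_ff <- function(eps_a = 0.2, eps_b = 0.2, sig_a = 3, sig_b = 3,
                      q_a = 0, q_b = 0, overrides = NULL,
                      rule = "geometric") {
  structure(list(
    species = list(A = species_params("A", eps_a, sig_a, q_a),
                   B = species_params("B", eps_b, sig_b, q_b)),
    rules = mixing_rules(rule, overrides)),
    class = "forcefield")
}

# Study conditions for the RDF-route vs brute-force oracle identity:
# an equilibrating dense binary LJ fluid at liquid-like conditions
# (rho* ~ 0.6, T* ~ 1.2). The identity holds configuration by
# configuration, equilibrated or not.
oracle_config <- function(seed = 42L, n_sweeps = 300L,
                          N1 = 200L, N2 = 200L) {
  toy_sim_config(N1 = N1, N2 = N2, box_length = 26, temperature = 150,
                 epsilon_11 = 0.25, epsilon_22 = 0.25, sigma = 3,
                 r_cut = 13, n_sweeps = n_sweeps, max_displacement = 0.9,
                 seed = seed, snapshot_interval = 2L)
}

# Brute-force minimum over the 27 periodic image translations, used as the
# independent oracle for the minimum-image distance kernel.
dist_27_images <- function(x_i, x_j, box) {
  x_i <- x_i %% box   # into the primary cell; then 27 images suffice
  x_j <- x_j %% box
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  img <- sweep(sweep(shifts, 2, box, `*`), 2, x_j, `+`)
  min(sqrt(rowSums(sweep(img, 2, x_i, function(a, b) (b - a))^2)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
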