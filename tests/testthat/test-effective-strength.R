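test_that("a step-function g integrates to the closed form -(8/9) eps sigma^3", {
  eps <- 0.25; sig <- 3
  bw <- 0.005 * sig
  edges <- seq(0, 30 * sig, by = bw)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  g <- as.numeric(centers >= sig)
  rdf <- synthetic_rdf(edges, g, "A", "B", N_a = 10, N_b = 10, volume = 1e6)
  spec <- combine_pair(species_params("A", eps, sig),
                       species_params("B", eps, sig))
  res <- effective_interaction_strength(rdf, spec)
  closed <- -8 / 9 * eps * sig^3    # analytic integral of r^2 U_LJ over [sigma, Inf)
  expect_rel_equal(res$integral_value, closed, 0.01)
  # independent quadrature of the same integrand
  quad <- integrate(function(r) r^2 * lj_energy(r, eps, sig), sig, Inf,
                    rel.tol = 1e-10)$value
  expect_rel_equal(closed, quad, 1e-6)
  # the exported decomposition is exact: u_eff = prefactor * integral
  expect_identical(res$u_eff, res$prefactor * res$integral_value)
  expect_equal(res$prefactor, 4 * pi * 1 * 10 * 10 / 1e6)
})

test_that("g identically zero yields u_eff = 0 and the repulsive core is never evaluated", {
  edges <- seq(0, 10, by = 0.05)
  g <- numeric(length(edges) - 1)
  rdf <- synthetic_rdf(edges, g, "A", "A", N_a = 5, N_b = 5, volume = 1e3)
  spec <- combine_pair(species_params("A", 1, 3), species_params("A", 1, 3))
  res <- effective_interaction_strength(rdf, spec)
  expect_identical(res$u_eff, 0)
  # a huge g spike far outside the core dominates; zero bins at tiny r
  # (where U diverges) must contribute exactly nothing
  g2 <- g; g2[150] <- 1   # bin centred near r = 7.5
  rdf2 <- synthetic_rdf(edges, g2, "A", "A", N_a = 5, N_b = 5, volume = 1e3)
  res2 <- effective_interaction_strength(rdf2, spec)
  expect_true(is.finite(res2$u_eff))
  expect_lt(res2$u_eff, 0)
})

test_that("mismatched species pairs between RDF and potential are rejected", {
  edges <- seq(0, 10, by = 0.1)
  rdf <- synthetic_rdf(edges, rep(1, length(edges) - 1L), "A", "B", 5, 5, 1e3)
  spec <- combine_pair(species_params("A", 1, 3), species_params("C", 1, 3))
  expect_error(effective_interaction_strength(rdf, spec), "pair")
  # swapped order of the same pair is fine
  spec_ba <- combine_pair(species_params("B", 1, 3), species_params("A", 1, 3))
  expect_silent(effective_interaction_strength(rdf, spec_ba))
})

test_that("molecular aggregation sums exactly the right species pairs and delta_mix is linear", {
  # synthetic per-pair results for species {H, C_H} in type hex and
  # {F, C_F} in type pfh
  mk <- function(a, b, u) structure(
    list(species_a = a, species_b = b, u_eff = u), class = "ueff")
  sp <- c("H", "C_H", "F", "C_F")
  vals <- c("H|H" = -1, "C_H|H" = -2, "C_H|C_H" = -4,
            "F|F" = -8, "C_F|F" = -16, "C_F|C_F" = -32,
            "F|H" = -64, "C_F|H" = -128, "C_H|F" = -256, "C_F|C_H" = -512)
  res <- lapply(names(vals), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    mk(p[1], p[2], vals[[k]])
  })
  map <- c(H = "hex", C_H = "hex", F = "pfh", C_F = "pfh")
  mix <- aggregate_molecular(res, map, "hex", "pfh")
  expect_equal(mix$u_AA, -7)       # H-H + H-C_H + C_H-C_H
  expect_equal(mix$u_BB, -56)      # F-F + F-C_F + C_F-C_F
  expect_equal(mix$u_AB, -960)     # the four cross pairs
  expect_identical(mix$delta_mix, mix$u_AB - (mix$u_AA + mix$u_BB))
  # total over all pairs equals u_AA + u_BB + u_AB exactly
  expect_identical(excess_internal_energy(res),
                   mix$u_AA + mix$u_BB + mix$u_AB)
  expect_equal(excess_internal_energy(res), sum(vals))

  # exact cancellation case
  mix0 <- aggregate_molecular(
    list(mk("a", "a", -4), mk("b", "b", -6), mk("a", "b", -10)),
    c(a = "A", b = "B"), "A", "B")
  expect_identical(mix0$delta_mix, 0)

  # a missing pair is a coverage error naming the pair
  expect_error(aggregate_molecular(res[-4], map, "hex", "pfh"), "F\\|F")
})

test_that("excess energy is additive over disjoint pair subsets", {
  mk <- function(a, b, u) structure(
    list(species_a = a, species_b = b, u_eff = u), class = "ueff")
  subset1 <- list(mk("A", "A", -1.5), mk("A", "B", -3.25))
  subset2 <- list(mk("B", "B", -0.75))
  expect_identical(excess_internal_energy(c(subset1, subset2)),
                   excess_internal_energy(subset1) +
                     excess_internal_energy(subset2))
})

test_that("ideal kinetic energy is (3/2) N k_B T", {
  expect_identical(ideal_internal_energy(0, 300), 0)
  expect_identical(ideal_internal_energy(500, 0), 0)
  # 1.5 * 1000 * 0.0019872041 * 300, multiplied out by hand
  expect_equal(ideal_internal_energy(1000, 300), 894.241845)
})

test_that("RDF route with exact self counting reproduces the brute-force pair sum", {
  # small dense one-frame fixture, fine bins: identity within 1%
  sys <- make_random_mixture(60, 60, box_length = 16, min_separation = 2.6,
                             seed = 100)
  cfg <- toy_sim_config(N1 = 60, N2 = 60, box_length = 16, temperature = 150,
                        epsilon_11 = 0.3, epsilon_22 = 0.2, sigma = 2.9,
                        r_cut = 8, n_sweeps = 40, seed = 100,
                        snapshot_interval = 4)
  traj <- run_metropolis(cfg, initial = sys)
  ff <- toy_forcefield(cfg)
  res <- effective_strength_table(traj, traj$topology, ff,
                                  bin_width = 0.04, r_max = 8,
                                  exact_self_counting = TRUE)
  oracle <- mean_pair_energy(traj, forcefield = ff, r_cut = 8)
  expect_rel_equal(excess_internal_energy(res), oracle$total, 0.01)
  for (k in names(oracle$per_pair))
    expect_rel_equal(res[[k]]$u_eff, oracle$per_pair[[k]], 0.02)
})

test_that("halving the bin width moves u_eff by less than 0.5 percent", {
  cfg <- toy_sim_config(N1 = 60, N2 = 60, box_length = 16, temperature = 150,
                        epsilon_11 = 0.25, epsilon_22 = 0.25, sigma = 2.9,
                        r_cut = 8, n_sweeps = 60, seed = 17,
                        snapshot_interval = 4)
  traj <- run_metropolis(cfg)
  ff <- toy_forcefield(cfg)
  coarse <- effective_strength_table(traj, traj$topology, ff,
                                     bin_width = 0.05, r_max = 8)
  fine <- effective_strength_table(traj, traj$topology, ff,
                                   bin_width = 0.025, r_max = 8)
  for (k in names(coarse))
    expect_rel_equal(fine[[k]]$u_eff, coarse[[k]]$u_eff, 0.005)
})

test_that("label splitting leaves molecule-level aggregates unchanged", {
  cfg <- toy_sim_config(N1 = 80, N2 = 40, box_length = 16, temperature = 150,
                        epsilon_11 = 0.25, epsilon_22 = 0.25, sigma = 2.9,
                        r_cut = 8, n_sweeps = 30, seed = 23,
                        snapshot_interval = 5)
  traj <- run_metropolis(cfg)
  ff <- toy_forcefield(cfg)
  res <- effective_strength_table(traj, traj$topology, ff,
                                  bin_width = 0.05, r_max = 8)
  mix <- aggregate_molecular(res, c(S1 = "S1", S2 = "S2"), "S1", "S2")

  # relabel a random half of the S1 atoms as a new species S1b
  top2 <- traj$topology
  set.seed(1)
  idx <- sample(which(top2$species_label == "S1"), 40)
  top2$species_label[idx] <- "S1b"
  ff2 <- ff
  ff2$species$S1b <- species_params("S1b", cfg$epsilon_11, cfg$sigma)
  ff2$rules$overrides <- rbind(
    ff2$rules$overrides,
    data.frame(species_a = "S1b", species_b = "S2",
               epsilon = cfg$epsilon_12, sigma = cfg$sigma))
  res2 <- effective_strength_table(traj$frames, top2, ff2,
                                   bin_width = 0.05, r_max = 8)
  mix2 <- aggregate_molecular(res2, c(S1 = "S1", S1b = "S1", S2 = "S2"),
                              "S1", "S2")
  # counting-factor bookkeeping makes the aggregates split-invariant
  # (the pair_norm cancels between g and the prefactor); allow only
  # numerical noise well below the O(1/N) bias bound
  expect_rel_equal(mix2$u_AA, mix$u_AA, 1e-8)
  expect_rel_equal(mix2$u_AB, mix$u_AB, 1e-8)
  expect_rel_equal(mix2$u_BB, mix$u_BB, 1e-10)
  expect_lt(abs(mix2$delta_mix - mix$delta_mix), 1e-8 * abs(mix$u_AA))
})

test_that("doubling a configuration with its box doubles every u_eff", {
  sys <- make_random_mixture(50, 50, box_length = 15, min_separation = 2.5,
                             seed = 31)
  cfg <- toy_sim_config(N1 = 50, N2 = 50, box_length = 15, temperature = 150,
                        epsilon_11 = 0.25, epsilon_22 = 0.25, sigma = 2.9,
                        r_cut = 7, seed = 31)
  ff <- toy_forcefield(cfg)
  res1 <- effective_strength_table(sys$frame, sys$topology, ff,
                                   bin_width = 0.05, r_max = 7)
  # replicate 2 x 1 x 1
  xyz <- sys$frame$coordinates
  xyz2 <- rbind(xyz, sweep(xyz, 2, c(15, 0, 0), `+`))
  sp2 <- rep(sys$topology$species_label, 2)
  fr2 <- make_frame(xyz2, c(30, 15, 15))
  top2 <- make_topology(sp2, seq_along(sp2), sp2)
  res2 <- effective_strength_table(fr2, top2, ff, bin_width = 0.05,
                                   r_max = 7)
  for (k in names(res1))
    expect_rel_equal(res2[[k]]$u_eff, 2 * res1[[k]]$u_eff, 0.05)
})

test_that("the equimolar ideal-entropy term reproduces its conventional values", {
  expect_identical(ideal_mixing_entropy_term(0), 0)
  expect_equal(ideal_mixing_entropy_term(200), 275.5, tolerance = 2e-4)
  expect_equal(ideal_mixing_entropy_term(300), 413.2, tolerance = 2e-4)
  # linear in T
  expect_equal(ideal_mixing_entropy_term(250),
               (ideal_mixing_entropy_term(200) +
                  ideal_mixing_entropy_term(300)) / 2)
})
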