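#' Effective interaction strength of one species pair
#'
#' Computes the density-weighted pair-potential integral
#' \deqn{U^{eff}_{ab} = \frac{4\pi f_{ab} N_a N_b}{V}
#'       \int_0^{r_{max}} r^2 U_{ab}(r)\, g_{ab}(r)\, dr}
#' by the trapezoidal rule on the RDF's bin centers. The quantity is a
#' configuration-dependent, species-pair-resolved contribution to the
#' excess (configurational) internal energy: it measures how strongly the
#' pair interaction of species `a` and `b` acts in the sampled state.
#'
#' Bins where `g = 0` contribute an integrand value of exactly 0, so the
#' divergent repulsive core below first contact is never evaluated. The
#' prefactor follows the RDF's counting convention (`pair_norm`), so
#' `u_eff = prefactor * integral` holds exactly and, with
#' `exact_self_counting`, the RDF route reproduces the brute-force pair-sum
#' oracle up to binning error.
#'
#' @param rdf An [compute_partial_rdf()] result.
#' @param spec The matching `pair_potential_spec` (same species pair, either
#'   order).
#' @param include_coulomb Add the Coulomb term of `spec` to the LJ term?
#' @param tail_correction Add the analytic LJ tail
#'   \eqn{4\pi f_{ab} N_a N_b / V \int_{r_{max}}^\infty r^2 U_{LJ}(r) dr}
#'   assuming \eqn{g = 1} beyond the histogram range? Off by default: the
#'   empirical g is only known up to `r_max`. Not available with
#'   `include_coulomb` (the Coulomb tail integral diverges).
#' @return An object of class `ueff` with fields `species_a`, `species_b`,
#'   `f_ab`, `N_a`, `N_b`, `volume`, `integral_value` (A^3 kcal/mol),
#'   `prefactor` (A^-3), `u_eff` (kcal/mol), `r_max_used`, `include_coulomb`.
#' @export
effective_interaction_strength <- function(rdf, spec,
                                           include_coulomb = FALSE,
                                           tail_correction = FALSE) {
  stopifnot(inherits(rdf, "rdf"), inherits(spec, "pair_potential_spec"))
  rp <- sort(c(rdf$species_a, rdf$species_b))
  sp <- sort(c(spec$species_a, spec$species_b))
  if (!identical(rp, sp))
    stop(sprintf("RDF is for pair (%s, %s) but potential spec for (%s, %s)",
                 rdf$species_a, rdf$species_b, spec$species_a, spec$species_b),
         call. = FALSE)
  if (length(rdf$g) == 0L)
    stop("empty RDF: no bins to integrate", call. = FALSE)
  if (tail_correction && include_coulomb)
    stop("tail_correction is only defined for the pure LJ form", call. = FALSE)

  r <- rdf$bin_centers
  integrand <- numeric(length(r))
  nz <- rdf$g > 0
  integrand[nz] <- r[nz]^2 * pair_energy(r[nz], spec, include_coulomb) *
    rdf$g[nz]
  integral <- pracma::trapz(r, integrand)
  if (tail_correction) {
    R <- rdf$r_max
    eps <- spec$epsilon_ab; sig <- spec$sigma_ab
    integral <- integral + 4 * eps * (sig^12 / (9 * R^9) - sig^6 / (3 * R^3))
  }
  prefactor <- 4 * pi * rdf$pair_norm / rdf$volume
  structure(list(species_a = rdf$species_a, species_b = rdf$species_b,
                 f_ab = rdf$f_ab, N_a = rdf$N_a, N_b = rdf$N_b,
                 volume = rdf$volume,
                 integral_value = integral, prefactor = prefactor,
                 u_eff = prefactor * integral,
                 r_max_used = rdf$r_max,
                 include_coulomb = include_coulomb),
            class = "ueff")
}

#' @export
print.ueff <- function(x, ...) {
  cat(sprintf("U_eff(%s, %s) = %.6g kcal/mol  (integral %.6g A^3 kcal/mol x prefactor %.6g A^-3)\n",
              x$species_a, x$species_b, x$u_eff, x$integral_value,
              x$prefactor))
  invisible(x)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Effective interaction strengths for every species pair of a system
#'
#' Convenience pipeline: computes all K(K+1)/2 partial RDFs of the species
#' present in the topology and integrates each against its combined pair
#' potential.
#'
#' @inheritParams compute_partial_rdf
#' @param forcefield A `forcefield` covering every species in the topology.
#' @param include_coulomb Passed to [effective_interaction_strength()].
#' @param labels Optional subset/ordering of species labels; default all
#'   species in the topology, in first-appearance order.
#' @return A named list of `ueff` objects (class `ueff_set`), one per
#'   unordered species pair, named `"a|b"`. `as.data.frame()` turns it into
#'   the per-pair results table.
#' @export
effective_strength_table <- function(frames, topology, forcefield,
                                     bin_width = 0.05, r_max = NULL,
                                     include_coulomb = FALSE,
                                     exclude_intramolecular = TRUE,
                                     exact_self_counting = FALSE,
                                     labels = NULL) {
  stopifnot(inherits(forcefield, "forcefield"))
  frames <- as_frames(frames)
  if (is.null(labels)) labels <- unique(topology$species_label)
  missing <- setdiff(labels, names(forcefield$species))
  if (length(missing))
    stop("species missing from force field: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- list()
  for (i in seq_along(labels)) for (j in i:length(labels)) {
    a <- labels[i]; b <- labels[j]
    rdf <- compute_partial_rdf(frames, topology, a, b,
                               bin_width = bin_width, r_max = r_max,
                               exclude_intramolecular = exclude_intramolecular,
                               exact_self_counting = exact_self_counting)
    spec <- combine_pair(forcefield$species[[a]], forcefield$species[[b]],
                         forcefield$rules)
    out[[pair_key(a, b)]] <-
      effective_interaction_strength(rdf, spec,
                                     include_coulomb = include_coulomb)
  }
  structure(out, class = "ueff_set")
}

#' @export
as.data.frame.ueff_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(u)
    data.frame(species_a = u$species_a, species_b = u$species_b,
               f_ab = u$f_ab, N_a = u$N_a, N_b = u$N_b, V_A3 = u$volume,
               integral_A3_kcal_mol = u$integral_value,
               prefactor_A_minus3 = u$prefactor,
               u_eff_kcal_mol = u$u_eff,
               r_max_A = u$r_max_used,
               include_coulomb = u$include_coulomb,
               stringsAsFactors = FALSE)))
}

#' Aggregate species-pair strengths to molecular interaction energies
#'
#' Sums the species-pair effective strengths over molecule types:
#' \deqn{U^{eff}_{AB} = \sum_{a \in A}\sum_{b \in B} U^{eff}_{ab}}
#' giving the homomolecular energies `u_AA`, `u_BB`, the heteromolecular
#' energy `u_AB`, and the effective energy of mixing
#' \deqn{\Delta_{mix} U^{eff} = U^{eff}_{AB} - (U^{eff}_{AA} + U^{eff}_{BB}).}
#' Negative \eqn{\Delta_{mix} U^{eff}} indicates enthalpically favoured
#' mixing under this descriptor.
#'
#' @param results A `ueff_set` (or plain list of `ueff`) covering every
#'   species pair within the union of the two molecule types.
#' @param species_to_type Named character vector mapping each species label
#'   to its molecule type.
#' @param type_A,type_B The two molecule-type names entering the mixing
#'   decomposition.
#' @return An object of class `mixing_decomposition`: `u_AA`, `u_BB`,
#'   `u_AB`, `delta_mix` (all kcal/mol), `type_A`, `type_B`, `per_pair`
#'   (named numeric vector of the species-pair contributions), and
#'   `type_pair_sums` (sums for every molecule-type pair present, also
#'   beyond A and B).
#' @export
aggregate_molecular <- function(results, species_to_type, type_A, type_B) {
  results <- unclass(results)
  stopifnot(length(results) >= 1L)
  for (ty in c(type_A, type_B))
    if (!ty %in% species_to_type)
      stop("molecule type '", ty, "' not present in species_to_type map",
           call. = FALSE)
  got <- vapply(results, function(u) pair_key(u$species_a, u$species_b), "")
  names(results) <- got
  u_of <- function(a, b) {
    k <- pair_key(a, b)
    if (!k %in% got) return(NA_real_)
    results[[k]]$u_eff
  }
  species <- names(species_to_type)
  # coverage check over the species of A union B
  sAB <- species[species_to_type %in% c(type_A, type_B)]
  need <- character(0)
  for (i in seq_along(sAB)) for (j in i:length(sAB))
    if (!pair_key(sAB[i], sAB[j]) %in% got)
      need <- c(need, pair_key(sAB[i], sAB[j]))
  if (length(need))
    stop("missing species-pair results: ", paste(need, collapse = ", "),
         call. = FALSE)

  types <- unique(species_to_type)
  type_pair_sums <- list()
  for (i in seq_along(types)) for (j in i:length(types)) {
    tA <- types[i]; tB <- types[j]
    sa <- species[species_to_type == tA]
    sb <- species[species_to_type == tB]
    tot <- 0; complete <- TRUE
    seen <- character(0)
    for (a in sa) for (b in sb) {
      k <- pair_key(a, b)
      if (k %in% seen) next       # unordered pair within one type
      seen <- c(seen, k)
      v <- u_of(a, b)
      if (is.na(v)) { complete <- FALSE; next }
      tot <- tot + v
    }
    type_pair_sums[[paste(tA, tB, sep = "|")]] <-
      if (complete) tot else NA_real_
  }
  u_AA <- type_pair_sums[[paste(type_A, type_A, sep = "|")]]
  u_BB <- type_pair_sums[[paste(type_B, type_B, sep = "|")]]
  kAB <- paste(sort(c(type_A, type_B)), collapse = "|")
  u_AB <- type_pair_sums[[kAB]]
  per_pair <- vapply(results, function(u) u$u_eff, 0.0)
  structure(list(type_A = type_A, type_B = type_B,
                 u_AA = u_AA, u_BB = u_BB, u_AB = u_AB,
                 delta_mix = u_AB - (u_AA + u_BB),
                 per_pair = per_pair,
                 type_pair_sums = unlist(type_pair_sums)),
            class = "mixing_decomposition")
}

#' @export
print.mixing_decomposition <- function(x, ...) {
  cat(sprintf("Molecular effective interaction energies (kcal/mol)\n"))
  cat(sprintf("  U_eff(%s-%s) = %.6g\n", x$type_A, x$type_A, x$u_AA))
  cat(sprintf("  U_eff(%s-%s) = %.6g\n", x$type_B, x$type_B, x$u_BB))
  cat(sprintf("  U_eff(%s-%s) = %.6g\n", x$type_A, x$type_B, x$u_AB))
  cat(sprintf("  Delta_mix U_eff = %.6g  (%s)\n", x$delta_mix,
              if (is.na(x$delta_mix)) "NA"
              else if (x$delta_mix < 0) "mixing enthalpically favoured"
              else "demixing enthalpically favoured"))
  invisible(x)
}

#' Excess (configurational) internal energy from per-pair strengths
#'
#' The interaction part of the internal energy: the sum of the effective
#' interaction strengths over all unordered species pairs (self pairs enter
#' once, with their counting factor 1/2 already applied inside each term).
#'
#' @param results A `ueff_set` or list of `ueff`.
#' @return Energy in kcal/mol.
#' @export
excess_internal_energy <- function(results) {
  results <- unclass(results)
  sum(vapply(results, function(u) u$u_eff, 0.0))
}

#' Ideal (kinetic) internal energy of N point particles
#'
#' \eqn{(3/2) N k_B T} with \eqn{k_B} = 0.0019872041 kcal/(mol K).
#'
#' @param N Particle count (>= 0).
#' @param T Temperature in Kelvin (>= 0).
#' @return Energy in kcal/mol.
#' @export
ideal_internal_energy <- function(N, T) {
  stopifnot(N >= 0, T >= 0)
  1.5 * N * effint_constants$k_B * T
}

#' Ideal equimolar mixing-entropy term T R ln 2
#'
#' The entropic contribution of ideal equimolar binary mixing,
#' \eqn{T R \ln 2} with R = 1.987 cal/(mol K), returned as the bare numeric
#' value in the field's customary reporting convention (275.5 at 200 K,
#' 413.2 at 300 K). Note that the number equals the energy in cal/mol even
#' though it is conventionally quoted next to kcal/mol quantities; the
#' scaling is reported as printed rather than silently converted.
#'
#' @param T Temperature in Kelvin (> 0; the limit T -> 0 gives 0).
#' @return Numeric value of T R ln 2 (R in cal/(mol K)).
#' @export
ideal_mixing_entropy_term <- function(T) {
  stopifnot(T >= 0)
  T * effint_constants$R_cal * log(2)
}
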