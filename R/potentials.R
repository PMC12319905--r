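#' Physical constants used throughout the package
#'
#' All energies are in kcal/mol, lengths in Angstrom, charges in elementary
#' charges and temperatures in Kelvin.
#'
#' @format A list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, 0.0019872041 kcal/(mol K).}
#'   \item{k_e}{Coulomb prefactor, 332.06371 kcal A / (mol e^2).}
#'   \item{R_cal}{Gas constant in cal/(mol K), 1.987, used by the ideal
#'     mixing-entropy helper.}
#' }
#' @export
effint_constants <- list(
  k_B   = 0.0019872041,
  k_e   = 332.06371,
  R_cal = 1.987
)

#' Lennard-Jones 12-6 pair potential
#'
#' Evaluates \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}.
#' `epsilon` is the well depth and `sigma` the zero crossing; the minimum
#' sits at \eqn{2^{1/6}\sigma} with value \eqn{-\epsilon}.
#'
#' @param r Distance(s) in Angstrom; must be strictly positive.
#' @param epsilon Well depth in kcal/mol (>= 0).
#' @param sigma Size parameter in Angstrom (> 0).
#' @return Energy in kcal/mol, vectorised over `r`.
#' @examples
#' lj_energy(2^(1/6) * 2.95, 0.053, 2.95)  # -0.053 at the minimum
#' @export
lj_energy <- function(r, epsilon, sigma) {
  stopifnot(epsilon >= 0, sigma > 0)
  if (any(r <= 0)) stop("lj_energy: distance r must be > 0", call. = FALSE)
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Coulomb pair potential
#'
#' Point-charge interaction \eqn{k_e q_a q_b / r} with
#' \eqn{k_e = 332.06371} kcal A / (mol e^2), i.e. charges in elementary
#' charges give energies in kcal/mol directly.
#'
#' @param r Distance(s) in Angstrom; strictly positive.
#' @param q_a,q_b Partial charges in elementary charges.
#' @return Energy in kcal/mol, vectorised over `r`.
#' @export
coulomb_energy <- function(r, q_a, q_b) {
  if (any(r <= 0)) stop("coulomb_energy: distance r must be > 0", call. = FALSE)
  effint_constants$k_e * q_a * q_b / r
}

#' Per-species nonbonded parameters
#'
#' @param label Species identifier (e.g. `"F"`, `"C_H"`).
#' @param epsilon LJ well depth, kcal/mol (>= 0).
#' @param sigma LJ size parameter, Angstrom (> 0).
#' @param charge Partial charge, elementary charges.
#' @return An object of class `species_params`.
#' @export
species_params <- function(label, epsilon, sigma, charge = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(epsilon >= 0, sigma > 0)
  structure(list(label = label, epsilon = epsilon, sigma = sigma,
                 charge = charge),
            class = "species_params")
}

#' Mixing-rule configuration
#'
#' Cross-species LJ parameters are generated from like-species parameters by
#' the chosen default rule; individually listed pairs bypass the rule and use
#' the supplied values verbatim (both orderings of the pair).
#'
#' @param default_rule `"geometric"` (\eqn{\epsilon_{ab}=\sqrt{\epsilon_a\epsilon_b}},
#'   \eqn{\sigma_{ab}=\sqrt{\sigma_a\sigma_b}}) or `"lorentz_berthelot"`
#'   (geometric epsilon, arithmetic-mean sigma).
#' @param overrides `NULL` or a data.frame with columns
#'   `species_a, species_b, epsilon, sigma`.
#' @return An object of class `mixing_rules`.
#' @export
mixing_rules <- function(default_rule = c("geometric", "lorentz_berthelot"),
                         overrides = NULL) {
  default_rule <- match.arg(default_rule)
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    need <- c("species_a", "species_b", "epsilon", "sigma")
    if (!all(need %in% names(overrides)))
      stop("overrides must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    stopifnot(all(overrides$epsilon >= 0), all(overrides$sigma > 0))
  }
  structure(list(default_rule = default_rule, overrides = overrides),
            class = "mixing_rules")
}

find_override <- function(rules, a, b) {
  ov <- rules$overrides
  if (is.null(ov) || nrow(ov) == 0L) return(NULL)
  hit <- (ov$species_a == a & ov$species_b == b) |
         (ov$species_a == b & ov$species_b == a)
  if (!any(hit)) return(NULL)
  ov[which(hit)[1L], , drop = FALSE]
}

#' Combine two species into a pair-potential specification
#'
#' Applies the configured combination rule (or a per-pair override) to
#' produce the cross parameters for one unordered species pair. The result
#' is symmetric: `combine_pair(a, b, ...)` and `combine_pair(b, a, ...)`
#' are identical up to the order of the stored labels.
#'
#' @param a,b `species_params` objects.
#' @param rules A `mixing_rules` object; default geometric rule, no overrides.
#' @return An object of class `pair_potential_spec` with fields `species_a`,
#'   `species_b`, `epsilon_ab`, `sigma_ab`, `q_a`, `q_b` and `origin`
#'   (`"combined"` or `"override"`).
#' @export
combine_pair <- function(a, b, rules = mixing_rules()) {
  stopifnot(inherits(a, "species_params"), inherits(b, "species_params"),
            inherits(rules, "mixing_rules"))
  ov <- find_override(rules, a$label, b$label)
  if (!is.null(ov)) {
    eps <- ov$epsilon; sig <- ov$sigma; origin <- "override"
  } else {
    eps <- sqrt(a$epsilon * b$epsilon)
    sig <- switch(rules$default_rule,
                  geometric = sqrt(a$sigma * b$sigma),
                  lorentz_berthelot = (a$sigma + b$sigma) / 2)
    origin <- "combined"
  }
  structure(list(species_a = a$label, species_b = b$label,
                 epsilon_ab = eps, sigma_ab = sig,
                 q_a = a$charge, q_b = b$charge, origin = origin),
            class = "pair_potential_spec")
}

#' Evaluate a pair potential on a distance grid
#'
#' Sum of the Lennard-Jones term and, when `include_coulomb = TRUE`, the
#' point-charge Coulomb term of the pair specification.
#'
#' @param r Distance(s), Angstrom, strictly positive.
#' @param spec A `pair_potential_spec`.
#' @param include_coulomb Include the Coulomb term? Default `FALSE`: the
#'   descriptor is usually analysed for the van der Waals part alone.
#' @return Energy in kcal/mol, vectorised over `r`.
#' @export
pair_energy <- function(r, spec, include_coulomb = FALSE) {
  stopifnot(inherits(spec, "pair_potential_spec"))
  e <- lj_energy(r, spec$epsilon_ab, spec$sigma_ab)
  if (include_coulomb) e <- e + coulomb_energy(r, spec$q_a, spec$q_b)
  e
}

#' @export
print.pair_potential_spec <- function(x, ...) {
  cat(sprintf("Pair potential %s-%s (%s): epsilon = %g kcal/mol, sigma = %g A, q = (%g, %g) e\n",
              x$species_a, x$species_b, x$origin,
              x$epsilon_ab, x$sigma_ab, x$q_a, x$q_b))
  invisible(x)
}

#' Read a force-field parameter table
#'
#' The file is plain structured text with two sections. Lines starting with
#' `#` and blank lines are ignored.
#'
#' ```
#' [species]
#' # label  epsilon  sigma  charge
#' F    0.053  2.95  -0.12
#' C_F  0.066  3.50   0.36
#'
#' [pair_overrides]        # optional
#' # label_a  label_b  epsilon  sigma
#' H  F  0.025  2.90
#' ```
#'
#' @param path Path to the force-field file.
#' @param default_rule Combination rule applied to pairs without an override;
#'   see [mixing_rules()].
#' @return An object of class `forcefield`: a list with `species` (named list
#'   of [species_params()]) and `rules` (a [mixing_rules()] object).
#' @export
read_forcefield <- function(path, default_rule = "geometric") {
  if (!file.exists(path)) stop("force-field file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  species <- list()
  ov <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% c("species", "pair_overrides"))
        stop("unknown force-field section [", section, "]", call. = FALSE)
      next
    }
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (section == "species") {
      if (length(tok) < 3L)
        stop("malformed species line: '", ln, "'", call. = FALSE)
      q <- if (length(tok) >= 4L) as.numeric(tok[4L]) else 0
      if (tok[1L] %in% names(species))
        stop("duplicate species label '", tok[1L], "' in force field", call. = FALSE)
      species[[tok[1L]]] <- species_params(tok[1L], as.numeric(tok[2L]),
                                           as.numeric(tok[3L]), q)
    } else if (section == "pair_overrides") {
      if (length(tok) != 4L)
        stop("malformed pair_overrides line: '", ln, "'", call. = FALSE)
      ov[[length(ov) + 1L]] <- data.frame(
        species_a = tok[1L], species_b = tok[2L],
        epsilon = as.numeric(tok[3L]), sigma = as.numeric(tok[4L]),
        stringsAsFactors = FALSE)
    } else {
      stop("content before any [section] header: '", ln, "'", call. = FALSE)
    }
  }
  if (length(species) == 0L)
    stop("force-field file declares no species", call. = FALSE)
  overrides <- if (length(ov)) do.call(rbind, ov) else NULL
  structure(list(species = species,
                 rules = mixing_rules(default_rule, overrides)),
            class = "forcefield")
}

#' Write a force-field table in the format of [read_forcefield()]
#'
#' @param ff A `forcefield` object.
#' @param path Output path.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "forcefield"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("[species]", con)
  writeLines("# label epsilon_kcal_mol sigma_A charge_e", con)
  for (sp in ff$species)
    writeLines(sprintf("%s %.10g %.10g %.10g", sp$label, sp$epsilon,
                       sp$sigma, sp$charge), con)
  ov <- ff$rules$overrides
  if (!is.null(ov) && nrow(ov)) {
    writeLines(c("", "[pair_overrides]", "# label_a label_b epsilon_kcal_mol sigma_A"), con)
    for (i in seq_len(nrow(ov)))
      writeLines(sprintf("%s %s %.10g %.10g", ov$species_a[i], ov$species_b[i],
                         ov$epsilon[i], ov$sigma[i]), con)
  }
  invisible(path)
}

#' Build the full table of pair-potential specs for a force field
#'
#' @param ff A `forcefield` object.
#' @param labels Optional subset of species labels; default all, in file order.
#' @return Named list of `pair_potential_spec`, one per unordered pair
#'   (including self pairs), named `"a|b"`.
#' @export
all_pair_specs <- function(ff, labels = NULL) {
  stopifnot(inherits(ff, "forcefield"))
  if (is.null(labels)) labels <- names(ff$species)
  missing <- setdiff(labels, names(ff$species))
  if (length(missing))
    stop("species not in force field: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (i in seq_along(labels)) for (j in i:length(labels)) {
    a <- labels[i]; b <- labels[j]
    out[[paste(a, b, sep = "|")]] <-
      combine_pair(ff$species[[a]], ff$species[[b]], ff$rules)
  }
  out
}
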