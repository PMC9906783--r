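#' Radiative rate of a single triplet sublevel
#'
#' Spin-orbit coupling splits the emitting T1 state of an iridium phosphor
#' into three sublevels (zero-field splitting); each sublevel i decays
#' radiatively at
#' \deqn{k_i = \frac{4}{3 t_0} \alpha_0^3 \, \Delta E_i^3 \sum_{\alpha \in
#'   \{x,y,z\}} |M_\alpha^i|^2}
#' where \eqn{\Delta E_i} is the sublevel excitation energy and
#' \eqn{M_\alpha^i} the transition dipole components, both in atomic
#' units; \eqn{t_0} is the atomic unit of time and \eqn{\alpha_0} the
#' fine-structure constant, so `k_i` is returned in 1/s. A zero dipole
#' gives a non-emissive sublevel (`rate_s = 0`, infinite lifetime).
#'
#' @param energy_hartree sublevel excitation energy in hartree (> 0).
#' @param dipole_au length-3 numeric transition dipole (a.u.).
#' @return list with `rate_s` (1/s) and `lifetime_s` (s, possibly `Inf`).
#' @export
radiative_rate <- function(energy_hartree, dipole_au) {
  if (energy_hartree <= 0) stop("excitation energy must be positive")
  stopifnot(length(dipole_au) == 3, all(is.finite(dipole_au)))
  k <- (4 / 3) * .phys$alpha0^3 * energy_hartree^3 * sum(dipole_au^2) /
    .phys$t0_s
  list(rate_s = k, lifetime_s = if (k > 0) 1 / k else Inf)
}

#' Construct a validated set of three triplet sublevels
#'
#' @param energies_hartree three excitation energies (hartree); sorted
#'   ascending internally.
#' @param dipoles_au 3 x 3 matrix of transition dipoles (rows = sublevels,
#'   matched to `energies_hartree` before sorting).
#' @return object of class `sublevel_set` with energies, dipoles, rates
#'   and the gaps dE12, dE13 (hartree).
#' @export
sublevel_set <- function(energies_hartree, dipoles_au) {
  stopifnot(length(energies_hartree) == 3)
  dipoles_au <- as.matrix(dipoles_au)
  stopifnot(nrow(dipoles_au) == 3, ncol(dipoles_au) == 3)
  o <- order(energies_hartree)
  e <- energies_hartree[o]
  m <- dipoles_au[o, , drop = FALSE]
  rates <- vapply(1:3, function(i) radiative_rate(e[i], m[i, ])$rate_s,
                  numeric(1))
  structure(list(energies_hartree = e, dipoles_au = m, rates_s = rates,
                 dE12 = e[2] - e[1], dE13 = e[3] - e[1]),
            class = "sublevel_set")
}

#' Boltzmann-averaged radiative lifetime of the T1 manifold
#'
#' Thermal population of the three zero-field-split sublevels gives the
#' observable radiative lifetime
#' \deqn{\tau = \frac{1 + e^{-\Delta E_{1,2}/k_B T} +
#'   e^{-\Delta E_{1,3}/k_B T}}{k_1 + k_2 e^{-\Delta E_{1,2}/k_B T} +
#'   k_3 e^{-\Delta E_{1,3}/k_B T}}}
#' with gaps in hartree and `T` in kelvin (default 300 K). Nonradiative
#' decay is deliberately excluded. If all three rates are zero the complex
#' is non-emissive and `Inf` is returned.
#'
#' @param set a `sublevel_set`.
#' @param temperature_K temperature in kelvin.
#' @return lifetime in seconds (`Inf` when non-emissive).
#' @export
boltzmann_lifetime <- function(set, temperature_K = 300) {
  stopifnot(inherits(set, "sublevel_set"), temperature_K > 0)
  kT <- .phys$kB_hartree * temperature_K
  w <- c(1, exp(-set$dE12 / kT), exp(-set$dE13 / kT))
  denom <- sum(set$rates_s * w)
  if (denom == 0) return(Inf)
  sum(w) / denom
}

#' Strickler-Berg solvent correction of a radiative lifetime
#'
#' Divides a vacuum radiative lifetime by the squared solvent refractive
#' index (DMSO default n = 1.4793).
#'
#' @param tau_vacuum lifetime (any time unit).
#' @param n solvent refractive index (> 0).
#' @return corrected lifetime in the same unit.
#' @export
strickler_berg_correct <- function(tau_vacuum, n = 1.4793) {
  if (n <= 0) stop("refractive index must be positive")
  tau_vacuum / n^2
}

#' Mean emission energy from the three T1 sublevels
#'
#' Arithmetic mean of the three sublevel excitation energies, reported in
#' eV; the TDDFT analogue of the experimental mean emission energy.
#'
#' @param set a `sublevel_set`.
#' @return energy in eV.
#' @export
mean_emission_energy <- function(set) {
  stopifnot(inherits(set, "sublevel_set"))
  hartree_to_ev(mean(set$energies_hartree))
}

#' Read a triplet-sublevel table (TSV) into sublevel sets
#'
#' Boundary contract for spin-orbit TDDFT output. Expected tab-separated
#' columns: `complex_id`, `sublevel` (1..3), `energy`, `unit` (`"eV"` or
#' `"hartree"`), `mx`, `my`, `mz` (transition dipole components, a.u.).
#' Exactly three sublevels per complex are required; energies in eV are
#' converted to hartree.
#'
#' @param path TSV file path.
#' @return named list of `sublevel_set` objects keyed by complex id.
#' @export
read_sublevel_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("complex_id", "sublevel", "energy", "unit", "mx", "my", "mz")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sublevel table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_unit <- setdiff(unique(df$unit), c("eV", "hartree"))
  if (length(bad_unit)) stop("unknown energy unit tag: ",
                             paste(bad_unit, collapse = ", "))
  df$energy_hartree <- ifelse(df$unit == "hartree", df$energy,
                              ev_to_hartree(df$energy))
  sets <- lapply(split(df, df$complex_id), function(grp) {
    if (nrow(grp) != 3) {
      stop("complex '", grp$complex_id[1], "' has ", nrow(grp),
           " sublevels; exactly 3 are required")
    }
    grp <- grp[order(grp$sublevel), ]
    sublevel_set(grp$energy_hartree, as.matrix(grp[, c("mx", "my", "mz")]))
  })
  sets
}

#' Radiative-lifetime post-processing of a sublevel table
#'
#' Convenience wrapper: reads the TSV, computes per-sublevel rates, the
#' Boltzmann-averaged lifetime with Strickler-Berg solvent correction, and
#' the mean emission energy.
#'
#' @param path TSV path (see [read_sublevel_table()]).
#' @param temperature_K temperature (default 300 K).
#' @param refractive_index solvent refractive index (default DMSO, 1.4793).
#' @return data.frame with `complex_id`, `k1_s`, `k2_s`, `k3_s`,
#'   `lifetime_us`, `em_mean_eV`.
#' @export
lifetimes_from_table <- function(path, temperature_K = 300,
                                 refractive_index = 1.4793) {
  sets <- read_sublevel_table(path)
  rows <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    tau <- strickler_berg_correct(
      boltzmann_lifetime(s, temperature_K), refractive_index)
    data.frame(complex_id = id, k1_s = s$rates_s[1], k2_s = s$rates_s[2],
               k3_s = s$rates_s[3], lifetime_us = tau * 1e6,
               em_mean_eV = mean_emission_energy(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
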