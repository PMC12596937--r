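# Transcription kinetics: salt-dependent promoter detachment, pH modulation,
# Mg.NTP saturation, and the lumped elongation-limited rate law.

#' Sequence specification of the RNA construct
#'
#' Base composition of the transcript. Transcription is assumed to initiate
#' with A then G (the prerequisite for AG cap-analog competition at
#' initiation). Molar mass is computed from per-residue nucleotide
#' monophosphate masses unless supplied explicitly.
#'
#' @param n_a,n_u,n_c,n_g per-base counts (nucleotides).
#' @param starts_ag logical; transcript starts 5'-A-G.
#' @param molar_mass optional molar mass override (g/mol).
#' @return an `ivt_sequence` list with `length`, counts, `molar_mass`.
#' @export
ivt_sequence <- function(n_a, n_u, n_c, n_g, starts_ag = TRUE,
                         molar_mass = NULL) {
  counts <- c(A = n_a, U = n_u, C = n_c, G = n_g)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("base counts must be nonnegative integers")
  res_mass <- c(A = 329.21, U = 306.17, C = 305.18, G = 345.21)
  mm <- molar_mass %||% (sum(counts * res_mass) + 18.02)
  structure(list(length = sum(counts), counts = counts,
                 starts_ag = isTRUE(starts_ag), molar_mass = mm),
            class = "ivt_sequence")
}

#' Read a sequence specification from a FASTA file
#'
#' Counts bases of the first record; T is read as U (template convention:
#' the supplied sequence is the transcript).
#' @param path FASTA file.
#' @param ... passed to [ivt_sequence()].
#' @export
read_ivt_sequence <- function(path, ...) {
  lines <- readLines(path)
  seqs <- lines[!startsWith(lines, ">")]
  s <- toupper(paste(seqs, collapse = ""))
  s <- chartr("T", "U", s)
  bad <- setdiff(strsplit(s, "")[[1]], c("A", "U", "C", "G"))
  if (length(bad)) stop("non-AUCG characters in sequence: ",
                        paste(unique(bad), collapse = ""))
  n <- vapply(c("A", "U", "C", "G"),
              function(b) lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))),
              integer(1))
  ivt_sequence(n_a = n[["A"]], n_u = n[["U"]], n_c = n[["C"]], n_g = n[["G"]], ...)
}

#' @export
print.ivt_sequence <- function(x, ...) {
  cat("<ivt_sequence>", x$length, "nt; counts",
      paste(names(x$counts), x$counts, collapse = " "),
      "; molar mass", format(x$molar_mass, big.mark = ","), "g/mol\n")
  invisible(x)
}

#' Kinetic parameters of the transcription rate law
#'
#' @param k_off_1M promoter detachment rate scale at 1 M effective salt
#'   (s^-1). 10^3.93 describes the salt-sensitive reference construct;
#'   10^2.93 (the default) ordinary constructs.
#' @param n_salt exponent of the effective-salt power law (> 0).
#' @param k_on polymerase-promoter association rate constant (M^-1 s^-1);
#'   with `k_off` it sets the dissociation constant Kd = k_off/k_on.
#' @param k_cat RNA chains completed per second per occupied promoter
#'   (s^-1), i.e. elongation-limited throughput for the whole transcript.
#' @param K_M_ntp half-saturation constant for each Mg.NTP complex (M),
#'   shared across the four NTPs.
#' @param K_a,K_b acid- and base-side constants of the pH response factor
#'   Gamma_pH (M). The factor peaks at [H+] = sqrt(K_a K_b).
#' @param protons_per_ntp bookkeeping stoichiometry of proton release per
#'   NTP incorporated. Informational: the reactor's charge accounting makes
#'   the pH trajectory emerge from speciation, and at pH near 8 it releases
#'   almost exactly one proton equivalent per NTP.
#' @return an `ivt_kinetics` parameter list.
#' @export
ivt_kinetics <- function(k_off_1M = 10^2.93, n_salt = 5.0, k_on = 1e7,
                         k_cat = 0.017, K_M_ntp = 1.5e-4,
                         K_a = 1e-7, K_b = 1e-9, protons_per_ntp = 1) {
  p <- list(k_off_1M = k_off_1M, n_salt = n_salt, k_on = k_on, k_cat = k_cat,
            K_M_ntp = K_M_ntp, K_a = K_a, K_b = K_b,
            protons_per_ntp = protons_per_ntp)
  if (any(unlist(p) <= 0)) stop("all kinetic parameters must be positive")
  structure(p, class = "ivt_kinetics")
}

#' Catalyst state (DNA template and active polymerase)
#'
#' @param dna_nM,polymerase_nM concentrations in nM.
#' @return an `ivt_catalysts` list with concentrations in M.
#' @export
ivt_catalysts <- function(dna_nM = 150, polymerase_nM = 200) {
  if (dna_nM < 0 || polymerase_nM < 0) stop("catalyst concentrations must be >= 0")
  structure(list(dna = dna_nM * 1e-9, polymerase = polymerase_nM * 1e-9),
            class = "ivt_catalysts")
}

#' Promoter detachment rate constant
#'
#' Power law in the effective salt concentration:
#' \eqn{k_{off} = k_{off,1M} [salt]^{n_{salt}}}. Zero salt gives zero
#' detachment (the irreversible-binding limit).
#'
#' @param effective_salt effective salt concentration (M), >= 0.
#' @param params an [ivt_kinetics()] set.
#' @return detachment rate constant (s^-1), vectorized over salt.
#' @export
k_off <- function(effective_salt, params = ivt_kinetics()) {
  stopifnot(all(effective_salt >= 0))
  params$k_off_1M * effective_salt^params$n_salt
}

#' pH modulation factor of the rate constants
#'
#' Classical diprotic enzyme pH response,
#' \eqn{\Gamma_{pH} = (1 + [H^+]/K_a + K_b/[H^+])^{-1}}, in (0, 1], with a
#' single maximum at \eqn{[H^+] = \sqrt{K_a K_b}}.
#'
#' @param pH solution pH (vectorized).
#' @param params an [ivt_kinetics()] set.
#' @export
gamma_pH <- function(pH, params = ivt_kinetics()) {
  h <- 10^(-pH)
  1 / (1 + h / params$K_a + params$K_b / h)
}

#' Equilibrium promoter occupancy
#'
#' Fraction of DNA promoters bound by polymerase at binding equilibrium with
#' dissociation constant Kd = k_off/k_on, from the exact two-species binding
#' quadratic (no excess-polymerase approximation).
#'
#' @param catalysts an [ivt_catalysts()] state.
#' @param koff detachment rate constant (s^-1).
#' @param params an [ivt_kinetics()] set.
#' @return occupancy in [0, 1].
#' @export
promoter_occupancy <- function(catalysts, koff, params = ivt_kinetics()) {
  D <- catalysts$dna; P <- catalysts$polymerase
  if (D <= 0) return(0)
  if (P <= 0) return(0)
  Kd <- koff / params$k_on
  if (Kd <= 0) return(min(P, D) / D)
  b <- P + D + Kd
  PD <- (b - sqrt(b^2 - 4 * P * D)) / 2
  min(max(PD / D, 0), 1)
}

# product of Michaelis terms over the four Mg.NTP complexes
ntp_saturation <- function(spec, params) {
  cplx <- c("MgATP2-", "MgUTP2-", "MgCTP2-", "MgGTP2-")
  sat <- 1
  for (s in cplx) {
    c_s <- spec$species[s]
    c_s <- if (is.na(c_s)) 0 else unname(c_s)
    sat <- sat * c_s / (params$K_M_ntp + c_s)
  }
  sat
}

#' Instantaneous transcription rate
#'
#' Lumped elongation-limited rate law: completed transcripts per volume and
#' time, \eqn{r = k_{cat} [DNA] \phi_{occ} \Gamma_{pH} \prod_i S_i}, where
#' \eqn{\phi_{occ}} is the equilibrium promoter occupancy at the current
#' effective salt and \eqn{S_i} are Michaelis saturation terms in the free
#' Mg.NTP complex concentrations.
#'
#' @param spec a converged [solve_speciation()] result for the current state.
#' @param catalysts an [ivt_catalysts()] state.
#' @param params an [ivt_kinetics()] set.
#' @param seq an [ivt_sequence()] (carried for interface symmetry; the
#'   lumped law already absorbs length into `k_cat`).
#' @return RNA production rate (M/s).
#' @export
transcription_rate <- function(spec, catalysts, params = ivt_kinetics(),
                               seq = NULL) {
  rate_factors(spec, catalysts, params)$rate
}

#' Transcription rate with its multiplicative factors
#'
#' Exposes each factor of the rate law separately (occupancy, pH factor,
#' NTP saturation, detachment constant) for rate-decline attribution.
#'
#' @inheritParams transcription_rate
#' @return list with `rate` (M/s), `occupancy`, `gamma`, `saturation`,
#'   `k_off` (s^-1), `effective_salt` (M).
#' @export
rate_factors <- function(spec, catalysts, params = ivt_kinetics()) {
  stopifnot(inherits(spec, "ivt_speciation"))
  ko <- k_off(spec$effective_salt, params)
  occ <- promoter_occupancy(catalysts, ko, params)
  g <- gamma_pH(spec$pH, params)
  sat <- ntp_saturation(spec, params)
  list(rate = params$k_cat * catalysts$dna * occ * g * sat,
       occupancy = occ, gamma = g, saturation = sat, k_off = ko,
       effective_salt = spec$effective_salt)
}
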