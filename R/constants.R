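#' Equilibrium constant set for IVT solution speciation
#'
#' Builds the thermodynamic description of the IVT solution used by
#' [solve_speciation()]: a tableau of aqueous species formed from the
#' component basis (H+, Mg2+, the four NTPs, orthophosphate, pyrophosphate,
#' tris, acetate, cap analog), their cumulative formation constants
#' (log10 beta at 25 C, infinite-dilution scale, from critically evaluated
#' stability-constant compilations), formal charges, and the per-species
#' effective-salt weights \eqn{\omega_{ion}}.
#'
#' The effective-salt weights shipped here are a synthetic calibration: they
#' reproduce the qualitative orderings that characterize IVT rate inhibition
#' (chloride-bearing salts more disruptive than acetate at equal molarity;
#' free Mg2+ strongly disruptive per mole), and should be replaced with
#' system-specific values when available. The solubility product refers to
#' anhydrous Mg3(PO4)2.
#'
#' @param overrides named list of replacements. Recognized names:
#'   `logK` (named numeric, per species), `omega` (named numeric, per species
#'   or spectator), `Ksp_Mg3PO42` (scalar), `Kw` (scalar, as pKw).
#' @return An object of class `ivt_constants`: list with the species tableau
#'   (`species`, `stoich`, `logK`, `charge`, `omega`), spectator weights
#'   (`omega_spectator`), `Ksp_Mg3PO42`, and a `version` tag.
#' @export
ivt_constants <- function(overrides = list()) {
  comp <- c("H", "Mg", "ATP", "UTP", "CTP", "GTP",
            "Pi", "PPi", "tris", "Ac", "cap")

  # species table: name, stoichiometry over components, log10 beta, charge,
  # omega (effective-salt weight). Free basis species have logK = 0.
  def <- list(
    #          H  Mg  A  U  C  G Pi PP tr Ac cp   logK     z   omega
    `H+`    = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,  0,       +1, 0),
    `Mg2+`  = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0,  0,       +2, 3.0),
    `OH-`   = c(-1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -13.997, -1, 0)
  )
  ntp <- c("ATP", "UTP", "CTP", "GTP")
  for (k in seq_along(ntp)) {
    n <- ntp[k]
    e <- function(H, Mg) { v <- numeric(11); v[1] <- H; v[2] <- Mg; v[2 + k] <- 1; v }
    def[[paste0(n, "4-")]]     <- c(e(0, 0),  0.00, -4, 1.0)
    def[[paste0("H", n, "3-")]] <- c(e(1, 0),  6.50, -3, 0.5)
    def[[paste0("H2", n, "2-")]] <- c(e(2, 0), 10.50, -2, 0.25)
    def[[paste0("Mg", n, "2-")]] <- c(e(0, 1),  4.29, -2, 0.5)
    def[[paste0("MgH", n, "-")]] <- c(e(1, 1),  8.80, -1, 0.25)
  }
  pie <- function(H, Mg, i) { v <- numeric(11); v[1] <- H; v[2] <- Mg; v[i] <- 1; v }
  def$`PO43-`   <- c(pie(0, 0, 7),  0.000, -3, 0.5)
  def$`HPO42-`  <- c(pie(1, 0, 7), 12.375, -2, 0.3)
  def$`H2PO4-`  <- c(pie(2, 0, 7), 19.573, -1, 0.3)
  def$`H3PO4`   <- c(pie(3, 0, 7), 21.721,  0, 0)
  def$`MgHPO4`  <- c(pie(1, 1, 7), 15.245,  0, 0)
  def$`PPi4-`   <- c(pie(0, 0, 8),  0.000, -4, 1.0)
  def$`HPPi3-`  <- c(pie(1, 0, 8),  9.400, -3, 0.5)
  def$`MgPPi2-` <- c(pie(0, 1, 8),  5.410, -2, 0.5)
  def$`tris`    <- c(pie(0, 0, 9),  0.000,  0, 0)
  def$`trisH+`  <- c(pie(1, 0, 9),  8.070, +1, 1.0)
  def$`Ac-`     <- c(pie(0, 0, 10), 0.000, -1, 0.25)
  def$`HAc`     <- c(pie(1, 0, 10), 4.756,  0, 0)
  def$`cap4-`   <- c(pie(0, 0, 11), 0.000, -4, 1.0)

  m <- do.call(rbind, def)
  species <- rownames(m)
  stoich <- m[, 1:11, drop = FALSE]
  colnames(stoich) <- comp
  logK <- m[, 12]
  charge <- m[, 13]
  omega <- m[, 14]
  names(logK) <- names(charge) <- names(omega) <- species

  omega_spectator <- c(sodium = 0.5, chloride = 1.5, strong_base = 0.5,
                       rna_backbone = 0.0)

  x <- structure(list(
    components = comp,
    species = species,
    stoich = stoich,
    logK = logK,
    charge = charge,
    omega = omega,
    omega_spectator = omega_spectator,
    Ksp_Mg3PO42 = 1.0e-24,
    version = "ivtsim-constants-1"
  ), class = "ivt_constants")

  if (length(overrides)) {
    if (!is.null(overrides$logK)) {
      bad <- setdiff(names(overrides$logK), x$species)
      if (length(bad)) stop("unknown species in logK override: ",
                            paste(bad, collapse = ", "))
      x$logK[names(overrides$logK)] <- overrides$logK
    }
    if (!is.null(overrides$omega)) {
      for (nm in names(overrides$omega)) {
        if (nm %in% x$species) x$omega[nm] <- overrides$omega[[nm]]
        else if (nm %in% names(x$omega_spectator))
          x$omega_spectator[nm] <- overrides$omega[[nm]]
        else stop("unknown species in omega override: ", nm)
      }
    }
    if (!is.null(overrides$Ksp_Mg3PO42)) x$Ksp_Mg3PO42 <- overrides$Ksp_Mg3PO42
    if (!is.null(overrides$Kw)) x$logK["OH-"] <- -abs(overrides$Kw)
    extra <- setdiff(names(overrides), c("logK", "omega", "Ksp_Mg3PO42", "Kw"))
    if (length(extra)) stop("unknown override field(s): ",
                            paste(extra, collapse = ", "))
  }
  if (x$Ksp_Mg3PO42 <= 0) stop("Ksp must be > 0")
  x
}

#' @export
print.ivt_constants <- function(x, ...) {
  cat("<ivt_constants> ", x$version, "\n", sep = "")
  cat(" ", length(x$species), "species over", length(x$components),
      "components; Ksp(Mg3(PO4)2) =", format(x$Ksp_Mg3PO42), "\n")
  invisible(x)
}

#' Write / read an equilibrium constants file
#'
#' Serializes an `ivt_constants` object to a structured YAML file (one record
#' per species with stoichiometry, log10 K, charge, omega) and reads it back.
#'
#' @param constants an `ivt_constants` object.
#' @param path file path.
#' @return `read_ivt_constants()` returns an `ivt_constants` object.
#' @export
write_ivt_constants <- function(constants, path) {
  stopifnot(inherits(constants, "ivt_constants"))
  recs <- lapply(constants$species, function(s) {
    st <- constants$stoich[s, ]
    list(stoichiometry = as.list(st[st != 0]),
         log10K = unname(constants$logK[s]),
         charge = unname(constants$charge[s]),
         omega = unname(constants$omega[s]))
  })
  names(recs) <- constants$species
  yaml::write_yaml(list(
    version = constants$version,
    Ksp_Mg3PO42 = constants$Ksp_Mg3PO42,
    omega_spectator = as.list(constants$omega_spectator),
    species = recs
  ), path)
  invisible(path)
}

#' @rdname write_ivt_constants
#' @export
read_ivt_constants <- function(path) {
  y <- yaml::read_yaml(path)
  base <- ivt_constants()
  if (!identical(sort(names(y$species)), sort(base$species)))
    stop("constants file species set differs from the built-in tableau; ",
         "extend ivt_constants() instead")
  logK <- vapply(y$species, function(r) r$log10K, numeric(1))
  omega <- vapply(y$species, function(r) r$omega, numeric(1))
  ov <- list(logK = logK, omega = c(omega, unlist(y$omega_spectator)),
             Ksp_Mg3PO42 = y$Ksp_Mg3PO42)
  out <- ivt_constants(ov)
  out$version <- y$version %||% out$version
  out
}
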