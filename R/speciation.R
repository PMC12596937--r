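#' @importFrom rlang %||%
NULL

# ---- tableau preparation -------------------------------------------------

# Precompute fast-access structures from an ivt_constants object.
# Cached on the constants object via an attribute so repeated speciation
# calls (ODE right-hand sides) pay no setup cost.
prep_tableau <- function(constants) {
  tab <- attr(constants, ".tableau")
  if (!is.null(tab)) return(tab)
  A <- constants$stoich
  tab <- list(
    A = A,
    lnbeta = constants$logK * log(10),
    z = constants$charge,
    omega = constants$omega,
    omega_spec = constants$omega_spectator,
    comp = constants$components,
    species = constants$species,
    Ksp = constants$Ksp_Mg3PO42,
    # reducibility for the nested-bisection fallback: each species holds at
    # most one ligand (non-H, non-Mg component, stoich 0/1) and 0/1 Mg
    reducible = {
      lig_cols <- setdiff(constants$components, c("H", "Mg"))
      L <- A[, lig_cols, drop = FALSE]
      all(L %in% c(0, 1)) && all(rowSums(L) <= 1) && all(A[, "Mg"] %in% c(0, 1))
    }
  )
  tab
}

# totals vector (M, .solution_fields order) -> per-component totals + fixed charge
totals_to_components <- function(tot) {
  Tcomp <- c(H = NA_real_, Mg = tot[[1]], ATP = tot[[2]], UTP = tot[[3]],
             CTP = tot[[4]], GTP = tot[[5]], Pi = tot[[7]], PPi = tot[[8]],
             tris = tot[[9]], Ac = tot[[10]], cap = tot[[6]])
  fixed_charge <- tot[[11]] + tot[[13]] - tot[[12]] - tot[[14]]
  fixed_abs <- tot[[11]] + tot[[13]] + tot[[12]] + tot[[14]]
  list(T = Tcomp, fixed_charge = fixed_charge, fixed_abs = fixed_abs)
}

# ---- core solver ---------------------------------------------------------

# Solve the speciation equilibria for a totals vector (M, .solution_fields
# order). Damped Newton on ln(free component concentrations) with analytic
# Jacobian; guaranteed nested-bisection fallback on the proton condition.
# Returns a plain list (no class) for speed inside ODE right-hand sides.
speciate_core <- function(tot, tab, start = NULL, tol = 1e-10, max_iter = 100) {
  tc <- totals_to_components(tot)
  Tcomp <- tc$T
  comp <- tab$comp
  active <- c(TRUE, Tcomp[-1] > 0)      # H always active
  names(active) <- comp
  act <- comp[active]
  # species involving only active components (negative H stoich, e.g. OH-, ok)
  inact_cols <- tab$A[, !active, drop = FALSE]
  sp_ok <- rowSums(abs(inact_cols)) == 0
  A <- tab$A[sp_ok, active, drop = FALSE]
  lnb <- tab$lnbeta[sp_ok]
  z <- tab$z[sp_ok]
  nact <- length(act)
  iH <- 1L

  Ta <- Tcomp[act]
  scale_T <- pmax(Ta, 1e-12); scale_T[iH] <- 1  # H row scaled separately

  # initial guess
  x <- if (!is.null(start) && length(start) == nact && all(is.finite(start))) {
    start
  } else {
    x0 <- log(pmax(Ta / 2, 1e-12)); x0[iH] <- log(1e-7); x0
  }

  eval_F <- function(x) {
    s <- exp(lnb + drop(A %*% x))
    Fv <- drop(crossprod(A, s)) - Ta
    Q <- sum(z * s) + tc$fixed_charge
    Sabs <- sum(abs(z) * s) + tc$fixed_abs
    Fv[iH] <- Q
    list(s = s, Fv = Fv, Sabs = max(Sabs, 1e-14))
  }
  merit <- function(ev) {
    r <- abs(ev$Fv) / scale_T
    r[iH] <- abs(ev$Fv[iH]) / ev$Sabs
    max(r)
  }

  ev <- eval_F(x)
  m0 <- merit(ev)
  iter <- 0L
  ok <- FALSE
  while (iter < max_iter) {
    if (m0 <= tol) { ok <- TRUE; break }
    iter <- iter + 1L
    As <- A * ev$s
    J <- crossprod(A, As)                       # J[j,k] = sum a_ij a_ik s_i
    J[iH, ] <- drop(crossprod(As, z))           # charge row
    dx <- tryCatch(solve(J, -ev$Fv), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) break
    cap <- max(abs(dx))
    if (cap > 3) dx <- dx * (3 / cap)
    t <- 1
    improved <- FALSE
    for (ls in 1:25) {
      xn <- x + t * dx
      evn <- eval_F(xn)
      mn <- merit(evn)
      if (is.finite(mn) && mn < m0) {
        x <- xn; ev <- evn; m0 <- mn; improved <- TRUE; break
      }
      t <- t / 2
    }
    if (!improved) break
  }
  if (!ok && m0 <= 1e-8) ok <- TRUE  # accept spec-level tolerance

  if (!ok) {
    bis <- speciate_bisect(Ta, tc, A, lnb, z, iH, tab, act, tol)
    if (is.null(bis)) {
      return(list(converged = FALSE, residual = m0, iterations = iter,
                  x = x, active = act))
    }
    x <- bis; ev <- eval_F(x); m0 <- merit(ev); iter <- iter + 1000L
    ok <- m0 <= 1e-8
  }

  s <- ev$s
  names(s) <- tab$species[sp_ok]
  h <- unname(exp(x[iH]))
  list(converged = ok, residual = m0, iterations = iter, x = x, active = act,
       species = s, pH = -log10(h), sp_ok = sp_ok)
}

# Nested bisection fallback: outer on ln[H+] (charge balance is strictly
# increasing in H+), inner on ln[Mg2+] (Mg balance strictly increasing),
# ligand free concentrations in closed form. Requires the reducible tableau
# structure (at most one ligand and one Mg per species).
speciate_bisect <- function(Ta, tc, A, lnb, z, iH, tab, act, tol) {
  if (!tab$reducible) return(NULL)
  nact <- length(act)
  lig <- setdiff(seq_len(nact), c(iH, which(act == "Mg")))
  iMg <- which(act == "Mg")
  has_mg <- length(iMg) == 1L

  frees_at <- function(lnh, lnm) {
    x <- numeric(nact)
    x[iH] <- lnh
    if (has_mg) x[iMg] <- lnm
    for (j in lig) {
      rows <- A[, j] == 1
      # denominator: sum over species holding this ligand of beta*h^aH*m^aMg
      d <- exp(lnb[rows] + A[rows, iH] * lnh +
                 (if (has_mg) A[rows, iMg] * lnm else 0))
      x[j] <- log(Ta[j]) - log(sum(d))
    }
    x
  }
  mg_res <- function(lnh, lnm) {
    x <- frees_at(lnh, lnm)
    s <- exp(lnb + drop(A %*% x))
    sum(A[, iMg] * s) - Ta[iMg]
  }
  charge_res <- function(lnh) {
    lnm <- NA_real_
    if (has_mg) {
      lo <- log(Ta[iMg]) - 40; hi <- log(Ta[iMg])
      if (mg_res(lnh, lo) > 0) return(NA_real_)
      for (k in 1:70) {
        mid <- (lo + hi) / 2
        if (mg_res(lnh, mid) > 0) hi <- mid else lo <- mid
      }
      lnm <- (lo + hi) / 2
    }
    x <- frees_at(lnh, lnm)
    s <- exp(lnb + drop(A %*% x))
    attr(x, "Q") <- sum(z * s) + tc$fixed_charge
    x
  }
  lo <- log(10^-14.5); hi <- log(10^0.5)
  xlo <- charge_res(lo); xhi <- charge_res(hi)
  if (is.na(attr(xlo, "Q")) || is.na(attr(xhi, "Q"))) return(NULL)
  if (attr(xlo, "Q") > 0 || attr(xhi, "Q") < 0) return(NULL)
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    xm <- charge_res(mid)
    if (attr(xm, "Q") > 0) hi <- mid else lo <- mid
  }
  as.numeric(charge_res((lo + hi) / 2))
}

# ---- user-facing API -----------------------------------------------------

#' Solve the instantaneous ionic speciation of an IVT solution
#'
#' Distributes the conserved totals of an [ivt_solution()] over all aqueous
#' species of the equilibrium tableau by solving the coupled mass-action,
#' mass-balance and electroneutrality equations, and reports pH, free-species
#' concentrations, the effective salt concentration and the Mg3(PO4)2
#' supersaturation. Activities are taken equal to concentrations (ideal
#' solution); an activity-coefficient hook (e.g. a Davies correction) would
#' slot in where species concentrations enter the mass-action laws.
#'
#' The solver works in log-concentration space (concentrations span more
#' than ten orders of magnitude) with a damped Newton iteration and analytic
#' Jacobian, falling back to a guaranteed nested bisection on the proton
#' condition when Newton fails.
#'
#' @param comp an [ivt_solution()].
#' @param constants an [ivt_constants()] set.
#' @param start optional warm start (log free concentrations, as returned in
#'   `$x` of a previous result for the same active component set).
#' @param tol convergence tolerance on scaled mass-balance and charge
#'   residuals (default `1e-10`; must be at least satisfied to `1e-8`).
#' @return An `ivt_speciation` object: list with `species` (named vector of
#'   free concentrations, M), `pH`, `effective_salt` (M), `sigma`
#'   (dimensionless supersaturation), spectator concentrations, convergence
#'   diagnostics (`residual`, `iterations`), and the warm-start vector `x`.
#' @export
solve_speciation <- function(comp, constants = ivt_constants(), start = NULL,
                             tol = 1e-10) {
  stopifnot(inherits(comp, "ivt_solution"), inherits(constants, "ivt_constants"))
  tot <- solution_totals(comp)
  if (any(tot < 0)) stop("negative total concentration")
  tab <- prep_tableau(constants)
  core <- speciate_core(tot, tab, start = start, tol = tol)
  if (!core$converged) {
    stop("speciation failed to converge: scaled residual ",
         format(core$residual), " after ", core$iterations, " iterations")
  }
  build_speciation_result(core, tot, tab)
}

build_speciation_result <- function(core, tot, tab) {
  spect <- c(sodium = tot[[11]], chloride = tot[[12]],
             strong_base = tot[[13]], rna_backbone = tot[[14]])
  eff <- sum(tab$omega[core$sp_ok] * core$species) +
    sum(tab$omega_spec[names(spect)] * spect)
  m <- unname(core$species["Mg2+"]) %||% 0
  p <- unname(core$species["PO43-"]) %||% 0
  m <- if (is.na(m)) 0 else m
  p <- if (is.na(p)) 0 else p
  sigma <- if (m > 0 && p > 0) log(m^3 * p^2 / tab$Ksp) else -Inf
  structure(list(
    species = core$species,
    spectators = spect,
    pH = core$pH,
    effective_salt = eff,
    sigma = sigma,
    residual = core$residual,
    iterations = core$iterations,
    x = core$x,
    active = core$active,
    totals = tot
  ), class = "ivt_speciation")
}

#' @export
print.ivt_speciation <- function(x, ...) {
  cat("<ivt_speciation>\n")
  cat("  pH", round(x$pH, 3),
      " effective salt", round(x$effective_salt * 1000, 2), "mM",
      " sigma", if (is.finite(x$sigma)) round(x$sigma, 3) else "-Inf", "\n")
  cat("  residual", format(x$residual), "in", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
as.data.frame.ivt_speciation <- function(x, ...) {
  data.frame(species = c(names(x$species), names(x$spectators)),
             concentration_M = unname(c(x$species, x$spectators)),
             row.names = NULL)
}

#' Tidy a speciation result into a tibble of species concentrations
#' @param x an `ivt_speciation` object.
#' @param ... unused.
#' @export
tidy.ivt_speciation <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Effective salt concentration of a speciation state
#'
#' The weighted sum \eqn{\sum_i \omega_{ion,i} [ion_i]} over every enumerated
#' ionic complex (plus charged spectators), the lumped driver of
#' polymerase-promoter detachment.
#'
#' @param result a converged `ivt_speciation`.
#' @param constants the `ivt_constants` used to produce it.
#' @return effective salt concentration (M).
#' @export
effective_salt <- function(result, constants = ivt_constants()) {
  stopifnot(inherits(result, "ivt_speciation"))
  om <- constants$omega[names(result$species)]
  if (any(is.na(om)))
    stop("missing omega entry for species: ",
         paste(names(result$species)[is.na(om)], collapse = ", "))
  oms <- constants$omega_spectator[names(result$spectators)]
  if (any(is.na(oms)))
    stop("missing omega entry for spectator: ",
         paste(names(result$spectators)[is.na(oms)], collapse = ", "))
  sum(om * result$species) + sum(oms * result$spectators)
}

#' Thermodynamic supersaturation of magnesium phosphate
#'
#' \eqn{\sigma = \ln([Mg^{2+}]^3 [PO_4^{3-}]^2 / K_{sp})} for anhydrous
#' Mg3(PO4)2. Positive values mean a thermodynamic driving force for
#' precipitation. When either free ion is absent the ionic product is zero
#' and `-Inf` is returned (no driving force, by convention).
#'
#' @param result a converged `ivt_speciation`.
#' @param constants the `ivt_constants` used to produce it.
#' @return dimensionless supersaturation (log scale).
#' @export
supersaturation <- function(result, constants = ivt_constants()) {
  stopifnot(inherits(result, "ivt_speciation"))
  if (constants$Ksp_Mg3PO42 <= 0) stop("Ksp must be > 0")
  m <- result$species["Mg2+"]; p <- result$species["PO43-"]
  m <- if (is.na(m)) 0 else unname(m)
  p <- if (is.na(p)) 0 else unname(p)
  if (m <= 0 || p <= 0) return(-Inf)
  log(m^3 * p^2 / constants$Ksp_Mg3PO42)
}
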