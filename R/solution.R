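#' Solution composition of the IVT reactor
#'
#' Conserved (analytical) total concentrations of every moiety in the
#' reactor or in a feed solution. Speciation redistributes these totals
#' over aqueous species but never creates or destroys them. All arguments
#' are in mM (the user-facing unit); values are stored internally in mol/L.
#'
#' `sodium`, `chloride`, `strong_base` and `rna_backbone` are spectators:
#' they carry charge (and an effective-salt weight) but take part in no
#' protonation or Mg-binding equilibria. `strong_base` counts cation
#' equivalents delivered by e.g. NaOH feeds; `rna_backbone` counts RNA
#' phosphodiester backbone charges (one per incorporated nucleotide).
#'
#' @param mg,atp,utp,ctp,gtp,cap,phosphate,pyrophosphate,tris,acetate totals, mM.
#' @param sodium,chloride,strong_base,rna_backbone spectator totals, mM.
#' @param temperature K (carried; constants are 25 C values).
#' @param na_counterions if `TRUE` (default) sodium is incremented by the
#'   counterion equivalents of the acidic components as supplied
#'   (4 per NTP and cap, 2 per phosphate and pyrophosphate, 1 per acetate),
#'   i.e. components are assumed added as their neutral sodium salts.
#'   Set `FALSE` to specify the full ion inventory yourself.
#' @return An `ivt_solution`: named list of totals in mol/L.
#' @examples
#' sol <- ivt_solution(mg = 12, atp = 5, utp = 5, ctp = 5, gtp = 5,
#'                     tris = 40, chloride = 30)
#' @export
ivt_solution <- function(mg = 0, atp = 0, utp = 0, ctp = 0, gtp = 0,
                         cap = 0, phosphate = 0, pyrophosphate = 0,
                         tris = 0, acetate = 0,
                         sodium = 0, chloride = 0, strong_base = 0,
                         rna_backbone = 0, temperature = 310.15,
                         na_counterions = TRUE) {
  v <- vapply(list(mg = mg, atp = atp, utp = utp, ctp = ctp, gtp = gtp,
                   cap = cap, phosphate = phosphate,
                   pyrophosphate = pyrophosphate, tris = tris,
                   acetate = acetate, sodium = sodium, chloride = chloride,
                   strong_base = strong_base, rna_backbone = rna_backbone),
              function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(v))) stop("non-finite concentration in solution")
  if (any(v < 0)) stop("negative total concentration: ",
                       paste(names(v)[v < 0], collapse = ", "))
  if (na_counterions) {
    v["sodium"] <- v["sodium"] + 4 * (atp + utp + ctp + gtp + cap) +
      2 * (phosphate + pyrophosphate) + acetate
  }
  out <- as.list(v / 1000)  # mM -> M
  out$temperature <- temperature
  structure(out, class = "ivt_solution")
}

# fields that are conserved concentrations (M)
.solution_fields <- c("mg", "atp", "utp", "ctp", "gtp", "cap", "phosphate",
                      "pyrophosphate", "tris", "acetate", "sodium",
                      "chloride", "strong_base", "rna_backbone")

# map solution fields -> tableau components (spectators excluded)
.component_of_field <- c(mg = "Mg", atp = "ATP", utp = "UTP", ctp = "CTP",
                         gtp = "GTP", cap = "cap", phosphate = "Pi",
                         pyrophosphate = "PPi", tris = "tris", acetate = "Ac")

#' @export
print.ivt_solution <- function(x, ...) {
  cat("<ivt_solution> totals (mM):\n")
  v <- unlist(x[.solution_fields]) * 1000
  print(round(v[v > 0], 4))
  invisible(x)
}

#' @export
as.data.frame.ivt_solution <- function(x, ...) {
  data.frame(component = .solution_fields,
             total_mM = unlist(x[.solution_fields]) * 1000,
             row.names = NULL)
}

# internal: numeric vector of totals (M) in .solution_fields order
solution_totals <- function(comp) {
  vapply(.solution_fields, function(f) comp[[f]] %||% 0, numeric(1))
}

# internal: rebuild an ivt_solution from a totals vector (M)
solution_from_totals <- function(tot, temperature = 310.15) {
  out <- as.list(tot)
  names(out) <- .solution_fields
  out$temperature <- temperature
  structure(out, class = "ivt_solution")
}

#' Mix two solutions volumetrically
#'
#' Ideal instantaneous mixing: each total becomes the volume-weighted mean,
#' `(c1 V1 + c2 V2) / (V1 + V2)`.
#'
#' @param a,b `ivt_solution` objects.
#' @param va,vb volumes (any common unit).
#' @return an `ivt_solution`.
#' @export
mix_solutions <- function(a, va, b, vb) {
  stopifnot(inherits(a, "ivt_solution"), inherits(b, "ivt_solution"),
            va >= 0, vb >= 0, va + vb > 0)
  ta <- solution_totals(a); tb <- solution_totals(b)
  solution_from_totals((ta * va + tb * vb) / (va + vb),
                       temperature = (a$temperature * va + b$temperature * vb) / (va + vb))
}
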