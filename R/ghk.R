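## Physical constants (CODATA), fixed for the whole package.
.FARADAY <- 96485.332  # C/mol
.RGAS <- 8.31446       # J/(mol K)

.default_valences <- c(
  K = 1L, Na = 1L, Li = 1L, Rb = 1L, Cs = 1L, H = 1L,
  Ca = 2L, Mg = 2L, Ba = 2L, Sr = 2L, Zn = 2L,
  Cl = -1L, Br = -1L, I = -1L, F = -1L
)

#' Ionic conditions of a patch-clamp recording
#'
#' Describes the solutions on the two sides of an excised inside-out patch
#' (pipette = extracellular face, bath = cytoplasmic face), together with the
#' relative permeability of each ion species. Permeabilities are dimensionless
#' and referenced to K+ (whose permeability, when present, must be exactly 1).
#'
#' @param pipette named numeric vector of pipette-side concentrations (mM);
#'   names are ion species labels such as `"K"`, `"Na"`, `"Ca"`, `"Cl"`.
#' @param bath named numeric vector of bath-side concentrations (mM).
#' @param permeabilities named numeric vector of relative permeabilities;
#'   species not listed are treated as impermeant (permeability 0).
#' @param temperature absolute temperature in K. The default 295.65 K
#'   (22.5 degrees C) is the midpoint of a typical 21-24 degrees C room-temperature
#'   recording session; RT/F is then 25.48 mV.
#' @param valences optional named integer vector overriding the built-in
#'   valence table (needed only for species the table does not know).
#'
#' @return An object of class `"ion_conditions"`: a list with elements
#'   `ions` (data frame with columns `ion`, `valence`, `pipette_mM`,
#'   `bath_mM`, `permeability`) and `temperature`.
#' @export
#' @examples
#' ion_conditions(pipette = c(K = 210, Cl = 210),
#'                bath = c(Na = 210, Cl = 210),
#'                permeabilities = c(K = 1, Na = 1 / 1.21))
ion_conditions <- function(pipette, bath, permeabilities = c(K = 1),
                           temperature = 295.65, valences = NULL) {
  if (is.null(names(pipette)) || is.null(names(bath)))
    stop("'pipette' and 'bath' must be named numeric vectors (mM)")
  ions <- union(names(pipette), names(bath))
  conc <- function(v, ion) if (ion %in% names(v)) unname(v[ion]) else 0
  val_tab <- .default_valences
  if (!is.null(valences)) val_tab[names(valences)] <- as.integer(valences)
  unknown <- setdiff(ions, names(val_tab))
  if (length(unknown))
    stop("unknown valence for ion(s): ", paste(unknown, collapse = ", "),
         "; supply via 'valences'")
  perm <- function(ion)
    if (ion %in% names(permeabilities)) unname(permeabilities[ion]) else 0
  tab <- data.frame(
    ion = ions,
    valence = as.integer(val_tab[ions]),
    pipette_mM = vapply(ions, conc, numeric(1), v = pipette),
    bath_mM = vapply(ions, conc, numeric(1), v = bath),
    permeability = vapply(ions, perm, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(tab$pipette_mM < 0) || any(tab$bath_mM < 0))
    stop("concentrations must be >= 0")
  if (any(tab$permeability < 0)) stop("permeabilities must be >= 0")
  if (!is.numeric(temperature) || temperature < 273 || temperature > 320)
    stop("temperature must lie in [273, 320] K")
  if ("K" %in% names(permeabilities) && permeabilities[["K"]] != 1)
    stop("K+ is the reference species: its permeability must be exactly 1")
  structure(list(ions = tab, temperature = temperature),
            class = "ion_conditions")
}

#' @export
print.ion_conditions <- function(x, ...) {
  cat(sprintf("Ionic conditions (T = %.2f K, RT/F = %.2f mV)\n",
              x$temperature, 1000 * .RGAS * x$temperature / .FARADAY))
  print(x$ions, row.names = FALSE)
  invisible(x)
}

#' Convenience constructor for a monovalent bi-ionic condition
#'
#' One permeant cation species on each side at equal (or stated)
#' concentrations, chloride as the impermeant counter-ion -- the standard
#' configuration for measuring a permeability ratio from the reversal
#' potential.
#'
#' @param p_ratio permeability ratio P(pipette ion)/P(bath ion); the bath ion
#'   receives permeability `1/p_ratio` so that the pipette ion keeps the
#'   reference value 1.
#' @param conc_pipette,conc_bath salt concentrations (mM).
#' @param pipette_ion,bath_ion cation species labels.
#' @param temperature K.
#' @return An `"ion_conditions"` object.
#' @export
bi_ionic_conditions <- function(p_ratio = 1.21, conc_pipette = 210,
                                conc_bath = 210, pipette_ion = "K",
                                bath_ion = "Na", temperature = 295.65) {
  if (p_ratio <= 0) stop("'p_ratio' must be > 0")
  pip <- stats::setNames(c(conc_pipette, conc_pipette), c(pipette_ion, "Cl"))
  bat <- stats::setNames(c(conc_bath, conc_bath), c(bath_ion, "Cl"))
  perms <- stats::setNames(c(1, 1 / p_ratio, 0), c(pipette_ion, bath_ion, "Cl"))
  ion_conditions(pip, bat, perms, temperature = temperature)
}

#' Goldman-Hodgkin-Katz current
#'
#' Constant-field current summed over all permeant species. The membrane
#' potential convention is that of an inside-out patch: V = bath (cytoplasmic)
#' side minus pipette (extracellular) side, and positive current corresponds
#' to cation flow from bath to pipette. Each species contributes
#' `P * z * u * (c_bath - c_pipette * exp(-u)) / (1 - exp(-u))` with
#' `u = zFV/RT`; the removable singularity at V = 0 is replaced by its
#' analytic continuation, so no voltage produces NaN.
#'
#' The absolute scale of a GHK current depends on the permeability
#' coefficients and membrane area, which single-channel work does not resolve;
#' `scale` converts the dimensionless-permeability flux (concentration units,
#' mM) to pA. Use [ghk_conductance_scale()] to calibrate it so that the slope
#' conductance at the reversal potential matches a measured channel
#' conductance.
#'
#' @param v membrane potential(s), mV (bath minus pipette).
#' @param conditions an [ion_conditions()] object.
#' @param scale multiplicative scale converting the raw flux to pA.
#' @return Numeric vector of currents, same length as `v`.
#' @export
ghk_current <- function(v, conditions, scale = 1) {
  stopifnot(inherits(conditions, "ion_conditions"))
  tab <- conditions$ions
  if (all(tab$permeability == 0))
    stop("at least one ion must have nonzero permeability")
  rt <- .RGAS * conditions$temperature
  total <- numeric(length(v))
  for (i in seq_len(nrow(tab))) {
    p <- tab$permeability[i]
    if (p == 0) next
    z <- tab$valence[i]
    cin <- tab$bath_mM[i]     # cytoplasmic face
    cout <- tab$pipette_mM[i] # extracellular face
    u <- z * .FARADAY * v * 1e-3 / rt
    phi <- numeric(length(v))
    small <- abs(u) < 1e-8
    us <- u[!small]
    phi[!small] <- us * (cin - cout * exp(-us)) / (1 - exp(-us))
    # second-order expansion around u = 0
    phi[small] <- (cin - cout) + u[small] * (cin + cout) / 2
    total <- total + p * z * phi
  }
  scale * total
}

#' GHK reversal potential
#'
#' Zero-current voltage of the GHK voltage equation over monovalent cations
#' and monovalent anions (whose concentrations enter with sides swapped).
#' Multivalent species must be impermeant (permeability 0) and are excluded;
#' this matches the treatment of Ca2+ and Mg2+ as impermeant in TRIC-channel
#' selectivity experiments.
#'
#' @param conditions an [ion_conditions()] object.
#' @return Reversal potential in mV (bath-minus-pipette convention, as in
#'   [ghk_current()]).
#' @export
#' @examples
#' cond <- bi_ionic_conditions(p_ratio = 1.21)
#' ghk_reversal(cond)  # about +4.86 mV
ghk_reversal <- function(conditions) {
  stopifnot(inherits(conditions, "ion_conditions"))
  tab <- conditions$ions
  if (all(tab$permeability == 0))
    stop("all permeabilities are zero: reversal potential undefined")
  bad <- abs(tab$valence) > 1 & tab$permeability > 0
  if (any(bad))
    stop("multivalent species must be impermeant (permeability 0): ",
         paste(tab$ion[bad], collapse = ", "))
  cat_i <- tab$valence == 1L
  an_i <- tab$valence == -1L
  num <- sum(tab$permeability[cat_i] * tab$pipette_mM[cat_i]) +
    sum(tab$permeability[an_i] * tab$bath_mM[an_i])
  den <- sum(tab$permeability[cat_i] * tab$bath_mM[cat_i]) +
    sum(tab$permeability[an_i] * tab$pipette_mM[an_i])
  if (num <= 0 || den <= 0)
    stop("no permeant species with nonzero concentration on one side")
  1000 * .RGAS * conditions$temperature / .FARADAY * log(num / den)
}

#' Bi-ionic permeability ratio from a reversal potential
#'
#' Inverts the GHK voltage equation for the monovalent bi-ionic case: with one
#' permeant cation X in the pipette and one permeant cation Y in the bath,
#' `P_X / P_Y = ([Y]_bath / [X]_pipette) * exp(E_rev * F / RT)`. At equal
#' concentrations this reduces to `exp(E_rev * F / RT)`.
#'
#' @param e_rev reversal potential, mV (bath-minus-pipette convention).
#' @param conditions an [ion_conditions()] object whose pipette side holds
#'   exactly one monovalent cation at nonzero concentration and whose bath
#'   side holds exactly one (different or same label is not checked beyond
#'   side exclusivity).
#' @return The dimensionless permeability ratio P(pipette cation)/P(bath
#'   cation).
#' @export
#' @examples
#' cond <- bi_ionic_conditions()
#' bi_ionic_permeability(4.84, cond)  # about 1.21
bi_ionic_permeability <- function(e_rev, conditions) {
  stopifnot(inherits(conditions, "ion_conditions"))
  tab <- conditions$ions
  pip <- tab[tab$valence == 1L & tab$pipette_mM > 0, , drop = FALSE]
  bat <- tab[tab$valence == 1L & tab$bath_mM > 0, , drop = FALSE]
  if (nrow(pip) != 1L || nrow(bat) != 1L)
    stop("bi-ionic case requires exactly one monovalent cation per side ",
         "at nonzero concentration")
  if (pip$pipette_mM <= 0 || bat$bath_mM <= 0)
    stop("bi-ionic concentrations must be > 0")
  rt <- .RGAS * conditions$temperature
  (bat$bath_mM / pip$pipette_mM) * exp(e_rev * 1e-3 * .FARADAY / rt)
}

#' Calibrate the GHK current scale to a slope conductance
#'
#' Returns the `scale` argument for [ghk_current()] such that the slope
#' conductance of the GHK current at the reversal potential equals
#' `conductance` (pS). This anchors simulated I/V data to a measured
#' single-channel conductance.
#'
#' @param conditions an [ion_conditions()] object.
#' @param conductance target slope conductance at the reversal potential, pS.
#' @return Numeric scale (pA per raw flux unit).
#' @export
ghk_conductance_scale <- function(conditions, conductance = 163.7) {
  if (conductance <= 0) stop("'conductance' must be > 0")
  v0 <- ghk_reversal(conditions)
  h <- 0.5 # mV
  slope_raw <- (ghk_current(v0 + h, conditions) -
    ghk_current(v0 - h, conditions)) / (2 * h) # raw units per mV
  if (slope_raw <= 0) stop("degenerate GHK slope at reversal")
  (conductance / 1000) / slope_raw
}
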