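# gas constant, kcal mol^-1 K^-1
R_KCAL <- 1.98720425e-3

#' Binding free energy from a dissociation constant
#'
#' `dG = RT ln(K / 1 M)` with K an equilibrium *dissociation* constant in
#' molar units against the 1 M standard state. Under this convention a
#' sub-molar K gives a negative free energy, and tighter binding (smaller
#' K) is more negative. Assay temperature defaults to 25 C.
#'
#' @param K dissociation constant, molar (> 0).
#' @param temperature kelvin (default 298.15).
#' @return free energy in kcal/mol.
#' @export
dg_from_k <- function(K, temperature = 298.15) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive and finite")
  if (temperature <= 0) stop("temperature must be > 0")
  R_KCAL * temperature * log(K)
}

#' Deuteration shift of the binding free energy
#'
#' `ddG(H -> D) = -RT ln(K_D / K_H)`, positive when the deuterated ligand
#' binds more tightly (K_D < K_H). Equals
#' `dg_from_k(K_H) - dg_from_k(K_D)` identically.
#'
#' @param K_H,K_D dissociation constants (molar) of the protiated and
#'   deuterated species.
#' @param temperature kelvin (default 298.15).
#' @return shift in kcal/mol.
#' @export
ddg_deuteration <- function(K_H, K_D, temperature = 298.15) {
  if (any(c(K_H, K_D) <= 0) || any(!is.finite(c(K_H, K_D)))) {
    stop("binding constants must be positive and finite")
  }
  -R_KCAL * temperature * log(K_D / K_H)
}

#' Convert between pIC50 and molar IC50
#'
#' `IC50 = 10^(-pIC50)` molar; the round trip is exact.
#'
#' @param value pIC50 (dimensionless) or concentration (molar), per
#'   `direction`.
#' @param direction `"to_molar"` (pIC50 -> molar) or `"to_pic50"`
#'   (molar -> pIC50).
#' @return converted value.
#' @export
pic50_convert <- function(value, direction = c("to_molar", "to_pic50")) {
  direction <- match.arg(direction)
  if (direction == "to_molar") return(10^(-value))
  if (any(value <= 0)) stop("molar concentration must be > 0")
  -log10(value)
}

#' @rdname pic50_convert
#' @param pic50 pIC50 value.
#' @export
pic50_to_molar <- function(pic50) pic50_convert(pic50, "to_molar")

#' @rdname pic50_convert
#' @param molar concentration in molar.
#' @export
molar_to_pic50 <- function(molar) pic50_convert(molar, "to_pic50")
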