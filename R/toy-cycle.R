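#' End-to-end deuteration cycle on surrogate fixtures
#'
#' Exercises the whole pipeline without external quantum chemistry: builds
#' an ammonium-like donor hydrogen-bonded to `n_hydr` waters (the
#' hydration-leg cluster) and to `n_inter` acceptors standing in for the
#' receptor site (the interaction-leg cluster), evaluates each species
#' with the surrogate energy model for the protiated form and for its
#' Ubbelohde-contracted (deuterated) form, and books the legs through
#' [deuteration_shift()].
#'
#' Deuteration weakens every individual hydrogen bond under the surrogate
#' model, so each leg's `X(H) - X(D)` difference is negative; the *net*
#' `ddE_BIND` is positive when the hydration leg loses more than the
#' interaction leg (more/stronger hydrogen bonds on the hydration side)
#' and negative in the opposite case. With `eps_hydr = eps_inter` the sign
#' is controlled purely by `n_hydr` vs `n_inter`.
#'
#' @param n_hydr number of waters hydrogen-bonded to the ligand in the
#'   hydration leg (1-4).
#' @param n_inter number of receptor-site acceptors in the interaction
#'   leg (1-4).
#' @param eps_hydr dielectric of the hydration leg (default 78.36,
#'   aqueous).
#' @param eps_inter dielectric of the interaction leg (default 4.0,
#'   protein interior).
#' @param contraction Ubbelohde contraction fraction (default 0.023).
#' @param params base `toy_energy_params`; its `eps` is overridden per
#'   leg.
#' @return a `cycle_result` with method tag `"toy"`.
#' @export
toy_cycle <- function(n_hydr = 3L, n_inter = 1L,
                      eps_hydr = 78.36, eps_inter = 4.0,
                      contraction = 0.023,
                      params = toy_energy_params()) {
  stopifnot(n_hydr >= 1L, n_hydr <= 4L, n_inter >= 1L, n_inter <= 4L)
  leg <- function(n_acc, eps) {
    p <- params; p$eps <- eps
    cl <- build_donor_hub(n_acc)
    parts <- split_donor_hub(cl)
    species <- list(cluster = cl, ligand = parts$ligand,
                    solvent = parts$solvent)
    vapply(c(H = "H", D = "D"), function(iso) {
      e_sp <- vapply(species, function(sp) {
        if (is.null(sp)) return(0)
        if (iso == "D") {
          sp <- apply_ubbelohde(sp, contraction = contraction)$structure
        }
        as.numeric(total_energy(sp, p))
      }, numeric(1))
      # dE_leg = E(cluster) - E(ligand) - E(solvent)
      sum(e_sp * c(1, -1, -1))
    }, numeric(1))
  }
  hydr <- leg(n_hydr, eps_hydr)
  inter <- leg(n_inter, eps_inter)
  deuteration_shift(hydr[["H"]], hydr[["D"]], inter[["H"]], inter[["D"]],
                    method = "toy",
                    eps = c(hydration = eps_hydr, interaction = eps_inter))
}
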