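#' Energy-record tables
#'
#' The thermodynamic-cycle bookkeeping consumes tables of component
#' electronic energies (kcal/mol): one row per (species, isotope state,
#' dielectric, method). Species labels are free but the cycle operations
#' look for `ligand`, `receptor`, `complex`, `ligand_water_cluster` and
#' `water_pentamer`. Energies are electronic only (no zero-point or
#' thermal corrections), matching the convention of the cycle they feed.
#'
#' @param df data.frame with columns `species`, `isotope` ("H" or "D"),
#'   `epsilon` (dielectric, >= 1), `energy_kcal` (finite), `method`
#'   (free-text tag, e.g. "M06-2X" or "toy").
#' @return validated data.frame of class `energy_records`.
#' @export
energy_records <- function(df) {
  need <- c("species", "isotope", "epsilon", "energy_kcal", "method")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  if (!all(df$isotope %in% c("H", "D"))) stop("isotope must be 'H' or 'D'")
  if (any(!is.finite(df$energy_kcal))) stop("non-finite energy")
  if (any(df$epsilon < 1)) stop("dielectric must be >= 1")
  key <- paste(df$species, df$isotope, df$epsilon, df$method)
  if (anyDuplicated(key)) {
    stop("duplicate record: ", key[duplicated(key)][1L])
  }
  rownames(df) <- NULL
  class(df) <- c("energy_records", "data.frame")
  df
}

#' @rdname energy_records
#' @param path TSV path with the same columns.
#' @export
read_energy_records <- function(path) {
  energy_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname energy_records
#' @param records an `energy_records` table.
#' @export
write_energy_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

lookup_energy <- function(records, species, isotope, epsilon = NULL,
                          method = NULL) {
  sel <- records$species == species & records$isotope == isotope
  if (!is.null(epsilon)) sel <- sel & abs(records$epsilon - epsilon) < 1e-9
  if (!is.null(method)) sel <- sel & records$method == method
  hit <- records[sel, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("missing energy record: species '%s', isotope %s, epsilon %s%s",
                 species, isotope,
                 if (is.null(epsilon)) "any" else format(epsilon),
                 if (is.null(method)) "" else paste0(", method ", method)))
  }
  if (nrow(hit) > 1L) {
    stop(sprintf("ambiguous energy record for species '%s' isotope %s: %d matches; specify epsilon/method",
                 species, isotope, nrow(hit)))
  }
  hit
}

#' Hydration-leg energy
#'
#' Homodesmotic hydration scheme: the ligand plus a water pentamer react
#' to the ligand-five-water cluster, conserving the hydrogen-bond count on
#' both sides, so
#' `dE_HYDR = E(ligand.(H2O)5) - E(ligand) - E((H2O)5)`.
#' Each species is looked up at whatever dielectric its record declares
#' (the scheme mixes dielectrics by design); the tags are echoed on the
#' result.
#'
#' @param records an `energy_records` table.
#' @param isotope `"H"` or `"D"`.
#' @param method optional method tag filter.
#' @return hydration energy (kcal/mol) with attributes `eps` (named per
#'   species) and `method`.
#' @export
hydration_energy <- function(records, isotope = c("H", "D"), method = NULL) {
  isotope <- match.arg(isotope)
  cl <- lookup_energy(records, "ligand_water_cluster", isotope, method = method)
  lig <- lookup_energy(records, "ligand", isotope, method = method)
  pen <- lookup_energy(records, "water_pentamer", isotope, method = method)
  val <- cl$energy_kcal - lig$energy_kcal - pen$energy_kcal
  structure(val,
            eps = c(ligand_water_cluster = cl$epsilon, ligand = lig$epsilon,
                    water_pentamer = pen$epsilon),
            method = unique(c(cl$method, lig$method, pen$method)))
}

#' Receptor-interaction-leg energy
#'
#' `dE_INTER = E(complex) - (E(ligand) + E(receptor))`, with the complex
#' and the receptor evaluated at the protein-interior dielectric and the
#' free ligand at the aqueous dielectric. A record whose stored dielectric
#' disagrees with its declared role is a configuration error.
#'
#' @param records an `energy_records` table.
#' @param isotope `"H"` or `"D"`.
#' @param eps_protein protein-interior dielectric (default 4.0).
#' @param eps_water aqueous dielectric (default 78.36).
#' @param method optional method tag filter.
#' @return interaction energy (kcal/mol) with `eps`/`method` attributes.
#' @export
interaction_energy <- function(records, isotope = c("H", "D"),
                               eps_protein = 4.0, eps_water = 78.36,
                               method = NULL) {
  isotope <- match.arg(isotope)
  cx <- lookup_energy(records, "complex", isotope, eps_protein, method)
  rec <- lookup_energy(records, "receptor", isotope, eps_protein, method)
  lig <- lookup_energy(records, "ligand", isotope, eps_water, method)
  val <- cx$energy_kcal - (lig$energy_kcal + rec$energy_kcal)
  structure(val,
            eps = c(complex = cx$epsilon, receptor = rec$epsilon,
                    ligand = lig$epsilon),
            method = unique(c(cx$method, rec$method, lig$method)))
}

#' Assemble the two-leg deuteration cycle
#'
#' Combines hydration and receptor-interaction leg energies for the
#' protiated (H) and deuterated (D) species into the full cycle:
#' `dE_BIND(i) = dE_INTER(i) - dE_HYDR(i)` per isotope, and the
#' deuteration shift
#' `ddE_BIND(H->D) = ddE_INTER(H->D) - ddE_HYDR(H->D)`,
#' where every `X(H->D)` difference is `X(H) - X(D)` (positive means the
#' deuterated species is favored in that leg). Legs carrying conflicting
#' method tags refuse to combine.
#'
#' @param hydr_H,hydr_D hydration-leg energies (kcal/mol), e.g. from
#'   [hydration_energy()] or entered directly from a published table.
#' @param inter_H,inter_D interaction-leg energies (kcal/mol).
#' @param method optional method tag for the result.
#' @param eps optional dielectric tag(s) for the result.
#' @return a `cycle_result`: list with per-isotope legs (`dE_hydr`,
#'   `dE_inter`, `dE_bind`, each named `c(H=, D=)`), the three H->D
#'   differences (`ddE_hydr`, `ddE_inter`, `ddE_bind`), `method`, `eps`.
#' @export
deuteration_shift <- function(hydr_H, hydr_D, inter_H, inter_D,
                              method = NULL, eps = NULL) {
  meths <- unique(c(method,
                    attr(hydr_H, "method"), attr(hydr_D, "method"),
                    attr(inter_H, "method"), attr(inter_D, "method")))
  meths <- meths[!is.na(meths)]
  if (length(meths) > 1L) {
    stop("refusing to combine legs from mixed methods: ",
         paste(meths, collapse = ", "))
  }
  vals <- c(hydr_H, hydr_D, inter_H, inter_D)
  if (any(!is.finite(vals))) stop("leg energies must be finite")
  hH <- as.numeric(hydr_H); hD <- as.numeric(hydr_D)
  iH <- as.numeric(inter_H); iD <- as.numeric(inter_D)
  structure(
    list(dE_hydr = c(H = hH, D = hD),
         dE_inter = c(H = iH, D = iD),
         dE_bind = c(H = iH - hH, D = iD - hD),
         ddE_hydr = hH - hD,
         ddE_inter = iH - iD,
         ddE_bind = (iH - iD) - (hH - hD),
         method = if (length(meths)) meths else NA_character_,
         eps = eps),
    class = "cycle_result"
  )
}

#' Compute a full deuteration cycle from an energy table
#'
#' Convenience wrapper running [hydration_energy()] and
#' [interaction_energy()] for both isotopes and feeding
#' [deuteration_shift()].
#'
#' @inheritParams interaction_energy
#' @return a `cycle_result`.
#' @export
build_cycle <- function(records, method = NULL, eps_protein = 4.0,
                        eps_water = 78.36) {
  deuteration_shift(
    hydration_energy(records, "H", method),
    hydration_energy(records, "D", method),
    interaction_energy(records, "H", eps_protein, eps_water, method),
    interaction_energy(records, "D", eps_protein, eps_water, method),
    method = method, eps = c(protein = eps_protein, water = eps_water)
  )
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> method %s%s\n", x$method,
              if (is.null(x$eps)) "" else
                paste0(", eps ", paste(format(x$eps), collapse = "/"))))
  m <- rbind(dE_HYDR = c(x$dE_hydr, x$ddE_hydr),
             dE_INTER = c(x$dE_inter, x$ddE_inter),
             dE_BIND = c(x$dE_bind, x$ddE_bind))
  colnames(m) <- c("H2O", "D2O", "ddE(H2O-D2O)")
  print(round(m, 2))
  invisible(x)
}

#' Tabulate deuteration cycles
#'
#' Renders one or more `cycle_result`s as a long table: one row per
#' quantity (`dE_HYDR`, `dE_INTER`, `dE_BIND`) and cycle, with columns
#' for the H2O and D2O values and their difference, tagged by method and
#' dielectric. Values are kcal/mol. If a stored `ddE_bind` disagrees with
#' the recomputed `ddE_inter - ddE_hydr` by more than 0.005 kcal/mol a
#' validation warning is raised.
#'
#' @param results a `cycle_result` or list of them.
#' @param digits decimals for the formatted text rendering (default 2).
#' @return data.frame with columns `method`, `eps`, `quantity`, `dE_H2O`,
#'   `dE_D2O`, `ddE_H2O_D2O`; print with `format_cycle_table()` or write
#'   with [utils::write.csv()].
#' @export
cycle_table <- function(results, digits = 2L) {
  if (inherits(results, "cycle_result")) results <- list(results)
  if (length(results) < 1L) stop("need at least one cycle result")
  rows <- lapply(results, function(r) {
    recomputed <- r$ddE_inter - r$ddE_hydr
    if (abs(recomputed - r$ddE_bind) > 0.005) {
      warning(sprintf(
        "cycle inconsistency: stored ddE_bind %.4f vs recomputed %.4f",
        r$ddE_bind, recomputed))
    }
    eps_tag <- if (is.null(r$eps)) NA_character_ else
      paste(format(r$eps, trim = TRUE), collapse = "/")
    data.frame(
      method = r$method, eps = eps_tag,
      quantity = c("dE_HYDR", "dE_INTER", "dE_BIND"),
      dE_H2O = c(r$dE_hydr[["H"]], r$dE_inter[["H"]], r$dE_bind[["H"]]),
      dE_D2O = c(r$dE_hydr[["D"]], r$dE_inter[["D"]], r$dE_bind[["D"]]),
      ddE_H2O_D2O = c(r$ddE_hydr, r$ddE_inter, r$ddE_bind)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "digits") <- digits
  out
}

#' @rdname cycle_table
#' @param tab a table from [cycle_table()].
#' @return `format_cycle_table`: character vector of formatted lines.
#' @export
format_cycle_table <- function(tab, digits = attr(tab, "digits")) {
  if (is.null(digits)) digits <- 2L
  fmt <- tab
  for (cn in c("dE_H2O", "dE_D2O", "ddE_H2O_D2O")) {
    fmt[[cn]] <- sprintf(paste0("%.", digits, "f"), tab[[cn]])
  }
  utils::capture.output(print(fmt, row.names = FALSE))
}

#' Count hydrogen bonds in a structure
#'
#' Geometric criterion: an N-H or O-H donor whose donor-acceptor (heavy
#' atom) distance is below `d_max` and whose D-H...A angle exceeds
#' `angle_min`. Acceptors are N, O or F atoms other than the donor and
#' not covalently bonded to the hydrogen. Used for checking that a
#' hydration scheme conserves its hydrogen-bond count (homodesmotic
#' accounting).
#'
#' @param s a `mol_structure` with bonds.
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimal D-H...A angle, degrees (default 120).
#' @return integer count of hydrogen bonds.
#' @export
count_hbonds <- function(s, d_max = 3.5, angle_min = 120) {
  nrow(find_hbonds(s, d_max, angle_min))
}

# shared H-bond enumeration: rows (h, donor, acceptor, d_da, d_ha, angle)
find_hbonds <- function(s, d_max = 3.5, angle_min = 120) {
  ex <- detect_exchangeable(s)
  xyz <- coords(s)
  el <- s$atoms$element
  acc_ok <- el %in% c("N", "O", "F")
  out <- list()
  for (k in seq_len(nrow(ex))) {
    h <- ex$h[k]; d <- ex$donor[k]
    bonded_to_h <- c(s$bonds[s$bonds[, 1L] == h, 2L],
                     s$bonds[s$bonds[, 2L] == h, 1L])
    for (a in which(acc_ok)) {
      if (a == d || a %in% bonded_to_h) next
      d_da <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (d_da > d_max) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang <= angle_min) next
      d_ha <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      out[[length(out) + 1L]] <- data.frame(
        h = h, donor = d, acceptor = a, d_da = d_da, d_ha = d_ha,
        angle = ang)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(h = integer(0), donor = integer(0),
                      acceptor = integer(0), d_da = numeric(0),
                      d_ha = numeric(0), angle = numeric(0)))
  }
  do.call(rbind, out)
}
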