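#' Detect exchangeable (acidic) hydrogens
#'
#' Identifies hydrogens bonded to N or O donors -- the protons that swap
#' for deuterium when the solvent is D2O. C-H (and by default S-H)
#' hydrogens do not exchange and are excluded. Ordering is deterministic
#' by hydrogen atom index.
#'
#' @param s a `mol_structure` with bonds populated.
#' @param donor_elements elements counted as exchangeable-proton donors
#'   (default `c("N", "O")`).
#' @return An `exchangeable_set`: data.frame with columns `h` (H atom
#'   index), `donor` (donor atom index), `donor_element`, `length`
#'   (current bond length, Angstrom).
#' @export
detect_exchangeable <- function(s, donor_elements = c("N", "O")) {
  if (is.null(s$bonds)) stop("structure has no bonds; run infer_bonds() first")
  el <- s$atoms$element
  xyz <- coords(s)
  h_idx <- which(el == "H")
  rows <- list()
  for (h in h_idx) {
    partners <- c(s$bonds[s$bonds[, 1L] == h, 2L],
                  s$bonds[s$bonds[, 2L] == h, 1L])
    donors <- partners[el[partners] %in% donor_elements]
    if (length(donors) > 1L) {
      stop("hydrogen ", h, " is bonded to more than one donor (atoms ",
           paste(sort(donors), collapse = ", "), "); ambiguous assignment")
    }
    if (length(donors) == 1L) {
      d <- donors[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        h = h, donor = d, donor_element = el[d],
        length = sqrt(sum((xyz[h, ] - xyz[d, ])^2))
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(h = integer(0), donor = integer(0),
               donor_element = character(0), length = numeric(0))
  out <- out[order(out$h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exchangeable_set", "data.frame")
  out
}

#' Apply the Ubbelohde bond-contraction protocol
#'
#' Empirical nuclear quantization for deuterated species: every acidic
#' X-H bond (X = N, O) is shortened by a fixed fraction -- 2.3% by
#' default, the contraction measured for the alanine zwitterion N-D bond
#' by neutron diffraction -- by moving only the hydrogen along the
#' donor-to-hydrogen direction. Heavy atoms never move. The scaled bonds
#' are returned as frozen-bond constraints (together with any atoms
#' already flagged frozen, e.g. truncation alpha-carbons) for a
#' downstream constrained geometry optimization.
#'
#' Applying the transform twice would contract twice, so the output
#' structure carries a provenance flag and re-application errors.
#'
#' @param s a `mol_structure` with bonds.
#' @param exchangeable optional `exchangeable_set`; detected from `s` when
#'   `NULL`.
#' @param contraction fractional bond shortening in `[0, 0.5)`;
#'   default `0.023`.
#' @param donor_elements passed to [detect_exchangeable()] when
#'   `exchangeable` is `NULL`.
#' @return list with elements `structure` (transformed `mol_structure`,
#'   flagged deuterated) and `constraints` (a `constraint_spec`: frozen
#'   bonds with target lengths, plus frozen atom indices).
#' @export
apply_ubbelohde <- function(s, exchangeable = NULL, contraction = 0.023,
                            donor_elements = c("N", "O")) {
  if (!is.numeric(contraction) || contraction < 0 || contraction >= 0.5) {
    stop("contraction must be in [0, 0.5)")
  }
  if (isTRUE(attr(s, "deuterated"))) {
    stop("structure is already deuterated; re-applying would contract twice")
  }
  if (is.null(exchangeable)) {
    exchangeable <- detect_exchangeable(s, donor_elements)
  } else {
    if (any(s$atoms$element[exchangeable$h] != "H")) {
      stop("exchangeable set lists a non-hydrogen atom")
    }
  }
  xyz <- coords(s)
  targets <- numeric(nrow(exchangeable))
  for (k in seq_len(nrow(exchangeable))) {
    h <- exchangeable$h[k]; d <- exchangeable$donor[k]
    v <- xyz[h, ] - xyz[d, ]
    len <- sqrt(sum(v * v))
    if (len < 1e-8) stop("zero-length bond between atoms ", d, " and ", h)
    newpos <- xyz[d, ] + (1 - contraction) * v
    s$atoms$x[h] <- newpos[1L]
    s$atoms$y[h] <- newpos[2L]
    s$atoms$z[h] <- newpos[3L]
    targets[k] <- (1 - contraction) * len
  }
  attr(s, "deuterated") <- TRUE
  spec <- structure(
    list(
      bonds = data.frame(i = exchangeable$donor, j = exchangeable$h,
                         target = targets),
      frozen_atoms = which(s$atoms$frozen)
    ),
    class = "constraint_spec"
  )
  ord <- order(spec$bonds$i, spec$bonds$j)
  spec$bonds <- spec$bonds[ord, , drop = FALSE]
  rownames(spec$bonds) <- NULL
  list(structure = s, constraints = spec)
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat(sprintf("<constraint_spec> %d frozen bonds, %d frozen atoms\n",
              nrow(x$bonds), length(x$frozen_atoms)))
  invisible(x)
}

#' Write a constraint table
#'
#' Plain-text TSV hand-off for an external optimizer: one row per frozen
#' bond (`bond  i  j  target`, 1-based indices, target length in Angstrom
#' to 6 decimals) and one per frozen atom (`atom  i`). Ordering is stable:
#' bonds by (i, j), then atoms ascending.
#'
#' @param spec a `constraint_spec` from [apply_ubbelohde()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(spec, path) {
  lines <- "type\ti\tj\ttarget_angstrom"
  if (nrow(spec$bonds) > 0L) {
    lines <- c(lines, sprintf("bond\t%d\t%d\t%.6f",
                              spec$bonds$i, spec$bonds$j, spec$bonds$target))
  }
  for (a in sort(spec$frozen_atoms)) {
    lines <- c(lines, sprintf("atom\t%d\t\t", a))
  }
  writeLines(lines, path)
  invisible(path)
}
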