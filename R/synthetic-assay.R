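#' Ground-truth parameters for a synthetic binding assay
#'
#' Bundles the generating parameters for a simulated radioligand
#' experiment, either a saturation assay (one-site hyperbola plus a linear
#' nonspecific component) or a competition assay (four-parameter logistic
#' in log10 concentration). These are the quantities the fitting module is
#' later asked to recover.
#'
#' @param kind `"saturation"` or `"competition"`.
#' @param K_D equilibrium dissociation constant, molar (saturation).
#' @param B_max maximal specific binding, fmol/mg protein (saturation).
#' @param ns_slope linear nonspecific binding slope, fmol/mg per nM of
#'   radioligand (saturation). The default 0.24 puts nonspecific binding
#'   near 20% of total at 15 nM for the default K_D/B_max.
#' @param pIC50 -log10 of the half-maximal displacer concentration, molar
#'   scale (competition).
#' @param hill Hill slope, restricted to `[0.5, 2]` (one-site competition
#'   curves observed experimentally fall in 0.9-1.4).
#' @param top,bottom upper/lower plateaus of the competition curve,
#'   response units (fmol/mg).
#' @param noise_sd SD of the additive Gaussian noise, response units.
#' @param n_replicates replicates per concentration (default 3,
#'   "triplicate").
#' @param seed integer RNG seed for dataset generation.
#' @return an `assay_truth` object (list).
#' @export
assay_truth <- function(kind = c("saturation", "competition"),
                        K_D = 4.7e-9, B_max = 18.6, ns_slope = 0.24,
                        pIC50 = 7.25, hill = 1, top = 100, bottom = 0,
                        noise_sd = 0, n_replicates = 3L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "saturation") {
    if (K_D <= 0) stop("K_D must be > 0")
    if (B_max <= 0) stop("B_max must be > 0")
    if (ns_slope < 0) stop("ns_slope must be >= 0")
  } else {
    if (!is.finite(pIC50)) stop("pIC50 must be finite")
    if (hill == 0) stop("hill = 0 gives a degenerate (flat) curve")
    if (hill < 0.5 || hill > 2) stop("hill must lie in [0.5, 2]")
    if (top <= bottom) stop("top must exceed bottom")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(kind = kind, K_D = K_D, B_max = B_max, ns_slope = ns_slope,
         pIC50 = pIC50, hill = hill, top = top, bottom = bottom,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "assay_truth"
  )
}

#' Default concentration grids
#'
#' Saturation: 8 radioligand concentrations spanning 1-15 nM (near-linear
#' spacing, the range used for 3H-tiotidine saturation). Competition: 10
#' displacer concentrations log-spaced over 0.01 nM - 100 uM (7 decades).
#'
#' @param n number of concentrations.
#' @return numeric vector of molar concentrations.
#' @export
default_saturation_grid <- function(n = 8L) seq(1, 15, length.out = n) * 1e-9

#' @rdname default_saturation_grid
#' @export
default_competition_grid <- function(n = 10L) 10^seq(-11, -4, length.out = n)

# mean model curves (exported for reuse by the fitting module and tests)

#' One-site specific-binding hyperbola
#' @param L radioligand concentration, molar.
#' @param K_D dissociation constant, molar.
#' @param B_max maximal specific binding.
#' @return mean specific binding `B_max * L / (K_D + L)`.
#' @export
saturation_mean <- function(L, K_D, B_max) B_max * L / (K_D + L)

#' Four-parameter logistic competition curve
#' @param x displacer concentration, molar.
#' @param pIC50 -log10(IC50 molar).
#' @param hill Hill slope.
#' @param top,bottom plateaus.
#' @return mean response `bottom + (top-bottom)/(1 + 10^((log10(x)+pIC50)*hill))`.
#' @export
competition_mean <- function(x, pIC50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^((log10(x) + pIC50) * hill))
}

#' Generate a synthetic saturation binding dataset
#'
#' Simulates total, nonspecific and specific bound radioligand over a
#' concentration grid: specific follows the one-site hyperbola, the
#' nonspecific component is linear in concentration, and i.i.d. Gaussian
#' noise of SD `truth$noise_sd` is added independently to the specific and
#' nonspecific signals per replicate; total is their sum, so the identity
#' `specific = total - nonspecific` holds exactly in every dataset. Noisy
#' responses may be negative and are deliberately not clipped, so the
#' fitting code has to cope with them. Reproducible under `truth$seed`.
#'
#' @param truth an `assay_truth` with `kind = "saturation"`.
#' @param conc_grid radioligand concentrations, molar
#'   (default [default_saturation_grid()]).
#' @return a `binding_dataset`: list with `kind`, `data` (long data.frame
#'   with columns `replicate`, `conc_molar`, `total`, `nonspecific`,
#'   `specific`), `truth`, `seed`.
#' @export
gen_saturation <- function(truth, conc_grid = default_saturation_grid()) {
  stopifnot(inherits(truth, "assay_truth"))
  if (truth$kind != "saturation") stop("truth$kind must be 'saturation'")
  if (length(conc_grid) == 0L || any(conc_grid <= 0)) {
    stop("concentrations must be positive and nonempty")
  }
  spec_mu <- saturation_mean(conc_grid, truth$K_D, truth$B_max)
  ns_mu <- truth$ns_slope * (conc_grid * 1e9) # slope is per nM
  with_seed(truth$seed, {
    rows <- lapply(seq_len(truth$n_replicates), function(r) {
      spec <- spec_mu + stats::rnorm(length(conc_grid), 0, truth$noise_sd)
      ns <- ns_mu + stats::rnorm(length(conc_grid), 0, truth$noise_sd)
      data.frame(replicate = r, conc_molar = conc_grid,
                 total = spec + ns, nonspecific = ns, specific = spec)
    })
    new_binding_dataset("saturation", do.call(rbind, rows), truth)
  })
}

#' Generate a synthetic competition binding dataset
#'
#' Monophasic displacement of bound radioligand by a competitor over a
#' log-spaced concentration grid, with additive Gaussian noise per
#' replicate. The measured response is stored in the `total` column
#' (`nonspecific`/`specific` are `NA`: a competition experiment reads a
#' single bound signal at fixed radioligand concentration).
#'
#' @param truth an `assay_truth` with `kind = "competition"`.
#' @param conc_grid displacer concentrations, molar; must span at least 4
#'   log units (default [default_competition_grid()], 0.01 nM - 100 uM).
#' @return a `binding_dataset`.
#' @export
gen_competition <- function(truth, conc_grid = default_competition_grid()) {
  stopifnot(inherits(truth, "assay_truth"))
  if (truth$kind != "competition") stop("truth$kind must be 'competition'")
  if (length(conc_grid) == 0L || any(conc_grid <= 0)) {
    stop("concentrations must be positive and nonempty")
  }
  if (log10(max(conc_grid) / min(conc_grid)) < 4) {
    stop("competition grid must span at least 4 log units")
  }
  mu <- competition_mean(conc_grid, truth$pIC50, truth$hill,
                         truth$top, truth$bottom)
  with_seed(truth$seed, {
    rows <- lapply(seq_len(truth$n_replicates), function(r) {
      data.frame(replicate = r, conc_molar = conc_grid,
                 total = mu + stats::rnorm(length(conc_grid), 0, truth$noise_sd),
                 nonspecific = NA_real_, specific = NA_real_)
    })
    new_binding_dataset("competition", do.call(rbind, rows), truth)
  })
}

new_binding_dataset <- function(kind, data, truth) {
  rownames(data) <- NULL
  structure(list(kind = kind, data = data, truth = truth, seed = truth$seed),
            class = "binding_dataset")
}

#' @export
print.binding_dataset <- function(x, ...) {
  cat(sprintf("<binding_dataset> %s: %d concentrations x %d replicates\n",
              x$kind, length(unique(x$data$conc_molar)),
              length(unique(x$data$replicate))))
  invisible(x)
}

#' Write / read a binding dataset as CSV
#'
#' Columns: `kind`, `replicate`, `conc_molar`, `total`, `nonspecific`,
#' `specific`.
#'
#' @param d a `binding_dataset`.
#' @param path CSV path.
#' @return `path` invisibly (`write_binding_csv`); a `binding_dataset`
#'   without truth metadata (`read_binding_csv`).
#' @export
write_binding_csv <- function(d, path) {
  df <- cbind(kind = d$kind, d$data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binding_csv
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "replicate", "conc_molar", "total", "nonspecific",
            "specific")
  if (!all(need %in% names(df))) {
    stop("binding CSV needs columns: ", paste(need, collapse = ", "))
  }
  kind <- unique(df$kind)
  if (length(kind) != 1L) stop("mixed assay kinds in one CSV")
  structure(list(kind = kind, data = df[, need[-1L]], truth = NULL,
                 seed = NA_integer_),
            class = "binding_dataset")
}
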