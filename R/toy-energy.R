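#' Parameters of the surrogate energy model
#'
#' A deliberately simple, desk-scale energy function used to exercise the
#' deuteration protocol and the thermodynamic cycle end to end. It is a
#' surrogate embodying one physical idea -- attenuation of hydrogen
#' bonding by deuteration through the dipole-charge interaction: the
#' donor-proton bond dipole `mu = |q_H| * r(X-H)` shrinks when the bond
#' contracts, weakening its attraction to the negative charge on the
#' acceptor. It is never a stand-in for quantum-chemical energies and its
#' absolute magnitudes mean nothing outside this package.
#'
#' Terms (kcal/mol):
#' \itemize{
#'   \item screened Coulomb `k_C q_i q_j / (eps r_ij)` over non-bonded
#'     pairs (1-2 exclusions only). Exchangeable (N/O-bonded) hydrogens do
#'     not enter as point charges: their charge is folded into the donor
#'     heavy atom and they act solely through the bond-dipole term below.
#'     This keeps the electrostatics invariant under the deuteration
#'     transform, so the whole isotope effect flows through the hydrogen
#'     bond, which is the mechanism being modeled.
#'   \item hydrogen-bond dipole-charge term
#'     `-k_HB * mu_XH * |q_acc| / (eps d^2)` with `d` the H...acceptor
#'     distance, over donor/acceptor pairs passing the geometric gates
#'     (donor-acceptor distance below `hb_dmax`, D-H...A angle above
#'     `hb_angle_min`).
#'   \item a repulsive `(r_min / R)^12` core on each gated donor-acceptor
#'     heavy-atom pair (unscreened), preventing collapse along the
#'     hydrogen bond.
#' }
#'
#' @param eps uniform dielectric screen (>= 1), mimicking a bulk
#'   continuum-solvent parameter.
#' @param k_coulomb Coulomb constant, 332.0636 kcal A mol^-1 e^-2.
#' @param k_hb hydrogen-bond coupling (kcal A mol^-1 per e.A of bond
#'   dipole per e of acceptor charge). The default 54 puts a water-water
#'   hydrogen bond near -5 kcal/mol at eps = 1.
#' @param r_min core radius, Angstrom (default 2.9, a typical O...O
#'   hydrogen-bond distance).
#' @param k_rep core strength, kcal/mol at `R = r_min` (default 1.2,
#'   balancing the dipole-charge attraction so an isolated hydrogen bond
#'   has an interior minimum near `r_min`).
#' @param hb_dmax donor-acceptor gate distance, Angstrom (default 3.5).
#' @param hb_angle_min D-H...A gate angle, degrees (default 120).
#' @return list of parameters of class `toy_energy_params`.
#' @export
toy_energy_params <- function(eps = 1, k_coulomb = 332.0636, k_hb = 54,
                              r_min = 2.9, k_rep = 1.2,
                              hb_dmax = 3.5, hb_angle_min = 120) {
  if (eps < 1) stop("eps must be >= 1")
  if (k_hb < 0) stop("k_hb must be >= 0")
  structure(list(eps = eps, k_coulomb = k_coulomb, k_hb = k_hb,
                 r_min = r_min, k_rep = k_rep, hb_dmax = hb_dmax,
                 hb_angle_min = hb_angle_min),
            class = "toy_energy_params")
}

#' Surrogate total energy of a cluster
#'
#' Evaluates the surrogate energy of [toy_energy_params()] on a structure
#' with charges and bonds. Deterministic; no cutoffs besides the
#' hydrogen-bond gates.
#'
#' @param s a `mol_structure` with partial charges and bonds.
#' @param params a `toy_energy_params` (default `toy_energy_params()`).
#' @return total energy (kcal/mol) with attribute `components` (named
#'   vector: `coulomb`, `hbond`, `repulsion`).
#' @export
total_energy <- function(s, params = toy_energy_params()) {
  q <- s$atoms$charge
  if (any(is.na(q))) stop("all atoms must carry partial charges")
  if (is.null(s$bonds)) stop("bonds required for donor detection")
  xyz <- coords(s)
  n <- n_atoms(s)
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(xyz))
    if (min(dm[upper.tri(dm)]) < 0.1) {
      stop("overlapping atoms (pair closer than 0.1 A)")
    }
  }
  ex <- detect_exchangeable(s)
  # fold exchangeable-H charges into their donors; those H atoms carry no
  # point charge of their own
  q_eff <- q
  if (nrow(ex) > 0L) {
    for (k in seq_len(nrow(ex))) {
      q_eff[ex$donor[k]] <- q_eff[ex$donor[k]] + q_eff[ex$h[k]]
      q_eff[ex$h[k]] <- 0
    }
  }
  active <- setdiff(seq_len(n), ex$h)
  bonded <- matrix(FALSE, n, n)
  if (nrow(s$bonds) > 0L) {
    bonded[s$bonds] <- TRUE
    bonded[s$bonds[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  e_coul <- 0
  if (length(active) >= 2L) {
    for (ii in seq_len(length(active) - 1L)) {
      i <- active[ii]
      for (jj in seq(ii + 1L, length(active))) {
        j <- active[jj]
        if (bonded[i, j]) next
        e_coul <- e_coul + q_eff[i] * q_eff[j] / dm[i, j]
      }
    }
    e_coul <- params$k_coulomb * e_coul / params$eps
  }
  hb <- find_hbonds(s, params$hb_dmax, params$hb_angle_min)
  e_hb <- 0; e_rep <- 0
  if (nrow(hb) > 0L) {
    for (k in seq_len(nrow(hb))) {
      h <- hb$h[k]; d <- hb$donor[k]; a <- hb$acceptor[k]
      r_xh <- sqrt(sum((xyz[h, ] - xyz[d, ])^2))
      mu <- abs(q[h]) * r_xh
      e_hb <- e_hb - params$k_hb * mu * abs(q[a]) /
        (params$eps * hb$d_ha[k]^2)
      e_rep <- e_rep + params$k_rep * (params$r_min / hb$d_da[k])^12
    }
  }
  structure(e_coul + e_hb + e_rep,
            components = c(coulomb = e_coul, hbond = e_hb,
                           repulsion = e_rep))
}

# connected components of the bond graph
bond_components <- function(s) {
  n <- n_atoms(s)
  comp <- integer(n)
  adj <- vector("list", n)
  if (!is.null(s$bonds) && nrow(s$bonds) > 0L) {
    for (k in seq_len(nrow(s$bonds))) {
      i <- s$bonds[k, 1L]; j <- s$bonds[k, 2L]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

#' Rigid scan of the donor-acceptor heavy-atom distance
#'
#' For a fixture holding a single hydrogen bond between two rigid
#' fragments, translates the acceptor fragment along the donor-to-acceptor
#' axis so the heavy-atom distance takes each grid value, evaluates the
#' surrogate energy, and reports the distance of minimal energy. The
#' minimum must be interior to the grid (bracketed); a minimum on the grid
#' edge raises a no-minimum error. Used to demonstrate the Ubbelohde
#' donor-acceptor elongation: the contracted (deuterated) copy of the same
#' fixture has its optimum at an equal or longer heavy-atom distance.
#'
#' @param s a `mol_structure` with exactly one hydrogen bond joining two
#'   bonded fragments.
#' @param grid heavy-atom distances to scan, Angstrom (default
#'   `seq(2.6, 3.6, by = 0.01)`).
#' @param params a `toy_energy_params`.
#' @return data.frame of class `distance_scan` with columns `distance`,
#'   `energy`, and attribute `argmin` (distance of minimal energy).
#' @export
scan_heavy_distance <- function(s, grid = seq(2.6, 3.6, by = 0.01),
                                params = toy_energy_params()) {
  if (length(grid) < 3L) stop("grid too coarse to bracket a minimum")
  grid <- sort(grid)
  hb <- find_hbonds(s, params$hb_dmax, params$hb_angle_min)
  if (nrow(hb) != 1L) {
    stop("scan fixture must contain exactly one hydrogen bond (found ",
         nrow(hb), ")")
  }
  comp <- bond_components(s)
  d <- hb$donor[1L]; a <- hb$acceptor[1L]
  if (comp[d] == comp[a]) {
    stop("donor and acceptor must belong to different bonded fragments")
  }
  xyz <- coords(s)
  axis <- unit(xyz[a, ] - xyz[d, ])
  r0 <- hb$d_da[1L]
  movers <- which(comp == comp[a])
  energies <- vapply(grid, function(g) {
    sh <- s
    shift <- (g - r0) * axis
    sh$atoms$x[movers] <- sh$atoms$x[movers] + shift[1L]
    sh$atoms$y[movers] <- sh$atoms$y[movers] + shift[2L]
    sh$atoms$z[movers] <- sh$atoms$z[movers] + shift[3L]
    as.numeric(total_energy(sh, params))
  }, numeric(1))
  k <- which.min(energies)
  if (k == 1L || k == length(grid)) {
    stop("no interior minimum on the scan grid [",
         format(min(grid)), ", ", format(max(grid)), "]")
  }
  out <- data.frame(distance = grid, energy = energies)
  attr(out, "argmin") <- grid[k]
  class(out) <- c("distance_scan", "data.frame")
  out
}

#' Distance of minimal energy from a scan
#' @param scan a `distance_scan` from [scan_heavy_distance()].
#' @return the argmin distance, Angstrom.
#' @export
scan_minimum <- function(scan) attr(scan, "argmin")
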