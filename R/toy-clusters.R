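# Internal geometry helpers for hydrogen-bonded toy clusters.
# Geometries are idealized (water r(OH) = 0.9572 A, HOH angle 104.52 deg,
# ring N-H 1.01 A, C-H 1.08 A); charges come from a fixed internal table
# (water TIP3P-like: O -0.834, H +0.417). Any self-consistent set works;
# the surrogate energy model only needs signs and rough magnitudes.

OH_LEN <- 0.9572
HOH_ANGLE <- 104.52 * pi / 180

unit <- function(v) v / sqrt(sum(v * v))

# a water molecule: O at `o`, H-O-H bisector along `bisector`, molecular
# plane spanned with `wing`; returns 3x3 coordinate matrix (O, H1, H2)
water_at <- function(o, bisector, wing) {
  b <- unit(bisector)
  w <- unit(wing - sum(wing * b) * b) # orthogonalize
  half <- HOH_ANGLE / 2
  h1 <- o + OH_LEN * (cos(half) * b + sin(half) * w)
  h2 <- o + OH_LEN * (cos(half) * b - sin(half) * w)
  rbind(o, h1, h2)
}

#' Generate a toy hydrogen-bonded cluster
#'
#' Small, chemically sensible clusters with explicit bonds and partial
#' charges, used as fixtures for the deuteration-geometry and surrogate
#' energy machinery. Each template places at least one N-H or O-H donor
#' pointing at an acceptor with an H...acceptor distance of 1.5-2.2 A.
#'
#' Templates:
#' \describe{
#'   \item{`water_pentamer`}{cyclic (H2O)5 ring, each water donating one
#'     H-bond to the next oxygen (5 H-bonds, 10 O-H covalent bonds, net
#'     charge 0).}
#'   \item{`imidazolium_acetate`}{an imidazolium cation (+1, two N-H
#'     donors) ion-paired with acetate (-1); one N-H points at a
#'     carboxylate oxygen.}
#'   \item{`donor_acceptor_pair`}{a water dimer with a single, near-linear
#'     O-H...O hydrogen bond.}
#' }
#'
#' @param template one of `"water_pentamer"`, `"imidazolium_acetate"`,
#'   `"donor_acceptor_pair"`.
#' @param seed integer seed for the (optional) coordinate jitter; with
#'   `jitter = 0` the geometry is fully deterministic, and two calls with
#'   the same seed are always identical.
#' @param jitter Gaussian positional noise SD in Angstrom (default 0).
#' @return a `mol_structure` with bonds, charges and `frozen = FALSE`.
#' @export
gen_toy_cluster <- function(template = c("water_pentamer",
                                         "imidazolium_acetate",
                                         "donor_acceptor_pair"),
                            seed = 1L, jitter = 0) {
  if (!is.character(template) || !template[1L] %in%
      c("water_pentamer", "imidazolium_acetate", "donor_acceptor_pair")) {
    stop("unknown template '", template[1L], "'")
  }
  template <- template[1L]
  s <- switch(template,
    water_pentamer = build_water_pentamer(),
    imidazolium_acetate = build_imidazolium_acetate(),
    donor_acceptor_pair = build_water_dimer()
  )
  if (jitter > 0) {
    s <- with_seed(as.integer(seed), {
      n <- n_atoms(s)
      s$atoms$x <- s$atoms$x + stats::rnorm(n, 0, jitter)
      s$atoms$y <- s$atoms$y + stats::rnorm(n, 0, jitter)
      s$atoms$z <- s$atoms$z + stats::rnorm(n, 0, jitter)
      s
    })
  }
  s$title <- template
  s
}

# evaluate `expr` under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# cyclic pentamer: oxygens on a circle with r(O...O) = 2.8 A, each water
# donates its first H toward the next oxygen; the second H alternates
# above/below the ring plane
build_water_pentamer <- function() {
  n <- 5L
  roo <- 2.8
  rad <- roo / (2 * sin(pi / n))
  atoms <- list(); bonds <- list()
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    th_next <- 2 * pi * (k %% n) / n
    o <- c(rad * cos(th), rad * sin(th), 0)
    o_next <- c(rad * cos(th_next), rad * sin(th_next), 0)
    u <- unit(o_next - o)                 # donated H along O -> next O
    h1 <- o + OH_LEN * u
    zhat <- c(0, 0, ifelse(k %% 2 == 0, -1, 1))
    h2 <- o + OH_LEN * (cos(HOH_ANGLE) * u + sin(HOH_ANGLE) * zhat)
    base <- (k - 1L) * 3L
    atoms[[k]] <- data.frame(
      element = c("O", "H", "H"),
      x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
      z = c(o[3], h1[3], h2[3]),
      charge = c(-0.834, 0.417, 0.417)
    )
    bonds[[k]] <- rbind(c(base + 1L, base + 2L), c(base + 1L, base + 3L))
  }
  mol_structure(do.call(rbind, atoms), do.call(rbind, bonds),
                title = "water_pentamer")
}

# water dimer: donor O at origin donating along +x, acceptor O at
# r(O...O) = 2.85 A with its HOH bisector pointing away from the donor
build_water_dimer <- function() {
  o_d <- c(0, 0, 0)
  h_don <- c(OH_LEN, 0, 0)
  h2 <- OH_LEN * c(cos(HOH_ANGLE), sin(HOH_ANGLE), 0)
  o_a <- c(2.85, 0, 0)
  acc <- water_at(o_a, bisector = c(1, 0, 0), wing = c(0, 0, 1))
  atoms <- data.frame(
    element = c("O", "H", "H", "O", "H", "H"),
    x = c(o_d[1], h_don[1], h2[1], acc[, 1]),
    y = c(o_d[2], h_don[2], h2[2], acc[, 2]),
    z = c(o_d[3], h_don[3], h2[3], acc[, 3]),
    charge = rep(c(-0.834, 0.417, 0.417), 2)
  )
  bonds <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 5L), c(4L, 6L))
  mol_structure(atoms, bonds, title = "donor_acceptor_pair")
}

# imidazolium (+1) ion-paired with acetate (-1); N1-H donates to a
# carboxylate oxygen at r(H...O) = 1.80 A
build_imidazolium_acetate <- function() {
  ring_r <- 1.35 / (2 * sin(pi / 5))
  ring_el <- c("N", "C", "N", "C", "C") # N1 C2 N3 C4 C5
  ring_q <- c(-0.30, 0.35, -0.30, 0.15, 0.15)
  h_q <- c(0.40, 0.05, 0.40, 0.05, 0.05) # H on N1,C2,N3,C4,C5
  h_len <- c(1.01, 1.08, 1.01, 1.08, 1.08)
  atoms <- list(); bonds <- list()
  ring_pos <- matrix(NA_real_, 5L, 3L)
  for (k in 1:5) {
    th <- 2 * pi * (k - 1) / 5
    ring_pos[k, ] <- c(ring_r * cos(th), ring_r * sin(th), 0)
  }
  idx <- 0L
  h_idx <- integer(5)
  for (k in 1:5) {
    u <- unit(ring_pos[k, ]) # radially outward
    hpos <- ring_pos[k, ] + h_len[k] * u
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = c(ring_el[k], "H"),
      x = c(ring_pos[k, 1], hpos[1]), y = c(ring_pos[k, 2], hpos[2]),
      z = c(ring_pos[k, 3], hpos[3]),
      charge = c(ring_q[k], h_q[k])
    )
    bonds[[length(bonds) + 1L]] <- c(idx + 1L, idx + 2L)
    h_idx[k] <- idx + 2L
    idx <- idx + 2L
  }
  # ring bonds between consecutive heavy atoms (rows 1,3,5,7,9)
  heavy <- seq(1L, 9L, by = 2L)
  for (k in 1:5) {
    bonds[[length(bonds) + 1L]] <- c(heavy[k], heavy[k %% 5 + 1L])
  }
  # acetate placed along the N1-H direction: accepting O at 1.80 A from H
  u <- unit(ring_pos[1L, ])
  h1 <- ring_pos[1L, ] + h_len[1L] * u
  o_acc <- h1 + 1.80 * u
  w <- c(0, 0, 1)
  v <- unit(cos(60 * pi / 180) * u + sin(60 * pi / 180) * c(-u[2], u[1], 0))
  c_cx <- o_acc + 1.25 * v
  o2 <- c_cx + 1.25 * unit(u * cos(-60 * pi / 180) +
                           c(-u[2], u[1], 0) * sin(-60 * pi / 180) + 0.4 * w)
  c_me <- c_cx + 1.50 * unit(v + c(0.3, 0.3, -0.5))
  me_u <- unit(c_me - c_cx)
  perp <- unit(c(-me_u[2], me_u[1], 0))
  hm <- lapply(0:2, function(i) {
    ang <- 2 * pi * i / 3
    d <- unit(0.5 * me_u + cos(ang) * perp + sin(ang) * c(0, 0, 1))
    c_me + 1.09 * d
  })
  ac <- data.frame(
    element = c("O", "C", "O", "C", "H", "H", "H"),
    x = c(o_acc[1], c_cx[1], o2[1], c_me[1], hm[[1]][1], hm[[2]][1], hm[[3]][1]),
    y = c(o_acc[2], c_cx[2], o2[2], c_me[2], hm[[1]][2], hm[[2]][2], hm[[3]][2]),
    z = c(o_acc[3], c_cx[3], o2[3], c_me[3], hm[[1]][3], hm[[2]][3], hm[[3]][3]),
    charge = c(-0.85, 0.70, -0.85, -0.30, 0.10, 0.10, 0.10)
  )
  base <- 10L
  bonds <- c(bonds, list(
    c(base + 1L, base + 2L), c(base + 2L, base + 3L), c(base + 2L, base + 4L),
    c(base + 4L, base + 5L), c(base + 4L, base + 6L), c(base + 4L, base + 7L)
  ))
  mol_structure(do.call(rbind, c(atoms, list(ac))), do.call(rbind, bonds),
                title = "imidazolium_acetate")
}

# ammonium-like donor (net +1) hydrogen-bonded to `n_acceptors` waters
# placed along tetrahedral N-H arms; used by toy_cycle()
build_donor_hub <- function(n_acceptors) {
  stopifnot(n_acceptors >= 0L, n_acceptors <= 4L)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  nh <- 1.01
  atoms <- data.frame(element = "N", x = 0, y = 0, z = 0, charge = -0.40)
  bonds <- list()
  for (k in 1:4) {
    h <- nh * dirs[k, ]
    atoms <- rbind(atoms, data.frame(element = "H", x = h[1], y = h[2],
                                     z = h[3], charge = 0.35))
    bonds[[length(bonds) + 1L]] <- c(1L, 1L + k)
  }
  idx <- 5L
  if (n_acceptors > 0L) {
    for (k in seq_len(n_acceptors)) {
      u <- dirs[k, ]
      o <- 2.90 * u
      wing <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      wat <- water_at(o, bisector = u, wing = wing)
      atoms <- rbind(atoms, data.frame(
        element = c("O", "H", "H"),
        x = wat[, 1], y = wat[, 2], z = wat[, 3],
        charge = c(-0.834, 0.417, 0.417)
      ))
      bonds[[length(bonds) + 1L]] <- c(idx + 1L, idx + 2L)
      bonds[[length(bonds) + 1L]] <- c(idx + 1L, idx + 3L)
      idx <- idx + 3L
    }
  }
  mol_structure(atoms, do.call(rbind, bonds),
                title = sprintf("donor_hub_%d", n_acceptors))
}

# split a donor-hub cluster into its ligand (atoms 1:5) and solvent parts
split_donor_hub <- function(s) {
  n <- n_atoms(s)
  lig <- mol_structure(s$atoms[1:5, ], s$bonds[s$bonds[, 2L] <= 5L, ,
                                               drop = FALSE],
                       title = "donor_hub_ligand")
  if (n == 5L) return(list(ligand = lig, solvent = NULL))
  sb <- s$bonds[s$bonds[, 1L] > 5L, , drop = FALSE] - 5L
  solv <- mol_structure(s$atoms[6:n, ], sb, title = "donor_hub_solvent")
  list(ligand = lig, solvent = solv)
}
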