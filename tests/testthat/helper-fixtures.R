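# shared fixtures and independent oracles

# two-atom N-H fixture along x, length `len`
make_nh <- function(len = 1.0) {
  mol_structure(
    data.frame(element = c("N", "H"), x = c(0, len), y = 0, z = 0,
               charge = c(-0.4, 0.4)),
    bonds = rbind(c(1L, 2L))
  )
}

# methane-like fixture: central C with 4 H, no acidic hydrogens
make_methane <- function() {
  d <- 1.09 / sqrt(3)
  mol_structure(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d),
               z = c(0, d, -d, -d, d),
               charge = c(-0.4, 0.1, 0.1, 0.1, 0.1)),
    bonds = cbind(1L, 2:5)
  )
}

# extract an atom subset as its own structure (bonds renumbered)
substructure <- function(s, idx) {
  idx <- sort(idx)
  keep <- s$bonds[s$bonds[, 1L] %in% idx & s$bonds[, 2L] %in% idx, ,
                  drop = FALSE]
  keep[] <- match(keep, idx)
  mol_structure(s$atoms[idx, ], keep, title = s$title)
}

# independent re-implementation of the surrogate energy: flat loops,
# no shared code paths with total_energy()
naive_toy_energy <- function(s, params = toy_energy_params()) {
  at <- s$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bonded <- function(i, j) {
    any((s$bonds[, 1] == i & s$bonds[, 2] == j) |
        (s$bonds[, 1] == j & s$bonds[, 2] == i))
  }
  partners <- function(i) {
    c(s$bonds[s$bonds[, 1] == i, 2], s$bonds[s$bonds[, 2] == i, 1])
  }
  # exchangeable hydrogens and folded charges
  exch_h <- c(); exch_d <- c()
  for (i in seq_len(n)) {
    if (at$element[i] != "H") next
    p <- partners(i)
    don <- p[at$element[p] %in% c("N", "O")]
    if (length(don) == 1) { exch_h <- c(exch_h, i); exch_d <- c(exch_d, don) }
  }
  q <- at$charge
  for (k in seq_along(exch_h)) {
    q[exch_d[k]] <- q[exch_d[k]] + q[exch_h[k]]
    q[exch_h[k]] <- 0
  }
  e_c <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (i %in% exch_h || j %in% exch_h) next
    if (bonded(i, j)) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e_c <- e_c + params$k_coulomb * q[i] * q[j] / (params$eps * r)
  }
  e_h <- 0; e_r <- 0
  for (k in seq_along(exch_h)) {
    h <- exch_h[k]; d <- exch_d[k]
    for (a in seq_len(n)) {
      if (!at$element[a] %in% c("N", "O", "F")) next
      if (a == d || a %in% partners(h)) next
      rda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (rda > params$hb_dmax) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang <= params$hb_angle_min) next
      rha <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      mu <- abs(at$charge[h]) * sqrt(sum((xyz[h, ] - xyz[d, ])^2))
      e_h <- e_h - params$k_hb * mu * abs(at$charge[a]) / (params$eps * rha^2)
      e_r <- e_r + params$k_rep * (params$r_min / rda)^12
    }
  }
  e_c + e_h + e_r
}

# random cluster of n_waters waters with random rigid placement, minimum
# O-O separation enforced (used for the pairwise-sum oracle)
random_water_cluster <- function(n_waters, seed) {
  set.seed(seed)
  os <- matrix(NA_real_, 0, 3)
  while (nrow(os) < n_waters) {
    cand <- runif(3, -4, 4)
    if (nrow(os) == 0 || min(sqrt(rowSums(sweep(os, 2, cand)^2))) > 2.4) {
      os <- rbind(os, cand)
    }
  }
  atoms <- list(); bonds <- list()
  for (k in seq_len(n_waters)) {
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    w <- rnorm(3); w <- w - sum(w * b) * b; w <- w / sqrt(sum(w^2))
    half <- 104.52 * pi / 360
    h1 <- os[k, ] + 0.9572 * (cos(half) * b + sin(half) * w)
    h2 <- os[k, ] + 0.9572 * (cos(half) * b - sin(half) * w)
    atoms[[k]] <- data.frame(
      element = c("O", "H", "H"),
      x = c(os[k, 1], h1[1], h2[1]), y = c(os[k, 2], h1[2], h2[2]),
      z = c(os[k, 3], h1[3], h2[3]),
      charge = c(-0.834, 0.417, 0.417))
    base <- (k - 1L) * 3L
    bonds[[k]] <- rbind(c(base + 1L, base + 2L), c(base + 1L, base + 3L))
  }
  mol_structure(do.call(rbind, atoms), do.call(rbind, bonds))
}
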