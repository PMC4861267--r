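records_fixture <- function() {
  energy_records(data.frame(
    species = c("ligand_water_cluster", "ligand", "water_pentamer",
                "complex", "receptor", "ligand"),
    isotope = "H",
    epsilon = c(78.36, 78.36, 78.36, 4, 4, 4),
    energy_kcal = c(-100, -20, -12.55, -500, -450, -10.36),
    method = "toy"
  ))
}

test_that("the hydration leg sums its homodesmotic scheme", {
  r <- records_fixture()
  # remove the eps=4 duplicate ligand row for unambiguous lookup
  r_h <- energy_records(r[-6, ])
  e <- hydration_energy(r_h, "H")
  expect_equal(as.numeric(e), -67.45)
  expect_equal(unname(attr(e, "eps")["ligand"]), 78.36)
  # null case
  r0 <- energy_records(data.frame(
    species = c("ligand_water_cluster", "ligand", "water_pentamer"),
    isotope = "H", epsilon = 78.36, energy_kcal = 0, method = "x"))
  expect_equal(as.numeric(hydration_energy(r0, "H")), 0)
  # missing record names the species and isotope
  expect_error(hydration_energy(r_h, "D"), "water_pentamer|ligand")
})

test_that("the interaction leg enforces its dielectric roles", {
  r <- records_fixture()
  e <- interaction_energy(r, "H", eps_protein = 4, eps_water = 78.36)
  expect_equal(as.numeric(e), -500 - (-450 - 20))
  # non-interacting limit
  r2 <- energy_records(data.frame(
    species = c("complex", "receptor", "ligand"),
    isotope = "H", epsilon = c(4, 4, 78.36),
    energy_kcal = c(-30, -20, -10), method = "x"))
  expect_equal(as.numeric(interaction_energy(r2, "H")), 0)
  # wrong dielectric for the ligand role -> missing-record error
  expect_error(interaction_energy(r2, "H", eps_water = 80),
               "missing energy record")
})

test_that("cycle assembly reproduces the published leg arithmetic", {
  # M06-2X, eps = 4: binding legs and deuteration shift
  cy <- deuteration_shift(-67.45, -67.39, -39.64, -40.09, method = "M06-2X")
  expect_equal(unname(cy$dE_bind), c(27.81, 27.30), tolerance = 1e-12)
  expect_equal(cy$ddE_bind, 0.51, tolerance = 1e-12)
  expect_equal(cy$ddE_hydr, -0.06, tolerance = 1e-12)
  expect_equal(cy$ddE_inter, 0.45, tolerance = 1e-12)
  # M06-2X, eps = 20
  cy20 <- deuteration_shift(-67.45, -67.39, -31.98, -32.30)
  expect_equal(cy20$ddE_bind, 0.38, tolerance = 1e-12)
  # B3LYP, eps = 4: opposite trend (protiated binds stronger)
  cyb <- deuteration_shift(-64.30, -64.22, -42.77, -42.59)
  expect_equal(cyb$ddE_bind, -0.10, tolerance = 1e-12)
  expect_equal(unname(cyb$dE_bind), c(21.53, 21.63), tolerance = 1e-12)
})

test_that("identical legs give a null shift; mixed methods refuse to combine", {
  cy <- deuteration_shift(-5, -5, -8, -8)
  expect_equal(cy$ddE_hydr, 0)
  expect_equal(cy$ddE_inter, 0)
  expect_equal(cy$ddE_bind, 0)
  hH <- structure(-5, method = "M06-2X")
  iH <- structure(-8, method = "B3LYP")
  expect_error(deuteration_shift(hH, -5, iH, -8), "mixed methods")
})

test_that("cycle identities hold on random energy tables", {
  set.seed(20)
  for (rep in 1:25) {
    legs <- rnorm(4, 0, 50)
    cy <- deuteration_shift(legs[1], legs[2], legs[3], legs[4])
    # additivity: dE_BIND = dE_INTER - dE_HYDR, exactly
    expect_identical(cy$dE_bind[["H"]], cy$dE_inter[["H"]] - cy$dE_hydr[["H"]])
    expect_identical(cy$dE_bind[["D"]], cy$dE_inter[["D"]] - cy$dE_hydr[["D"]])
    expect_equal(cy$ddE_bind, cy$ddE_inter - cy$ddE_hydr, tolerance = 1e-12)
    # antisymmetry: swapping H and D negates every difference
    sw <- deuteration_shift(legs[2], legs[1], legs[4], legs[3])
    expect_equal(sw$ddE_hydr, -cy$ddE_hydr)
    expect_equal(sw$ddE_inter, -cy$ddE_inter)
    expect_equal(sw$ddE_bind, -cy$ddE_bind)
  }
})

test_that("cycle tables render blocks per method/eps and flag inconsistency", {
  cy4 <- deuteration_shift(-67.45, -67.39, -39.64, -40.09,
                           method = "M06-2X", eps = 4)
  cy20 <- deuteration_shift(-67.45, -67.39, -31.98, -32.30,
                            method = "M06-2X", eps = 20)
  tab <- cycle_table(list(cy4, cy20))
  expect_equal(nrow(tab), 6L)
  bind_rows <- tab[tab$quantity == "dE_BIND", ]
  expect_equal(bind_rows$ddE_H2O_D2O, c(0.51, 0.38), tolerance = 1e-12)
  txt <- format_cycle_table(tab)
  expect_true(any(grepl("0.51", txt)))
  # all-zero cycle renders zeros
  tab0 <- cycle_table(deuteration_shift(0, 0, 0, 0))
  expect_true(all(tab0$dE_H2O == 0))
  # tampered ddE beyond 0.005 raises the validation warning
  bad <- cy4; bad$ddE_bind <- bad$ddE_bind + 0.01
  expect_warning(cycle_table(bad), "inconsistency")
})

test_that("the hydrogen-bond counter supports homodesmotic accounting", {
  p5 <- gen_toy_cluster("water_pentamer")
  da <- gen_toy_cluster("donor_acceptor_pair")
  expect_equal(count_hbonds(p5), 5L)
  expect_equal(count_hbonds(da), 1L)
  expect_equal(count_hbonds(make_methane()), 0L)
  # additivity over a disjoint union (fragments too far to interact):
  # the H-bond count of the combined system equals the sum of its parts
  far <- da
  far$atoms$x <- far$atoms$x + 50
  both <- mol_structure(rbind(p5$atoms, far$atoms),
                        rbind(p5$bonds, far$bonds + n_atoms(p5)))
  expect_equal(count_hbonds(both), count_hbonds(p5) + count_hbonds(da))
})

test_that("toy-backend legs weaken upon deuteration and the net shift can take either sign", {
  # hydration-style leg: protiated H-bonds are stronger (more negative)
  cyc <- toy_cycle(n_hydr = 2, n_inter = 2, eps_hydr = 78.36, eps_inter = 4)
  expect_lt(cyc$dE_hydr[["H"]], cyc$dE_hydr[["D"]])
  expect_lt(cyc$dE_inter[["H"]], cyc$dE_inter[["D"]])
  # equal dielectrics: the leg with more H-bonds loses more
  gain <- toy_cycle(n_hydr = 3, n_inter = 1, eps_hydr = 4, eps_inter = 4)
  lose <- toy_cycle(n_hydr = 1, n_inter = 3, eps_hydr = 4, eps_inter = 4)
  expect_gt(gain$ddE_bind, 0) # deuterated ligand binds tighter
  expect_lt(lose$ddE_bind, 0) # protiated ligand binds tighter
  expect_equal(gain$ddE_bind, -lose$ddE_bind, tolerance = 1e-10)
})

test_that("toy interaction energy of the ion pair is strictly attractive", {
  im <- gen_toy_cluster("imidazolium_acetate")
  cation <- substructure(im, 1:10)
  anion <- substructure(im, 11:17)
  p <- toy_energy_params(eps = 4)
  e_int <- as.numeric(total_energy(im, p)) -
    as.numeric(total_energy(cation, p)) - as.numeric(total_energy(anion, p))
  expect_lt(e_int, 0)
})

test_that("energy-record validation rejects malformed tables", {
  df <- data.frame(species = "ligand", isotope = "T", epsilon = 1,
                   energy_kcal = 0, method = "x")
  expect_error(energy_records(df), "isotope")
  df2 <- data.frame(species = c("a", "a"), isotope = "H", epsilon = 4,
                    energy_kcal = c(0, 1), method = "x")
  expect_error(energy_records(df2), "duplicate")
  df3 <- data.frame(species = "a", isotope = "H", epsilon = 0.5,
                    energy_kcal = 0, method = "x")
  expect_error(energy_records(df3), "dielectric")
})

test_that("the shipped synthetic energy table yields the expected cycle", {
  # component energies are synthetic, constructed so the leg differences
  # match the reference M06-2X eps=4 cycle
  path <- system.file("extdata", "synthetic_m062x_eps4.tsv",
                      package = "isoshift")
  cy <- build_cycle(read_energy_records(path), method = "M06-2X")
  expect_equal(cy$dE_hydr[["H"]], -67.45, tolerance = 1e-12)
  expect_equal(cy$dE_inter[["D"]], -40.09, tolerance = 1e-12)
  expect_equal(cy$ddE_bind, 0.51, tolerance = 1e-12)
})

test_that("energy records round-trip through TSV", {
  r <- records_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_records(r, path)
  r2 <- read_energy_records(path)
  expect_equal(r2$energy_kcal, r$energy_kcal)
  expect_equal(r2$species, r$species)
})
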