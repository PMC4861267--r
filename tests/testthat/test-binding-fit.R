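test_that("noiseless saturation fits recover the generating parameters exactly", {
  tr <- assay_truth("saturation", K_D = 4.7e-9, B_max = 18.6,
                    ns_slope = 0.24, noise_sd = 0)
  d <- gen_saturation(tr)
  f <- fit_saturation(d, mode = "specific")
  expect_true(f$converged)
  expect_equal(fit_param(f, "K_D")$estimate, 4.7e-9, tolerance = 1e-6)
  expect_equal(fit_param(f, "B_max")$estimate, 18.6, tolerance = 1e-6)

  fj <- fit_saturation(d, mode = "total_and_nonspecific")
  expect_true(fj$converged)
  expect_equal(fit_param(fj, "K_D")$estimate, 4.7e-9, tolerance = 1e-6)
  expect_equal(fit_param(fj, "B_max")$estimate, 18.6, tolerance = 1e-6)
  expect_equal(fit_param(fj, "ns_slope")$estimate, 0.24, tolerance = 1e-6)
})

test_that("noiseless competition fits recover the generating parameters exactly", {
  for (truth in list(c(pIC50 = 7.25, hill = 1),
                     c(pIC50 = 8.38, hill = 1.2))) {
    tr <- assay_truth("competition", pIC50 = truth[["pIC50"]],
                      hill = truth[["hill"]], top = 100, bottom = 0,
                      noise_sd = 0)
    f <- fit_competition(gen_competition(tr))
    expect_true(f$converged)
    expect_equal(fit_param(f, "pIC50")$estimate, truth[["pIC50"]],
                 tolerance = 1e-6)
    expect_equal(fit_param(f, "hill")$estimate, truth[["hill"]],
                 tolerance = 1e-6)
    expect_equal(fit_param(f, "top")$estimate, 100, tolerance = 1e-6)
  }
})

test_that("a brute-force SS lattice agrees with the fitted saturation optimum", {
  tr <- assay_truth("saturation", K_D = 4.7e-9, B_max = 18.6,
                    noise_sd = 1.3, seed = 91)
  d <- gen_saturation(tr)
  f <- fit_saturation(d)
  kd_hat <- fit_param(f, "K_D")$estimate * 1e9
  bm_hat <- fit_param(f, "B_max")$estimate
  kd_grid <- seq(2, 9, length.out = 100)   # nM lattice bracketing truth
  bm_grid <- seq(12, 26, length.out = 100)
  L <- d$data$conc_molar * 1e9
  y <- d$data$specific
  ss <- outer(kd_grid, bm_grid, Vectorize(function(kd, bm) {
    sum((y - bm * L / (kd + L))^2)
  }))
  best <- which(ss == min(ss), arr.ind = TRUE)[1, ]
  # the lattice SS minimum lies in the cell containing the fitted optimum
  dk <- diff(kd_grid)[1]; db <- diff(bm_grid)[1]
  expect_lt(abs(kd_grid[best[1]] - kd_hat), dk)
  expect_lt(abs(bm_grid[best[2]] - bm_hat), db)
  # and the continuous optimum is at least as good as any lattice node
  ss_hat <- sum((y - bm_hat * L / (kd_hat + L))^2)
  expect_lte(ss_hat, min(ss) + 1e-9)
})

test_that("Monte-Carlo recovery: K_D and B_max unbiased within 10% at 7% noise", {
  kd <- bm <- numeric(100)
  for (i in seq_len(100)) {
    tr <- assay_truth("saturation", K_D = 4.7e-9, B_max = 18.6,
                      noise_sd = 0.07 * 18.6, seed = 300 + i)
    f <- fit_saturation(gen_saturation(tr))
    kd[i] <- fit_param(f, "K_D")$estimate
    bm[i] <- fit_param(f, "B_max")$estimate
  }
  expect_lt(abs(mean(kd) - 4.7e-9) / 4.7e-9, 0.10)
  expect_lt(abs(mean(bm) - 18.6) / 18.6, 0.10)
})

test_that("Monte-Carlo recovery: mean fitted pIC50 stays in [7.7, 7.9] at 5% noise", {
  p <- numeric(100)
  for (i in seq_len(100)) {
    tr <- assay_truth("competition", pIC50 = 7.80, hill = 1, top = 100,
                      bottom = 0, noise_sd = 5, seed = 500 + i)
    p[i] <- fit_param(fit_competition(gen_competition(tr)), "pIC50")$estimate
  }
  expect_gt(mean(p), 7.7)
  expect_lt(mean(p), 7.9)
})

test_that("estimator bias shrinks as noise shrinks (noise ladder)", {
  bias_at <- function(noise_frac) {
    kd <- vapply(1:40, function(i) {
      tr <- assay_truth("saturation", K_D = 4.7e-9, B_max = 18.6,
                        noise_sd = noise_frac * 18.6, seed = 700 + i)
      fit_param(fit_saturation(gen_saturation(tr)), "K_D")$estimate
    }, numeric(1))
    abs(mean(kd) - 4.7e-9) / 4.7e-9
  }
  ladder <- vapply(c(0.10, 0.05, 0.01, 0.001), bias_at, numeric(1))
  expect_lt(ladder[4], ladder[1])
  expect_lt(ladder[4], 1e-3)
  expect_lt(ladder[3], 0.02)
})

test_that("pIC50-space and IC50-space fits locate the same optimum", {
  tr <- assay_truth("competition", pIC50 = 7.25, hill = 1.1, top = 100,
                    bottom = 5, noise_sd = 4, seed = 13)
  d <- gen_competition(tr)
  f1 <- fit_competition(d, space = "pic50")
  f2 <- fit_competition(d, space = "ic50")
  expect_lt(abs(fit_param(f1, "pIC50")$estimate -
                fit_param(f2, "pIC50")$estimate), 1e-4)
})

test_that("hill and bottom can be fixed", {
  tr <- assay_truth("competition", pIC50 = 7.0, hill = 1, top = 100,
                    bottom = 0, noise_sd = 3, seed = 21)
  d <- gen_competition(tr)
  f <- fit_competition(d, fix_hill = 1, fix_bottom = TRUE)
  expect_true(f$converged)
  expect_equal(fit_param(f, "hill")$estimate, 1)
  expect_equal(fit_param(f, "bottom")$estimate, 0)
  expect_true(is.na(fit_param(f, "hill")$se))
  expect_equal(fit_param(f, "pIC50")$estimate, 7.0, tolerance = 0.05)
})

test_that("bootstrap standard errors are available and sane", {
  tr <- assay_truth("saturation", noise_sd = 1.3, seed = 8)
  d <- gen_saturation(tr)
  f_cov <- fit_saturation(d)
  f_bs <- fit_saturation(d, se = "bootstrap", nboot = 200L, boot_seed = 2L)
  se_cov <- fit_param(f_cov, "K_D")$se
  se_bs <- fit_param(f_bs, "K_D")$se
  expect_gt(se_bs, 0)
  expect_lt(abs(log(se_bs / se_cov)), log(3)) # same order of magnitude
  # seeded: identical on repeat
  f_bs2 <- fit_saturation(d, se = "bootstrap", nboot = 200L, boot_seed = 2L)
  expect_equal(fit_param(f_bs2, "K_D")$se, se_bs)
})

test_that("pathological fitting inputs raise informative errors", {
  tr <- assay_truth("saturation", noise_sd = 0)
  d <- gen_saturation(tr, c(1e-9, 5e-9, 10e-9)) # 3 concentrations
  expect_error(fit_saturation(d), "4 distinct")
  d0 <- gen_saturation(assay_truth("saturation", noise_sd = 0))
  d0$data$specific <- 0
  expect_error(fit_saturation(d0), "no signal")
  # flat competition curve: no displacement
  trc <- assay_truth("competition", pIC50 = 7, top = 100, bottom = 0,
                     noise_sd = 1, seed = 2)
  dflat <- gen_competition(trc)
  # response rises slightly instead of falling: no displacement signal
  dflat$data$total <- 100 + 0.1 * log10(dflat$data$conc_molar * 1e9)
  expect_error(fit_competition(dflat), "no displacement")
})

test_that("Welch comparison behaves at the identities and the extremes", {
  tr <- assay_truth("competition", pIC50 = 7.25, noise_sd = 3, seed = 4)
  f <- fit_competition(gen_competition(tr))
  same <- compare_fits(f, f, "pIC50")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # group summaries 10 SE apart are decisively different
  w10 <- welch_test(10, 0.1, 6, 10 - 10 * sqrt(2) * 0.1, 0.1, 6)
  expect_lt(w10$p, 1e-3)
  expect_error(welch_test(1, 0, 6, 2, 0.1, 6), "degenerate")
})

test_that("the reported pIC50 drop of 2-methylhistamine is decisive", {
  # group means +/- SEM, n = 6 each (two triplicate experiments)
  w <- welch_test(8.38, 0.13, 6, 6.85, 0.16, 6)
  expect_lt(w$p, 1e-4)
  expect_gt(w$t, 5)
})
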