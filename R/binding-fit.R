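#' Fit a one-site saturation binding model
#'
#' Nonlinear least-squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) estimation of the equilibrium dissociation
#' constant K_D and maximal binding B_max from a saturation dataset.
#' `mode = "specific"` fits the hyperbola `B = B_max L / (K_D + L)` to the
#' specific-binding column; `mode = "total_and_nonspecific"` jointly fits
#' total (`B_max L/(K_D+L) + NS L`) and nonspecific (`NS L`) responses
#' with shared parameters. Concentrations are molar at the interface and
#' rescaled to nM internally for conditioning. Standard errors come from
#' the local covariance `(J'J)^-1 s^2`; a seeded nonparametric bootstrap
#' (residual resampling) is available instead.
#'
#' Initial values: K_D from the concentration nearest half-maximal mean
#' response, B_max as 1.1 x the maximal specific response.
#'
#' @param data a `binding_dataset` of kind `"saturation"` (or any list
#'   with a compatible `$data` data.frame).
#' @param mode `"specific"` or `"total_and_nonspecific"`.
#' @param se `"covariance"` (default) or `"bootstrap"`.
#' @param nboot bootstrap resamples (default 1000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return a `saturation_fit`: list with `coefficients` (data.frame of
#'   `param`, `estimate`, `se`, `units`; K_D in molar), `rss`,
#'   `converged`, `df_residual`, `mode`.
#' @export
fit_saturation <- function(data, mode = c("specific", "total_and_nonspecific"),
                           se = c("covariance", "bootstrap"),
                           nboot = 1000L, boot_seed = 1L) {
  mode <- match.arg(mode)
  se <- match.arg(se)
  df <- data$data
  if (length(unique(df$conc_molar)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  L <- df$conc_molar * 1e9 # nM internally
  if (mode == "specific") {
    if (all(is.na(df$specific))) stop("mode 'specific' needs a specific column")
    y <- df$specific
    if (all(abs(y) < .Machine$double.eps * 100)) stop("no signal: all responses zero")
    if (length(y) < 2L) stop("under-determined: fewer points than parameters")
    mu <- tapply(y, L, mean)
    Lu <- as.numeric(names(mu))
    bmax0 <- 1.1 * max(y)
    kd0 <- Lu[which.min(abs(mu - max(mu) / 2))]
    if (kd0 <= 0) kd0 <- stats::median(Lu)
    fd <- data.frame(L = L, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ Bmax * L / (KD + L), data = fd,
      start = list(KD = kd0, Bmax = bmax0),
      lower = c(1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    refit <- function(ynew) {
      fdb <- data.frame(L = L, y = ynew)
      stats::coef(minpack.lm::nlsLM(
        y ~ Bmax * L / (KD + L), data = fdb,
        start = list(KD = kd0, Bmax = bmax0), lower = c(1e-6, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)))
    }
    params <- c("K_D", "B_max")
    units <- c("molar", "fmol/mg")
    scale <- c(1e-9, 1) # nM -> molar on output
  } else {
    if (all(is.na(df$total)) || all(is.na(df$nonspecific))) {
      stop("mode 'total_and_nonspecific' needs total and nonspecific columns")
    }
    y <- c(df$total, df$nonspecific)
    if (all(abs(y) < .Machine$double.eps * 100)) stop("no signal: all responses zero")
    L2 <- c(L, L)
    is_tot <- rep(c(1, 0), each = nrow(df))
    spec_obs <- df$total - df$nonspecific
    mu <- tapply(spec_obs, L, mean)
    Lu <- as.numeric(names(mu))
    bmax0 <- 1.1 * max(spec_obs)
    kd0 <- Lu[which.min(abs(mu - max(mu) / 2))]
    ns0 <- max(stats::coef(stats::lm(df$nonspecific ~ 0 + L))[1L], 1e-6)
    fd <- data.frame(L = L2, y = y, is_tot = is_tot)
    fit <- minpack.lm::nlsLM(
      y ~ is_tot * Bmax * L / (KD + L) + NS * L, data = fd,
      start = list(KD = kd0, Bmax = bmax0, NS = ns0),
      lower = c(1e-6, 1e-6, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    refit <- function(ynew) {
      fdb <- data.frame(L = L2, y = ynew, is_tot = is_tot)
      stats::coef(minpack.lm::nlsLM(
        y ~ is_tot * Bmax * L / (KD + L) + NS * L, data = fdb,
        start = list(KD = kd0, Bmax = bmax0, NS = ns0),
        lower = c(1e-6, 1e-6, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)))
    }
    params <- c("K_D", "B_max", "ns_slope")
    units <- c("molar", "fmol/mg", "fmol/mg/nM")
    scale <- c(1e-9, 1, 1)
  }
  build_fit(fit, params, units, scale, se, nboot, boot_seed, refit,
            class = "saturation_fit", mode = mode)
}

#' Fit a four-parameter logistic competition curve
#'
#' Estimates pIC50, Hill slope and the two plateaus from a competition
#' dataset by nonlinear least squares in log10-concentration space (the
#' well-conditioned parameterization; IC50 is obtained by back-transform).
#' The Hill slope may be fixed (classically at 1 for one-site
#' competition), and the lower plateau may be fixed to 0 when the curve
#' does not sample it. A fit can alternatively be run with IC50 (nM) as
#' the free parameter (`space = "ic50"`); both parameterizations locate
#' the same optimum and report pIC50.
#'
#' A curve whose response does not decrease by at least 10% of its dynamic
#' range between the lowest and highest displacer concentration is
#' rejected as showing no displacement.
#'
#' @param data a `binding_dataset` of kind `"competition"`; the response
#'   is read from the `total` column.
#' @param fix_hill optional fixed Hill slope (e.g. `1`).
#' @param fix_bottom if `TRUE`, fixes the lower plateau at 0.
#' @param space `"pic50"` (default) or `"ic50"` fitting parameterization.
#' @param se,nboot,boot_seed as in [fit_saturation()].
#' @return a `competition_fit`: list with `coefficients` (`pIC50`,
#'   `hill`, `top`, `bottom`; fixed parameters carry `NA` SE), `IC50`
#'   (molar), `rss`, `converged`, `df_residual`.
#' @export
fit_competition <- function(data, fix_hill = NULL, fix_bottom = FALSE,
                            space = c("pic50", "ic50"),
                            se = c("covariance", "bootstrap"),
                            nboot = 1000L, boot_seed = 1L) {
  space <- match.arg(space)
  se <- match.arg(se)
  df <- data$data
  if (length(unique(df$conc_molar)) < 5L) {
    stop("need at least 5 distinct displacer concentrations")
  }
  x <- df$conc_molar
  y <- df$total
  lx <- log10(x)
  mu <- tapply(y, lx, mean)
  lu <- as.numeric(names(mu))
  dyn <- max(mu) - min(mu)
  decrease <- mu[[1L]] - mu[[length(mu)]]
  if (!(decrease >= 0.1 * dyn) || dyn <= 0) {
    stop("no displacement: response does not decrease by >= 10% of its range")
  }
  top0 <- max(mu); bot0 <- min(mu)
  p0 <- -lu[which.min(abs(mu - (top0 + bot0) / 2))]
  start <- list(pIC50 = p0, hill = 1, top = top0, bottom = bot0)
  fixed <- character(0)
  if (!is.null(fix_hill)) {
    if (fix_hill <= 0) stop("fix_hill must be > 0")
    start$hill <- NULL; fixed <- c(fixed, "hill")
  }
  if (isTRUE(fix_bottom)) { start$bottom <- NULL; fixed <- c(fixed, "bottom") }
  hill_term <- if (is.null(fix_hill)) quote(hill) else fix_hill
  bot_term <- if (isTRUE(fix_bottom)) 0 else quote(bottom)
  fd <- data.frame(lx = lx, y = y, xnM = x * 1e9)
  if (space == "pic50") {
    form <- stats::as.formula(substitute(
      y ~ BOT + (top - BOT) / (1 + 10^((lx + pIC50) * HILL)),
      list(BOT = bot_term, HILL = hill_term)))
  } else {
    start$IC50 <- 10^(-p0) * 1e9 # nM
    start$pIC50 <- NULL
    form <- stats::as.formula(substitute(
      y ~ BOT + (top - BOT) / (1 + (xnM / IC50)^HILL),
      list(BOT = bot_term, HILL = hill_term)))
  }
  do_fit <- function(ynew) {
    fdb <- fd; fdb$y <- ynew
    minpack.lm::nlsLM(form, data = fdb, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit <- do_fit(y)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ses <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(pmax(diag(vc), 0))
  names(ses) <- names(cf)
  if (space == "ic50") {
    # delta method: pIC50 = -log10(IC50 nM * 1e-9)
    ic50_nM <- cf[["IC50"]]
    p_est <- -log10(ic50_nM * 1e-9)
    p_se <- ses[["IC50"]] / (ic50_nM * log(10))
    cf <- c(pIC50 = p_est, cf[setdiff(names(cf), "IC50")])
    ses <- c(pIC50 = p_se, ses[setdiff(names(ses), "IC50")])
  }
  full <- c("pIC50", "hill", "top", "bottom")
  est <- c(cf["pIC50"],
           if ("hill" %in% names(cf)) cf["hill"] else fix_hill,
           cf["top"],
           if ("bottom" %in% names(cf)) cf["bottom"] else 0)
  sev <- c(ses["pIC50"],
           if ("hill" %in% names(ses)) ses["hill"] else NA_real_,
           ses["top"],
           if ("bottom" %in% names(ses)) ses["bottom"] else NA_real_)
  if (se == "bootstrap") {
    res <- stats::resid(fit)
    fitted_y <- stats::fitted(fit)
    bs <- with_seed(as.integer(boot_seed), {
      t(vapply(seq_len(nboot), function(b) {
        yb <- fitted_y + sample(res, length(res), replace = TRUE)
        cb <- tryCatch(stats::coef(do_fit(yb)), error = function(e) NULL)
        out <- rep(NA_real_, length(full)); names(out) <- full
        if (!is.null(cb)) {
          if ("IC50" %in% names(cb)) {
            cb <- c(pIC50 = -log10(cb[["IC50"]] * 1e-9),
                    cb[setdiff(names(cb), "IC50")])
          }
          out[names(cb)] <- cb
        }
        out
      }, numeric(length(full))))
    })
    bse <- apply(bs, 2L, stats::sd, na.rm = TRUE)
    sev[!is.na(sev)] <- bse[!is.na(sev)]
  }
  converged <- isTRUE(fit$convInfo$isConv)
  out <- structure(
    list(coefficients = data.frame(param = full, estimate = unname(est),
                                   se = unname(sev),
                                   units = c("-log10(M)", "", "resp", "resp")),
         IC50 = 10^(-est[[1L]]),
         rss = sum(stats::resid(fit)^2),
         converged = converged,
         df_residual = stats::df.residual(fit),
         fixed = fixed, space = space),
    class = "competition_fit"
  )
  if (converged) {
    if (est[[2L]] <= 0) out$converged <- FALSE
    if (est[[3L]] <= est[[4L]]) out$converged <- FALSE
  }
  out
}

# shared assembly for saturation fits (covariance or bootstrap SEs)
build_fit <- function(fit, params, units, scale, se, nboot, boot_seed,
                      refit, class, mode) {
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ses <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(pmax(diag(vc), 0))
  if (se == "bootstrap") {
    res <- stats::resid(fit)
    fitted_y <- stats::fitted(fit)
    bs <- with_seed(as.integer(boot_seed), {
      t(vapply(seq_len(nboot), function(b) {
        yb <- fitted_y + sample(res, length(res), replace = TRUE)
        out <- tryCatch(refit(yb), error = function(e)
          rep(NA_real_, length(cf)))
        out
      }, numeric(length(cf))))
    })
    ses <- apply(bs, 2L, stats::sd, na.rm = TRUE)
  }
  structure(
    list(coefficients = data.frame(param = params,
                                   estimate = unname(cf) * scale,
                                   se = unname(ses) * scale,
                                   units = units),
         rss = sum(stats::resid(fit)^2),
         converged = isTRUE(fit$convInfo$isConv),
         df_residual = stats::df.residual(fit),
         mode = mode),
    class = class
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit>", if (x$converged) "converged" else "NOT CONVERGED",
      sprintf("(mode %s, RSS %.4g)\n", x$mode, x$rss))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("<competition_fit>", if (x$converged) "converged" else "NOT CONVERGED",
      sprintf("(RSS %.4g, IC50 %.3g M)\n", x$rss, x$IC50))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Extract a parameter estimate and its SE from a fit
#' @param fit a `saturation_fit` or `competition_fit`.
#' @param param parameter name as in the fit's coefficient table.
#' @return named list `estimate`, `se`.
#' @export
fit_param <- function(fit, param) {
  co <- fit$coefficients
  row <- co[co$param == param, ]
  if (nrow(row) != 1L) stop("unknown parameter '", param, "'")
  list(estimate = row$estimate, se = row$se)
}

#' Welch's unpaired t-test from summary statistics
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees-of-freedom
#' correction, computed from group means, standard errors and sizes --
#' the comparison used for binding parameters reported as mean +/- SEM.
#'
#' @param mean1,mean2 group means.
#' @param se1,se2 standard errors of the means (must be > 0).
#' @param n1,n2 group sizes.
#' @return list `t`, `df`, `p`, `difference`.
#' @export
welch_test <- function(mean1, se1, n1, mean2, se2, n2) {
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0) {
    stop("degenerate comparison: standard errors must be positive and finite")
  }
  v <- se1^2 + se2^2
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, difference = mean1 - mean2)
}

#' Compare a parameter between two fits (Welch t-test)
#'
#' Treats the two fitted parameters as means with their standard errors
#' and applies [welch_test()]. The p-value is reported against the
#' conventional 0.05 threshold but no decision is hard-coded.
#'
#' @param a,b converged fits of the same class.
#' @param param parameter name (e.g. `"pIC50"`, `"K_D"`).
#' @param n per-group sample sizes underlying the SEs, length-2 (default
#'   `c(6, 6)`: two experiments in triplicate).
#' @return a `welch_comparison` list: `param`, `estimates`, `t`, `df`,
#'   `p`, `alpha`.
#' @export
compare_fits <- function(a, b, param, n = c(6L, 6L)) {
  if (!isTRUE(a$converged) || !isTRUE(b$converged)) {
    stop("both fits must have converged")
  }
  pa <- fit_param(a, param); pb <- fit_param(b, param)
  w <- welch_test(pa$estimate, pa$se, n[1L], pb$estimate, pb$se, n[2L])
  structure(
    list(param = param,
         estimates = c(a = pa$estimate, b = pb$estimate),
         se = c(a = pa$se, b = pb$se),
         t = w$t, df = w$df, p = w$p, alpha = 0.05),
    class = "welch_comparison"
  )
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("<welch_comparison> %s: %.4g vs %.4g, t = %.3f (df %.1f), p = %.3g\n",
              x$param, x$estimates[1L], x$estimates[2L], x$t, x$df, x$p))
  invisible(x)
}
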