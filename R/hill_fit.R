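#' Hill binding isotherm
#'
#' `S_obs = S_U + (S_B - S_U) / (1 + (Kd_app / L)^n)`: at `L = Kd_app` the
#' signal is midway between the plateaus for any Hill coefficient `n`; as
#' `L -> 0` it tends to `S_U` and as `L -> Inf` to `S_B`.
#'
#' @param L Ligand concentration(s) (> 0).
#' @param S_U,S_B Unbound/bound signal plateaus.
#' @param Kd_app Apparent dissociation constant (> 0, same units as `L`).
#' @param n Hill coefficient (> 0).
#' @return Predicted signal.
#' @examples
#' hill_model(2, S_U = 0, S_B = 1, Kd_app = 2, n = 3)  # 0.5 at L = Kd
#' @export
hill_model <- function(L, S_U, S_B, Kd_app, n) {
  stopifnot(all(L > 0), Kd_app > 0, n > 0)
  S_U + (S_B - S_U) / (1 + (Kd_app / L)^n)
}

#' Fit the Hill equation to a titration
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' [hill_model()] in linear signal space. `Kd_app` and `n` are
#' log-parameterised internally so they stay positive and are reported on
#' the natural scale with delta-method standard errors from the local
#' curvature. `"auto"` initialisation takes the plateaus from the
#' lowest/highest-concentration signals, `Kd_app` from the half-signal
#' crossing and `n = 1`.
#'
#' @param concentrations Ligand concentrations (> 0, >= 4 points; a warning
#'   is given below 5 points or when the data do not bracket the fitted
#'   transition).
#' @param signals Observed signals, same length.
#' @param init `"auto"` or a named list/vector with `S_U`, `S_B`,
#'   `Kd_app`, `n`.
#' @return Object of class `hill_fit`: list with `S_U`, `S_B`, `Kd_app`,
#'   `n`, `se` (named vector), `residuals`, `rss`, `sigma`, `converged`,
#'   `plateau_warning` (TRUE when the highest concentration fails to
#'   constrain `S_B`, i.e. lies below ~2x the fitted `Kd_app` or the
#'   relative SE of `S_B - S_U` exceeds 20%), `data`.
#' @examples
#' d <- simulate_binding_curve(800, 950, Kd_app = 2, n = 1.5,
#'                             concentrations = 10^seq(-2, 2, length.out = 12),
#'                             noise_cv = 0, seed = 1)
#' fit_hill(d$concentration_uM, d$signal)
#' @export
fit_hill <- function(concentrations, signals, init = "auto") {
  L <- as.numeric(concentrations); y <- as.numeric(signals)
  if (length(L) != length(y)) stop("concentrations and signals differ in length")
  if (any(L <= 0)) stop("concentrations must be > 0")
  if (length(L) < 4) stop("need at least 4 points")
  if (length(L) < 5) warning("fewer than 5 points: fit poorly constrained")

  if (identical(init, "auto")) {
    o <- order(L)
    s_u0 <- y[o][1]; s_b0 <- y[o][length(y)]
    half <- (s_u0 + s_b0) / 2
    up <- s_b0 >= s_u0
    cross <- if (up) which(y[o] >= half) else which(y[o] <= half)
    kd0 <- if (length(cross)) L[o][cross[1]] else stats::median(L)
    init <- list(S_U = s_u0, S_B = s_b0, Kd_app = kd0, n = 1)
  }
  init <- as.list(init)
  stopifnot(all(c("S_U", "S_B", "Kd_app", "n") %in% names(init)),
            init$Kd_app > 0, init$n > 0)

  df <- data.frame(L = L, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ S_U + (S_B - S_U) / (1 + (exp(lKd) / L)^exp(ln)),
    data = df,
    start = list(S_U = init$S_U, S_B = init$S_B,
                 lKd = log(init$Kd_app), ln = log(init$n)),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Hill fit failed: ", attr(fit, "condition")$message)

  cf <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  se_raw <- if (inherits(vc, "try-error")) rep(NA_real_, 4) else sqrt(diag(vc))
  names(se_raw) <- names(cf)
  kd <- exp(cf[["lKd"]]); nn <- exp(cf[["ln"]])
  se <- c(S_U = unname(se_raw["S_U"]), S_B = unname(se_raw["S_B"]),
          Kd_app = kd * unname(se_raw["lKd"]),   # delta method
          n = nn * unname(se_raw["ln"]))
  conv <- fit$convInfo$isConv %||% TRUE
  res <- stats::residuals(fit)
  rel_amp_se <- {
    amp <- abs(cf[["S_B"]] - cf[["S_U"]])
    if (!inherits(vc, "try-error") && amp > 0) {
      v <- vc["S_B", "S_B"] + vc["S_U", "S_U"] - 2 * vc["S_U", "S_B"]
      sqrt(max(v, 0)) / amp
    } else NA_real_
  }
  plateau_warning <- kd * 2 > max(L) ||
    (!is.na(rel_amp_se) && rel_amp_se > 0.2)
  if (plateau_warning)
    warning("highest concentration does not constrain the bound plateau")

  structure(list(
    S_U = cf[["S_U"]], S_B = cf[["S_B"]], Kd_app = kd, n = nn,
    se = se, residuals = as.numeric(res),
    rss = sum(res^2), sigma = stats::sigma(fit),
    converged = isTRUE(conv), plateau_warning = plateau_warning,
    data = df), class = "hill_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit:\n")
  cat(sprintf("  S_U    = %.6g +/- %.3g\n", x$S_U, x$se["S_U"]))
  cat(sprintf("  S_B    = %.6g +/- %.3g\n", x$S_B, x$se["S_B"]))
  cat(sprintf("  Kd_app = %.6g +/- %.3g\n", x$Kd_app, x$se["Kd_app"]))
  cat(sprintf("  n      = %.6g +/- %.3g\n", x$n, x$se["n"]))
  cat(sprintf("  rss = %.4g, converged: %s%s\n", x$rss, x$converged,
              if (x$plateau_warning) " (plateau warning)" else ""))
  invisible(x)
}
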