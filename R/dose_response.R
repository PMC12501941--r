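#' Four-parameter logistic model
#'
#' `f(c) = bottom + (top - bottom) / (1 + (c / c0)^h)` in
#' percent-of-control units: `top` is the response at zero dose,
#' `bottom` the response at saturating dose, `c0` the midpoint
#' concentration and `h` the Hill slope (h > 0 gives a decreasing
#' curve).
#'
#' @param conc concentration vector (same units as `c0`).
#' @param bottom,top,h,c0 model parameters.
#' @return predicted response.
#' @export
fourpl <- function(conc, bottom, top, h, c0) {
  bottom + (top - bottom) / (1 + (conc / c0)^h)
}

#' Background correction and percent-of-control summarisation
#'
#' Per condition and replicate, the mean of the background (cell-free)
#' wells is subtracted from every well; each dose's corrected value is
#' divided by the corrected zero-dose (control) value and scaled to
#' percent. Replicates are then summarised per dose as mean and sd
#' across the independent experiments.
#'
#' @param readings data.frame with columns `condition`, `replicate`,
#'   `concentration_uM`, `intensity`, `is_background` (see
#'   [read_plate_csv()]). Dose 0 (non-background) wells are the
#'   controls.
#' @return data.frame: `condition`, `concentration_uM`, `mean_pct`,
#'   `sd_pct`, `n_rep`.
#' @export
percent_of_control <- function(readings) {
  out <- list()
  for (cond in unique(readings$condition)) {
    rc <- readings[readings$condition == cond, , drop = FALSE]
    reps <- unique(rc$replicate[!rc$is_background])
    per_rep <- list()
    for (r in reps) {
      rr <- rc[rc$replicate == r, , drop = FALSE]
      bg_wells <- rr$intensity[rr$is_background]
      if (length(bg_wells) == 0) {
        bg_wells <- rc$intensity[rc$is_background]   # shared background
      }
      if (length(bg_wells) == 0) {
        warning("no background wells for condition '", cond,
                "'; assuming background 0")
        bg <- 0
      } else bg <- mean(bg_wells)
      wells <- rr[!rr$is_background, , drop = FALSE]
      ctrl <- mean(wells$intensity[wells$concentration_uM == 0]) - bg
      if (!is.finite(ctrl) || ctrl <= 0)
        stop("corrected control signal <= 0 for condition '", cond, "'")
      pct <- stats::aggregate(
        intensity ~ concentration_uM, data = wells,
        FUN = function(x) 100 * (mean(x) - bg) / ctrl)
      names(pct)[2] <- "pct"
      pct$replicate <- r
      per_rep[[as.character(r)]] <- pct
    }
    all_rep <- do.call(rbind, per_rep)
    agg <- stats::aggregate(pct ~ concentration_uM, data = all_rep,
                            FUN = function(x) c(mean(x), stats::sd(x),
                                                length(x)))
    out[[cond]] <- data.frame(condition = cond,
                              concentration_uM = agg$concentration_uM,
                              mean_pct = agg$pct[, 1],
                              sd_pct = agg$pct[, 2],
                              n_rep = agg$pct[, 3],
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [fourpl()] to (dose, percent-of-control)
#' points. The zero dose (control) is excluded from the fit, which is
#' parameterised in log(c0) for stability. Initialisation is a
#' deterministic multi-start grid (c0 over the dose range, Hill slope
#' in {0.5, 1, 2, 4}); the best Nelder-Mead solution is polished by
#' BFGS with numerically exact gradients via `optim`'s finite
#' differences, giving reproducible fits without randomness.
#'
#' @param conc dose vector (>= 0; zeros dropped).
#' @param response percent-of-control at each dose.
#' @return a `dose_response_fit`: list with `bottom`, `top`, `h`, `c0`,
#'   `gi50`, `rss`, `converged`.
#' @export
fit_4pl <- function(conc, response) {
  ok <- is.finite(conc) & is.finite(response) & conc > 0
  x <- conc[ok]; y <- response[ok]
  if (length(unique(x)) < 4)
    stop("need >= 4 informative (nonzero-dose) points")
  rss_fun <- function(par) {
    pred <- fourpl(x, par[1], par[2], exp(par[4]), exp(par[3]))
    sum((y - pred)^2)
  }
  starts <- expand.grid(
    lc0 = log(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)),
    lh = log(c(0.5, 1, 2, 4)))
  bottom0 <- min(y); top0 <- max(y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(bottom0, top0, starts$lc0[i], starts$lh[i])
    fit <- tryCatch(
      stats::optim(p0, rss_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          h = NA_real_, c0 = NA_real_, gi50 = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "dose_response_fit"))
  polished <- tryCatch(
    stats::optim(best$par, rss_fun, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) best)
  if (!is.null(polished) && polished$value <= best$value) best <- polished
  # Gauss-Newton polish; scaleOffset keeps it stable at ~zero residuals
  nfit <- tryCatch({
    st <- list(b = best$par[1], t = best$par[2], lc0 = best$par[3],
               lh = best$par[4])
    fit <- suppressWarnings(
      stats::nls(y ~ fourpl(x, b, t, exp(lh), exp(lc0)),
                 start = st,
                 control = stats::nls.control(
                   maxiter = 200, tol = 1e-10, scaleOffset = 1,
                   warnOnly = TRUE)))
    cf <- stats::coef(fit)
    list(par = c(cf[["b"]], cf[["t"]], cf[["lc0"]], cf[["lh"]]),
         value = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(nfit) && is.finite(nfit$value) &&
      nfit$value <= best$value) best <- nfit
  par <- best$par
  out <- structure(list(bottom = par[1], top = par[2],
                        h = exp(par[4]), c0 = exp(par[3]),
                        gi50 = NA_real_, rss = best$value,
                        converged = TRUE),
                   class = "dose_response_fit")
  out$gi50 <- gi50(out)
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: bottom=%.3g top=%.3g hill=%.3g c0=%.4g | GI50=%s | rss=%.3g%s\n",
    x$bottom, x$top, x$h, x$c0,
    if (is.na(x$gi50)) "NA (no 50%% crossing)" else sprintf("%.4g", x$gi50),
    x$rss, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' GI50: the 50-percent-of-control crossing of a fitted curve
#'
#' Solved in closed form from the 4PL parameters:
#' `gi50 = c0 * ((top - 50) / (50 - bottom))^(1/h)`. Returns `NA` when
#' the fitted curve never crosses 50 (i.e. 50 is not strictly between
#' `bottom` and `top`). This is the absolute-response definition of
#' growth inhibition, distinct from the relative midpoint `c0` whenever
#' `bottom + top != 100`.
#'
#' @param fit a [fit_4pl()] result (or any list with `bottom`, `top`,
#'   `h`, `c0`).
#' @return concentration, or `NA` if 50% is never reached.
#' @export
gi50 <- function(fit) {
  if (!isTRUE(fit$converged) && !is.null(fit$converged) &&
      is.na(fit$bottom)) return(NA_real_)
  if (is.na(fit$h) || fit$h == 0) stop("Hill slope is zero")
  lo <- min(fit$bottom, fit$top); hi <- max(fit$bottom, fit$top)
  if (!(lo < 50 && 50 < hi)) return(NA_real_)
  fit$c0 * ((fit$top - 50) / (50 - fit$bottom))^(1 / fit$h)
}

#' Simulate a dose-response plate
#'
#' Generates fluorescence readings from a 4PL ground truth for testing
#' and demonstrations: control and dose wells per replicate, plus
#' cell-free background wells, with additive Gaussian noise.
#'
#' @param condition label for the condition.
#' @param doses nonzero dose vector (uM); a 0-dose control is added.
#' @param bottom,top,h,c0 true 4PL parameters (percent-of-control).
#' @param replicates number of independent experiments.
#' @param background true background fluorescence (a.u.).
#' @param control_signal corrected control fluorescence (a.u.).
#' @param noise_sd additive noise sd in percent-of-control units.
#' @param seed RNG seed.
#' @return data.frame in [read_plate_csv()] layout.
#' @export
simulate_plate <- function(condition = "cellline_2D",
                           doses = c(1, 3, 10, 30, 100, 300),
                           bottom = 5, top = 100, h = 1, c0 = 25,
                           replicates = 3, background = 100,
                           control_signal = 900, noise_sd = 5,
                           seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(replicates)) {
    conc <- c(0, doses)
    true_pct <- c(100, fourpl(doses, bottom, top, h, c0))
    pct <- true_pct + stats::rnorm(length(conc), 0, noise_sd)
    rows[[r]] <- data.frame(
      condition = condition, replicate = r, concentration_uM = conc,
      intensity = background + control_signal * pct / 100,
      is_background = FALSE, stringsAsFactors = FALSE)
  }
  bg <- data.frame(condition = condition, replicate = 1,
                   concentration_uM = NA_real_,
                   intensity = rep(background, 3),
                   is_background = TRUE, stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(bg)))
  rownames(out) <- NULL
  out
}
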