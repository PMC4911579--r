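#' Fit a transfer curve: threshold voltage and field-effect mobility
#'
#' In the saturation regime `sqrt(|I_DS|)` is linear in gate voltage; the
#' abscissa intercept of that line is the threshold voltage `V_T` and the
#' slope gives the field-effect mobility through
#' `mu = slope^2 * 2L / (W * C_i)`. `otft_fit()` selects a linear window on
#' the accumulation branch automatically and returns a classed model object.
#'
#' Window policy: sweep points on the accumulation branch are kept if their
#' current exceeds three times the sub-threshold floor (the median current
#' magnitude of the off-end quarter of the sweep); optionally the highest
#' `high_vg_exclude` fraction of overdrive points is dropped to dodge
#' contact-resistance roll-off. Among all contiguous windows covering at
#' least `min_frac` of the kept branch (and at least 4 points), the fit uses
#' the longest window whose R-squared of the `sqrt(|I|)` vs `V_G` line is at
#' least `r2_min`; if no window reaches `r2_min`, the window with maximal
#' R-squared is used. Preferring the longest sufficiently linear segment
#' reproduces the manual "linear segment" choice while keeping the slope
#' estimate stable under noise; a pure maximum-R-squared rule degenerates to
#' the shortest allowed window.
#'
#' @param curve A [transfer_curve()].
#' @param min_frac Minimum window length as a fraction of the kept
#'   accumulation branch (default 0.3).
#' @param r2_min Linearity criterion for window acceptance (default 0.995).
#' @param high_vg_exclude Fraction of kept points at the high-overdrive end
#'   excluded before window search (default 0; the R-squared criterion
#'   already rejects windows contaminated by roll-off).
#' @param window Optional integer indices into the sweep to force a window,
#'   bypassing the policy.
#' @return An object of class `"otft_fit"` with components
#'   `threshold_voltage` (V), `mobility` (m^2/Vs), `fit_window` (V_G range
#'   used), `fit_r2`, `n_points`, `slope`, `intercept`, `window_idx`, `lm`
#'   and `curve`.
#' @seealso [saturation_current()], [gen_transfer_curve()]
#' @export
#' @examples
#' vg <- seq(20, -100, by = -10)
#' i <- saturation_current(vg, -10, 1e-6, W = 4e-3, L = 200e-6, C_i = 9e-5)
#' fit <- otft_fit(transfer_curve(vg, i, W = 4e-3, L = 200e-6, C_i = 9e-5))
#' coef(fit)  # V_T = -10 V, mu = 1e-6 m^2/Vs
otft_fit <- function(curve, min_frac = 0.3, r2_min = 0.995,
                     high_vg_exclude = 0, window = NULL) {
  stopifnot(inherits(curve, "transfer_curve"))
  # orient the sweep along increasing overdrive (off-state first)
  ord <- order(curve$v_g, decreasing = (curve$polarity == "p"))
  vg <- curve$v_g[ord]
  inorm <- if (curve$polarity == "p") -curve$i_ds[ord] else curve$i_ds[ord]

  if (is.null(window)) {
    n <- length(vg)
    off_idx <- seq_len(max(1L, floor(n / 4)))
    floor_i <- stats::median(abs(inorm[off_idx]))
    keep <- which(inorm > 3 * floor_i)
    if (high_vg_exclude > 0 && length(keep) > 0) {
      drop_n <- floor(high_vg_exclude * length(keep))
      if (drop_n > 0) keep <- keep[seq_len(length(keep) - drop_n)]
    }
    if (length(keep) < 4L)
      stop("extraction failure: fewer than 4 accumulation-branch points ",
           "above 3x the sub-threshold floor (device '", curve$device_id,
           "')", call. = FALSE)
    sel <- select_window(vg, sqrt(pmax(inorm, 0)), keep, min_frac, r2_min)
    if (is.null(sel))
      stop("extraction failure: no contiguous window of >= 4 points meets ",
           "the linearity criterion (device '", curve$device_id, "')",
           call. = FALSE)
    widx <- sel
  } else {
    widx <- match(window, ord)  # caller gives original indices
    widx <- sort(widx[!is.na(widx)])
    if (length(widx) < 4L)
      stop("forced window has fewer than 4 points", call. = FALSE)
  }

  if (any(inorm[widx] < 0))
    stop("data-convention error: negative currents on the fitted branch ",
         "after polarity normalization (device '", curve$device_id, "')",
         call. = FALSE)

  s <- sqrt(inorm[widx])
  fit <- stats::lm(s ~ vg[widx])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b == 0)
    stop("extraction failure: zero slope in the fitted window", call. = FALSE)
  v_t <- -a / b
  mu <- b^2 * 2 * curve$L / (curve$W * curve$C_i)
  r2 <- r_squared(s, stats::fitted(fit))

  structure(
    list(threshold_voltage = v_t, mobility = mu,
         fit_window = range(vg[widx]), fit_r2 = r2,
         n_points = length(widx), slope = b, intercept = a,
         window_idx = sort(ord[widx]), lm = fit, curve = curve),
    class = "otft_fit")
}

r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  max(0, min(1, 1 - sum((y - yhat)^2) / sst))
}

# Longest contiguous window (>= minlen points) with R^2 >= r2_min on the
# sqrt-current line; falls back to the max-R^2 window. `keep` are indices
# into (vg, s) already ordered along increasing overdrive.
select_window <- function(vg, s, keep, min_frac, r2_min) {
  runs <- split(keep, cumsum(c(1, diff(keep) != 1)))
  minlen <- max(4L, ceiling(min_frac * length(keep)))
  best <- NULL; best_key <- c(-Inf, -Inf)   # (length if r2 ok else -Inf, r2)
  fallback <- NULL; fallback_r2 <- -Inf
  for (run in runs) {
    nr <- length(run)
    if (nr < minlen) next
    for (len in minlen:nr) {
      for (start in 1:(nr - len + 1)) {
        idx <- run[start:(start + len - 1)]
        r2 <- window_r2(vg[idx], s[idx])
        if (is.na(r2)) next
        if (r2 > fallback_r2) { fallback_r2 <- r2; fallback <- idx }
        if (r2 >= r2_min) {
          key <- c(len, r2)
          if (key[1] > best_key[1] ||
              (key[1] == best_key[1] && key[2] > best_key[2])) {
            best_key <- key; best <- idx
          }
        }
      }
    }
  }
  if (!is.null(best)) best else fallback
}

window_r2 <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  r_squared(y, mean(y) + b * (x - mean(x)))
}

#' @export
print.otft_fit <- function(x, ...) {
  cat(sprintf("OTFT figures of merit ('%s'):\n", x$curve$device_id))
  cat(sprintf("  V_T  = %.4g V\n", x$threshold_voltage))
  cat(sprintf("  mu   = %.4g m^2/Vs (%.4g cm^2/Vs)\n",
              x$mobility, x$mobility * 1e4))
  cat(sprintf("  window: V_G in [%.4g, %.4g] V, %d points, R^2 = %.5f\n",
              x$fit_window[1], x$fit_window[2], x$n_points, x$fit_r2))
  invisible(x)
}

#' @export
coef.otft_fit <- function(object, ...) {
  c(V_T = object$threshold_voltage, mu = object$mobility)
}

#' @export
summary.otft_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.otft_fit")
}

#' @export
print.summary.otft_fit <- function(x, ...) {
  print(x$fit)
  se <- stats::coef(x$lm_summary)[, "Std. Error"]
  # first-order propagation of the line coefficients to V_T
  b <- x$fit$slope; a <- x$fit$intercept
  se_vt <- sqrt((se[1] / b)^2 + (a * se[2] / b^2)^2)
  cat(sprintf("  approx SE: V_T %.3g V, mu %.3g m^2/Vs\n",
              se_vt, abs(2 * b * se[2]) * 2 * x$fit$curve$L /
                (x$fit$curve$W * x$fit$curve$C_i)))
  invisible(x)
}

#' Predicted saturation current from a fitted device
#'
#' @param object An [otft_fit()] object.
#' @param v_g Gate voltages at which to predict; defaults to the fitted
#'   sweep.
#' @param ... Unused.
#' @return Currents in amperes.
#' @export
predict.otft_fit <- function(object, v_g = NULL, ...) {
  if (is.null(v_g)) v_g <- object$curve$v_g
  cu <- object$curve
  saturation_current(v_g, object$threshold_voltage, object$mobility,
                     W = cu$W, L = cu$L, C_i = cu$C_i,
                     polarity = cu$polarity)
}

#' @export
residuals.otft_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.otft_fit <- function(object, ...) stats::fitted(object$lm)

#' Simulate replicate transfer curves from a fitted device
#'
#' Draws synthetic sweeps from the fitted `(V_T, mu)` with multiplicative
#' noise estimated from the fit residuals (relative residual spread on the
#' square-root scale, doubled to return to the current scale).
#'
#' @param object An [otft_fit()].
#' @param nsim Number of replicate curves.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [transfer_curve()] objects.
#' @export
simulate.otft_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cu <- object$curve
  s <- sqrt(abs(if (cu$polarity == "p") -cu$i_ds else cu$i_ds))[object$window_idx]
  noise_rel <- 2 * stats::sd(stats::residuals(object$lm)) / mean(s)
  if (!is.finite(noise_rel)) noise_rel <- 0
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(k)
    gen_transfer_curve(v_t = object$threshold_voltage, mu = object$mobility,
                       W = cu$W, L = cu$L, C_i = cu$C_i,
                       sweep = cu$v_g, v_ds = cu$v_ds,
                       polarity = cu$polarity, noise_rel = noise_rel,
                       seed = seed + k - 1L,
                       device_id = sprintf("%s_sim%d", cu$device_id, k)))
}

#' Plot a fitted transfer curve
#'
#' Square-root of the current magnitude against gate voltage, with the
#' selected fit window highlighted and the fitted line extrapolated to its
#' abscissa intercept (the threshold voltage).
#'
#' @param x An [otft_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.otft_fit <- function(x, ...) {
  cu <- x$curve
  s <- sqrt(abs(cu$i_ds))
  graphics::plot(cu$v_g, s, xlab = "V_G (V)",
                 ylab = expression(sqrt(abs(I[DS])) ~ (A^{1/2})), ...)
  graphics::points(cu$v_g[x$window_idx], s[x$window_idx], pch = 19)
  graphics::abline(a = x$intercept, b = x$slope, lty = 2)
  graphics::abline(v = x$threshold_voltage, col = "grey60", lty = 3)
  graphics::mtext(sprintf("V_T = %.3g V, mu = %.3g cm^2/Vs",
                          x$threshold_voltage, x$mobility * 1e4), cex = 0.8)
  invisible(x)
}
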