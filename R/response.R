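#' Normalized current response
#'
#' Fractional change of the channel current upon binding at fixed biases,
#' `(I - I0) / I0`, with the baseline `I0` measured before exposure. Both
#' currents must be evaluated at the same gate and drain bias; a decrease in
#' current magnitude gives a negative response. The normalization cancels
#' device-to-device gain variation, which is why it is the transducing
#' signal of choice for these biosensors.
#'
#' @param i_signal Current after binding (A).
#' @param i_baseline Baseline current (A), non-zero.
#' @param device_id Label used in the zero-baseline error.
#' @return Unitless fractional change.
#' @export
#' @examples
#' normalized_response(-0.7e-6, -1e-6)  # -0.30
normalized_response <- function(i_signal, i_baseline, device_id = "device") {
  if (any(i_baseline == 0))
    stop("zero baseline current for device '", device_id, "'", call. = FALSE)
  (i_signal - i_baseline) / i_baseline
}

#' First-order decoupling of the binding response
#'
#' Differentiating the saturation-current law at constant capacitance gives,
#' to first order,
#' `dI/I0 = dmu/mu0 - 2 * dV_T / (V_G - V_T0)`,
#' where `V_T0` and `mu0` are the baseline figures of merit. Given any two
#' of the three fractional terms the third is solved for; given independently
#' measured values of all three, the first-order closure residual is
#' reported instead.
#'
#' @param delta_I_rel Normalized current response `dI/I0` (unitless), or NULL.
#' @param delta_mu_rel Mobility fractional change `dmu/mu0`, or NULL.
#' @param delta_vt_term Threshold term `dV_T/(V_G - V_T0)`, or NULL.
#' @param v_g Gate voltage at which the response is evaluated (V; the study
#'   convention is -100 V). Metadata only.
#' @param v_t0,mu_0 Baseline threshold voltage (V) and mobility (m^2/Vs).
#'   Metadata only.
#' @param device_id Label.
#' @return A `"binding_response"` object: list with `delta_I_rel`,
#'   `delta_mu_rel`, `delta_vt_term`, `residual`, `eval_v_g`, `v_t0`,
#'   `mu_0`, `device_id`. When one term was solved for, `residual` is zero
#'   by construction.
#' @export
#' @examples
#' # electrostatic-only response: a threshold term of 0.16 predicts -0.32
#' decompose_response(delta_mu_rel = 0, delta_vt_term = 0.16)$delta_I_rel
decompose_response <- function(delta_I_rel = NULL, delta_mu_rel = NULL,
                               delta_vt_term = NULL, v_g = -100,
                               v_t0 = NA_real_, mu_0 = NA_real_,
                               device_id = "device") {
  supplied <- !c(is.null(delta_I_rel), is.null(delta_mu_rel),
                 is.null(delta_vt_term))
  if (sum(supplied) < 2L)
    stop("supply at least two of delta_I_rel, delta_mu_rel, delta_vt_term",
         call. = FALSE)
  if (all(supplied)) {
    residual <- delta_I_rel - (delta_mu_rel - 2 * delta_vt_term)
  } else {
    residual <- 0
    if (is.null(delta_I_rel)) {
      delta_I_rel <- delta_mu_rel - 2 * delta_vt_term
    } else if (is.null(delta_mu_rel)) {
      delta_mu_rel <- delta_I_rel + 2 * delta_vt_term
    } else {
      delta_vt_term <- (delta_mu_rel - delta_I_rel) / 2
    }
  }
  structure(list(delta_I_rel = delta_I_rel, delta_mu_rel = delta_mu_rel,
                 delta_vt_term = delta_vt_term, residual = residual,
                 eval_v_g = v_g, v_t0 = v_t0, mu_0 = mu_0,
                 device_id = device_id),
            class = "binding_response")
}

#' @export
print.binding_response <- function(x, ...) {
  cat(sprintf("Binding response '%s' (V_G = %g V):\n", x$device_id, x$eval_v_g))
  cat(sprintf("  dI/I0              = %+.4f\n", x$delta_I_rel))
  cat(sprintf("  dmu/mu0            = %+.4f\n", x$delta_mu_rel))
  cat(sprintf("  dV_T/(V_G - V_T0)  = %+.4f\n", x$delta_vt_term))
  cat(sprintf("  first-order residual %+.2e\n", x$residual))
  invisible(x)
}

#' Binding response of a baseline/signal device pair
#'
#' Extracts figures of merit from both sweeps, evaluates the measured
#' normalized current response at `v_g`, forms both first-order fractional
#' terms from the extracted figures, and reports the closure residual.
#'
#' @param baseline,signal [transfer_curve()] objects (or already-fitted
#'   [otft_fit()] objects) for the same device before and after binding.
#' @param v_g Evaluation gate voltage (default -100 V).
#' @param ... Passed to [otft_fit()].
#' @return A `"binding_response"` object; the threshold shift in volts is
#'   attached as `delta_vt` and the baseline figures as `v_t0`, `mu_0`.
#' @export
pair_response <- function(baseline, signal, v_g = -100, ...) {
  fit0 <- if (inherits(baseline, "otft_fit")) baseline else otft_fit(baseline, ...)
  fit1 <- if (inherits(signal, "otft_fit")) signal else otft_fit(signal, ...)
  i0 <- current_at(fit0$curve, v_g)
  i1 <- current_at(fit1$curve, v_g)
  vt0 <- fit0$threshold_voltage
  res <- decompose_response(
    delta_I_rel = normalized_response(i1, i0, fit0$curve$device_id),
    delta_mu_rel = fit1$mobility / fit0$mobility - 1,
    delta_vt_term = (fit1$threshold_voltage - vt0) / (v_g - vt0),
    v_g = v_g, v_t0 = vt0, mu_0 = fit0$mobility,
    device_id = fit0$curve$device_id)
  res$delta_vt <- fit1$threshold_voltage - vt0
  res
}

#' Aggregate replicate responses
#'
#' Mean, standard deviation and relative standard deviation (RSD, the
#' study's reproducibility error) over a group of device-level values.
#'
#' @param values Numeric vector of per-device responses (n >= 1).
#' @param member_ids Optional labels, recycled/defaulted to indices.
#' @param group Group label.
#' @return An `"aggregate_response"` object with `mean`, `sd`, `rsd`,
#'   `n_devices`, `member_ids`, `group`.
#' @export
aggregate_responses <- function(values, member_ids = NULL, group = "group") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no values to aggregate", call. = FALSE)
  if (is.null(member_ids)) member_ids <- as.character(seq_along(values))
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(list(mean = m, sd = s,
                 rsd = if (m != 0) s / abs(m) else NA_real_,
                 n_devices = length(values), values = values,
                 member_ids = member_ids, group = group),
            class = "aggregate_response")
}

#' @export
print.aggregate_response <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d, RSD %.3g)\n",
              x$group, x$mean, x$sd, x$n_devices,
              if (is.na(x$rsd)) NA else x$rsd))
  invisible(x)
}

#' Welch two-sided t-test between two device groups
#'
#' Compares two groups of replicate responses with the unequal-variance
#' (Welch) two-sample t-test, either from raw values or from summary
#' statistics (mean, SD, n), and returns a significance verdict at `alpha`.
#'
#' @param x,y Either numeric vectors of raw per-device values (n >= 2 each),
#'   or `"aggregate_response"` objects, or length-3 numeric vectors
#'   `c(mean, sd, n)`.
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `df`, `p_value`, `alpha`, `significant`
#'   and the two group summaries.
#' @export
#' @examples
#' compare_groups(c(-0.23, 0.01, 9), c(-0.30, 0.17, 9))$significant  # FALSE
compare_groups <- function(x, y, alpha = 0.05) {
  gx <- as_group_summary(x); gy <- as_group_summary(y)
  if (gx["n"] < 2 || gy["n"] < 2)
    stop("insufficient replicates: each group needs n >= 2", call. = FALSE)
  a <- gx["sd"]^2 / gx["n"]; b <- gy["sd"]^2 / gy["n"]
  if (a + b == 0) {
    tstat <- if (gx["mean"] == gy["mean"]) 0 else Inf
    df <- gx["n"] + gy["n"] - 2
  } else {
    tstat <- (gx["mean"] - gy["mean"]) / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (gx["n"] - 1) + b^2 / (gy["n"] - 1))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  list(statistic = unname(tstat), df = unname(df), p_value = unname(p),
       alpha = alpha, significant = unname(p < alpha),
       group1 = gx, group2 = gy)
}

as_group_summary <- function(g) {
  if (inherits(g, "aggregate_response"))
    return(c(mean = g$mean, sd = g$sd, n = g$n_devices))
  g <- as.numeric(g)
  if (length(g) == 3L && g[3] >= 1 && g[3] == round(g[3]))
    return(c(mean = g[1], sd = g[2], n = g[3]))
  c(mean = mean(g), sd = stats::sd(g), n = length(g))
}
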