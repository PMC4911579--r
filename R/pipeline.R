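#' Run the device track: extraction, decoupling and aggregation
#'
#' For every baseline/signal sweep pair this extracts the figures of merit
#' from both curves, evaluates the normalized current response at `v_g`,
#' forms the first-order mobility and threshold terms, and aggregates each
#' quantity per group (mean, SD, RSD). With exactly two groups a Welch
#' two-sided t-test on the normalized responses yields the
#' equivalent-response verdict.
#'
#' @param pairs List of `list(baseline = , signal = )` pairs of
#'   [transfer_curve()]s (e.g. from [gen_paired_curves()]); or NULL to pair
#'   `baselines`/`signals` by device id (a trailing `_baseline`/`_signal`
#'   suffix is ignored).
#' @param baselines,signals Alternative input: two lists of
#'   [transfer_curve()]s to be paired by id.
#' @param groups Group label per pair (e.g. `"FBI"`, `"PFC"`); default one
#'   group `"all"`.
#' @param v_g Evaluation gate voltage (default -100 V).
#' @param alpha Significance level of the group comparison (default 0.05).
#' @param ... Passed to [otft_fit()].
#' @return A `"device_track"` object: `devices` (per-device data.frame),
#'   `aggregates` (per group x quantity), `comparison` (Welch verdict or
#'   NULL), `v_g`, `alpha`.
#' @export
run_device_track <- function(pairs = NULL, baselines = NULL, signals = NULL,
                             groups = NULL, v_g = -100, alpha = 0.05, ...) {
  if (is.null(pairs)) {
    if (is.null(baselines) || is.null(signals) || !length(baselines))
      stop("pairing error: no baseline/signal pairs supplied", call. = FALSE)
    strip <- function(cs) sub("_(baseline|signal)$", "",
                              vapply(cs, function(c) c$device_id, ""))
    bid <- strip(baselines); sid <- strip(signals)
    unmatched <- c(setdiff(bid, sid), setdiff(sid, bid))
    if (length(unmatched))
      stop("pairing error: unmatched baseline/signal ids: ",
           paste(unique(unmatched), collapse = ", "), call. = FALSE)
    pairs <- lapply(seq_along(baselines), function(k)
      list(baseline = baselines[[k]], signal = signals[[match(bid[k], sid)]]))
  }
  if (!length(pairs))
    stop("pairing error: no baseline/signal pairs supplied", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(pairs))
  groups <- rep_len(as.character(groups), length(pairs))

  resp <- lapply(pairs, function(p)
    pair_response(p$baseline, p$signal, v_g = v_g, ...))
  devices <- data.frame(
    device = vapply(pairs, function(p) p$baseline$device_id, ""),
    group = groups,
    v_t0 = vapply(resp, function(r) r$v_t0, 0),
    mu0 = vapply(resp, function(r) r$mu_0, 0),
    delta_I_rel = vapply(resp, function(r) r$delta_I_rel, 0),
    delta_mu_rel = vapply(resp, function(r) r$delta_mu_rel, 0),
    delta_vt_term = vapply(resp, function(r) r$delta_vt_term, 0),
    delta_vt = vapply(resp, function(r) r$delta_vt, 0),
    residual = vapply(resp, function(r) r$residual, 0),
    stringsAsFactors = FALSE)

  quantities <- c("delta_I_rel", "delta_mu_rel", "delta_vt_term", "delta_vt")
  aggregates <- list()
  for (g in unique(groups))
    for (q in quantities)
      aggregates[[paste(g, q, sep = ".")]] <-
        aggregate_responses(devices[[q]][groups == g],
                            devices$device[groups == g],
                            group = paste(g, q, sep = "."))
  comparison <- NULL
  if (length(unique(groups)) == 2L) {
    gs <- unique(groups)
    a <- devices$delta_I_rel[groups == gs[1]]
    b <- devices$delta_I_rel[groups == gs[2]]
    if (length(a) >= 2 && length(b) >= 2)
      comparison <- c(compare_groups(a, b, alpha = alpha),
                      list(groups = gs, quantity = "delta_I_rel"))
  }
  structure(list(devices = devices, aggregates = aggregates,
                 comparison = comparison, v_g = v_g, alpha = alpha),
            class = "device_track")
}

#' @export
print.device_track <- function(x, ...) {
  cat(sprintf("Device track: %d pairs, V_G = %g V\n",
              nrow(x$devices), x$v_g))
  for (ag in x$aggregates)
    if (ag$n_devices > 0) print(ag)
  if (!is.null(x$comparison))
    cat(sprintf("  %s vs %s normalized response: p = %.3g -> %s at %.2g\n",
                x$comparison$groups[1], x$comparison$groups[2],
                x$comparison$p_value,
                if (x$comparison$significant) "significantly different"
                else "not significantly different", x$alpha))
  invisible(x)
}

#' Run the structural track: dipoles and loop fluctuations
#'
#' Static per-monomer and whole-complex dipole moments; when a trajectory
#' is supplied, trajectory-averaged dipole statistics and the per-loop RMSF
#' profile; when a second (ligand-bound) trajectory is supplied, the
#' open-versus-closed loop contrast table.
#'
#' @param structure A [charged_structure()]; if it carries no charges, `pH`
#'   or `charge_file` must be given.
#' @param trajectory Optional [trajectory()] of the (unbound/open) system.
#' @param bound_trajectory Optional [trajectory()] of the ligand-bound
#'   (closed) system sharing residue numbering.
#' @param loops Loop definitions (default [default_loops()]).
#' @param trim Equilibration trim (default 0.1; see [rmsf()]).
#' @param pH If given, charges are assigned by rule at this pH.
#' @param charge_file If given, per-atom charges are read from this file.
#' @param monomers Monomer scope for dipole statistics (default all).
#' @return A `"structural_track"` object.
#' @export
run_structural_track <- function(structure, trajectory = NULL,
                                 bound_trajectory = NULL,
                                 loops = default_loops(), trim = 0.1,
                                 pH = NULL, charge_file = NULL,
                                 monomers = NULL) {
  stopifnot(inherits(structure, "charged_structure"))
  if (!is.null(charge_file)) structure <- read_charge_file(structure, charge_file)
  else if (!is.null(pH)) structure <- assign_residue_charges(structure, pH)
  if (structure$provenance == "none" || all(structure$atoms$charge == 0))
    stop("configuration error: no charge provenance — supply `pH`, ",
         "`charge_file`, or a pre-charged structure", call. = FALSE)

  static_monomer <- monomer_dipoles(structure)
  static_complex <- dipole_moment(structure)$magnitude

  dip_stats <- rmsf_open <- loops_open <- NULL
  if (!is.null(trajectory)) {
    trajectory$topology <- structure  # carry charges onto the topology
    dip_stats <- trajectory_dipole_stats(trajectory, monomers = monomers,
                                         trim = trim)
    rmsf_open <- rmsf(trajectory, trim = trim)
    loops_open <- loop_rmsf(rmsf_open, loops)
  }
  contrast <- rmsf_closed <- NULL
  if (!is.null(bound_trajectory)) {
    rmsf_closed <- rmsf(bound_trajectory, trim = trim)
    loops_closed <- loop_rmsf(rmsf_closed, loops)
    contrast <- data.frame(loop = names(loops_open),
                           open = as.numeric(loops_open),
                           closed = as.numeric(loops_closed),
                           ratio = as.numeric(loops_open / loops_closed))
  }
  structure(list(static_monomer_dipoles = static_monomer,
                 static_complex_dipole = static_complex,
                 dipole_stats = dip_stats, rmsf = rmsf_open,
                 rmsf_bound = rmsf_closed, loop_rmsf = loops_open,
                 contrast = contrast,
                 charge_provenance = structure$provenance),
            class = "structural_track")
}

#' @export
print.structural_track <- function(x, ...) {
  cat("Structural track (charges:", x$charge_provenance, ")\n")
  cat("  static per-monomer dipoles (D):",
      paste(sprintf("%s=%.1f", names(x$static_monomer_dipoles),
                    x$static_monomer_dipoles), collapse = ", "), "\n")
  if (!is.null(x$dipole_stats))
    cat(sprintf("  trajectory dipole: %.1f +/- %.1f D over %d frames\n",
                x$dipole_stats$mean, x$dipole_stats$sd,
                x$dipole_stats$n_frames_used))
  else cat("  trajectory dipole: absent (static-only input)\n")
  if (!is.null(x$loop_rmsf))
    cat("  loop RMSF (A):",
        paste(sprintf("%s=%.2f", names(x$loop_rmsf), x$loop_rmsf),
              collapse = ", "), "\n")
  else cat("  RMSF: absent (static-only input)\n")
  if (!is.null(x$contrast)) {
    cat("  open/closed contrast:\n")
    print(x$contrast, row.names = FALSE)
  }
  invisible(x)
}

#' Bridge the structural prediction to the device measurement
#'
#' Converts a protein-layer dipole moment into a Helmholtz dipole-layer
#' threshold-voltage shift and scores its agreement with the measured
#' shift in units of the measurement SD. Shifts are compared as magnitudes
#' — the measurement convention reports a positive magnitude while the
#' electrostatic argument fixes the sign — with the signs carried
#' alongside.
#'
#' @param dipole_D Dipole moment of the complex layer (debye; signed
#'   values contribute their magnitude, the sign is reported).
#' @param measured_shift Measured threshold shift (V; sign reported,
#'   magnitude compared).
#' @param measured_sd One standard deviation of the measured shift (V).
#' @param eps_r,area_nm2 Passed to [helmholtz_vt_shift()].
#' @return A `"bridge_report"`: `predicted_vt_shift`, `measured_vt_shift`,
#'   `measured_sd`, `agreement_sd_units`, `within_one_sd`, signs and the
#'   inputs.
#' @export
#' @examples
#' run_bridge(283, measured_shift = 29.04, measured_sd = 5.45)
run_bridge <- function(dipole_D, measured_shift, measured_sd,
                       eps_r = 3, area_nm2 = 1.50) {
  if (measured_sd < 0) stop("measured_sd must be >= 0", call. = FALSE)
  pred <- helmholtz_vt_shift(abs(dipole_D), eps_r = eps_r,
                             area_nm2 = area_nm2)
  gap <- abs(pred - abs(measured_shift))
  if (measured_sd == 0) {
    if (gap > 0)
      warning("degenerate agreement: zero SD with predicted != measured",
              call. = FALSE)
    agree <- if (gap == 0) 0 else Inf
  } else agree <- gap / measured_sd
  structure(list(predicted_vt_shift = pred,
                 measured_vt_shift = abs(measured_shift),
                 measured_sd = measured_sd,
                 agreement_sd_units = agree,
                 within_one_sd = agree <= 1,
                 predicted_sign = sign(dipole_D),
                 measured_sign = sign(measured_shift),
                 dipole_D = abs(dipole_D), eps_r = eps_r,
                 area_nm2 = area_nm2),
            class = "bridge_report")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat("Helmholtz bridge:\n")
  cat(sprintf("  predicted |dV_T| = %.2f V (M = %g D, eps_r = %g, A = %g nm^2)\n",
              x$predicted_vt_shift, x$dipole_D, x$eps_r, x$area_nm2))
  cat(sprintf("  measured  |dV_T| = %.2f +/- %.2f V\n",
              x$measured_vt_shift, x$measured_sd))
  cat(sprintf("  agreement: %.2f SD -> %s the 1-SD criterion\n",
              x$agreement_sd_units,
              if (x$within_one_sd) "within" else "outside"))
  invisible(x)
}

# flatten a track object into plain lists for serialization
as_report_list <- function(x) {
  if (inherits(x, "device_track")) {
    list(kind = "device_track", v_g = x$v_g, alpha = x$alpha,
         devices = x$devices,
         aggregates = lapply(x$aggregates, function(a)
           list(mean = a$mean, sd = a$sd, rsd = a$rsd, n = a$n_devices)),
         comparison = if (is.null(x$comparison)) NULL else
           x$comparison[c("statistic", "df", "p_value", "significant")])
  } else if (inherits(x, "structural_track")) {
    list(kind = "structural_track",
         static_monomer_dipoles = as.list(x$static_monomer_dipoles),
         static_complex_dipole = x$static_complex_dipole,
         dipole_mean = if (is.null(x$dipole_stats)) NULL else x$dipole_stats$mean,
         dipole_sd = if (is.null(x$dipole_stats)) NULL else x$dipole_stats$sd,
         loop_rmsf = if (is.null(x$loop_rmsf)) NULL else as.list(x$loop_rmsf),
         contrast = x$contrast)
  } else if (inherits(x, "bridge_report")) {
    list(kind = "bridge_report",
         predicted_vt_shift = x$predicted_vt_shift,
         measured_vt_shift = x$measured_vt_shift,
         measured_sd = x$measured_sd,
         agreement_sd_units = x$agreement_sd_units,
         within_one_sd = x$within_one_sd)
  } else stop("no report serialization for this object", call. = FALSE)
}

#' Write a machine-readable and a human-readable report
#'
#' Serializes a device-track, structural-track or bridge result to
#' `<stem>.json` (machine-readable) and `<stem>.md` (summary of the
#' printed output).
#'
#' @param x A `"device_track"`, `"structural_track"` or `"bridge_report"`.
#' @param stem Output path without extension.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(x, stem) {
  json <- paste0(stem, ".json"); md <- paste0(stem, ".md")
  jsonlite::write_json(as_report_list(x), json, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  txt <- utils::capture.output(print(x))
  writeLines(c(paste("#", class(x)[1]), "", "```", txt, "```"), md)
  invisible(c(json, md))
}
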