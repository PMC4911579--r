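#' Construct a transfer curve
#'
#' A transfer curve is one gate sweep of the drain-source current measured at
#' fixed drain bias, together with the device geometry and gate-dielectric
#' capacitance needed to convert the square-root-slope into a field-effect
#' mobility.
#'
#' All quantities are SI: volts, amperes, meters, farad per square meter.
#' The study devices are p-type (P3HT channel): the accumulation branch lies
#' at gate voltages below threshold and carries negative drain current at
#' negative drain bias.
#'
#' @param v_g Gate voltage sweep (V), monotone, length >= 4.
#' @param i_ds Drain-source current (A), same length as `v_g`.
#' @param v_ds Drain bias (V), scalar. Default -80 V.
#' @param W Channel width (m).
#' @param L Channel length (m).
#' @param C_i Gate capacitance per unit area (F/m^2).
#' @param polarity `"p"` or `"n"` carrier type.
#' @param device_id Label used in error messages and reports.
#' @return An object of class `"transfer_curve"`.
#' @export
#' @examples
#' vg <- seq(20, -100, by = -10)
#' i <- saturation_current(vg, v_t = -10, mu = 1e-6,
#'                         W = 4e-3, L = 200e-6, C_i = 9e-5)
#' tc <- transfer_curve(vg, i, W = 4e-3, L = 200e-6, C_i = 9e-5)
transfer_curve <- function(v_g, i_ds, v_ds = -80, W, L, C_i,
                           polarity = c("p", "n"), device_id = "device") {
  polarity <- match.arg(polarity)
  if (length(v_g) != length(i_ds))
    stop("`v_g` and `i_ds` must have the same length", call. = FALSE)
  if (length(v_g) < 4L)
    stop("a transfer curve needs at least 4 sweep points", call. = FALSE)
  dv <- diff(v_g)
  if (!(all(dv > 0) || all(dv < 0)))
    stop("`v_g` must be a monotone sweep", call. = FALSE)
  if (!all(is.finite(v_g)) || !all(is.finite(i_ds)))
    stop("non-finite values in sweep", call. = FALSE)
  check_geometry(W, L, C_i)
  structure(
    list(v_g = as.numeric(v_g), i_ds = as.numeric(i_ds),
         v_ds = as.numeric(v_ds)[1], W = W, L = L, C_i = C_i,
         polarity = polarity, device_id = as.character(device_id)[1]),
    class = "transfer_curve")
}

check_geometry <- function(W, L, C_i) {
  for (nm in c("W", "L", "C_i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf("Transfer curve '%s' (%s-type)\n", x$device_id, x$polarity))
  cat(sprintf("  V_G sweep : %+g to %+g V (%d points), V_DS = %g V\n",
              x$v_g[1], x$v_g[length(x$v_g)], length(x$v_g), x$v_ds))
  cat(sprintf("  |I_DS| range: %.3g to %.3g A\n",
              min(abs(x$i_ds)), max(abs(x$i_ds))))
  cat(sprintf("  W = %g m, L = %g m, C_i = %g F/m^2\n", x$W, x$L, x$C_i))
  invisible(x)
}

#' Saturation-regime channel current
#'
#' Gradual-channel saturation current of a thin-film transistor,
#' `I_DS = (W / 2L) * C_i * mu * (V_G - V_T)^2`, evaluated on the
#' accumulation side of threshold and zero on the off side. For p-type
#' devices the accumulation side is `V_G < V_T` and the returned current is
#' negative (conventional sign at negative drain bias); for n-type it is
#' `V_G > V_T` with positive current.
#'
#' @param v_g Gate voltage(s), V.
#' @param v_t Threshold voltage, V.
#' @param mu Field-effect mobility, m^2 V^-1 s^-1
#'   (0.01 cm^2/Vs = 1e-6 m^2/Vs).
#' @param W,L,C_i Channel width (m), length (m) and gate capacitance per
#'   area (F/m^2); all strictly positive.
#' @param polarity `"p"` (default) or `"n"`.
#' @return Current(s) in amperes, same length as `v_g`.
#' @export
#' @examples
#' # the study geometry: W = 4 mm, L = 200 um, C_i = 9 nF/cm^2
#' saturation_current(-100, v_t = -10, mu = 1e-6,
#'                    W = 4e-3, L = 200e-6, C_i = 9e-5)  # -7.29e-6 A
saturation_current <- function(v_g, v_t, mu, W, L, C_i,
                               polarity = c("p", "n")) {
  polarity <- match.arg(polarity)
  check_geometry(W, L, C_i)
  if (!is.numeric(mu) || mu <= 0)
    stop("`mu` must be a single positive number", call. = FALSE)
  ov <- v_g - v_t                       # overdrive
  on <- if (polarity == "p") ov <= 0 else ov >= 0
  i <- (W / (2 * L)) * C_i * mu * ov^2 * on
  if (polarity == "p") -i else i
}

#' Read / write transfer curves as delimited text
#'
#' The on-disk dialect is a delimited text file with a header row and columns
#' `v_g` (V) and `i_ds` (A), optionally `v_ds` (V); device metadata (channel
#' geometry, capacitance, polarity, id) lives in a YAML sidecar or is passed
#' as a list.
#'
#' @param file Path of the delimited file.
#' @param meta Either a path to a YAML file with fields `W`, `L`, `C_i`,
#'   optionally `polarity`, `device_id`, `v_ds`, or a named list with the
#'   same fields. Defaults to `<file>.yml` when that exists.
#' @param sep Field separator (default tab).
#' @return `read_iv()` returns a [transfer_curve()]; `write_iv()` returns
#'   `file` invisibly.
#' @export
read_iv <- function(file, meta = NULL, sep = "\t") {
  if (is.null(meta)) {
    side <- paste0(file, ".yml")
    if (!file.exists(side))
      stop("no metadata: supply `meta` or a '", side, "' sidecar", call. = FALSE)
    meta <- side
  }
  if (is.character(meta)) meta <- yaml::read_yaml(meta)
  dat <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("v_g", "i_ds")
  if (!all(need %in% names(dat)))
    stop("file must contain columns `v_g` and `i_ds`", call. = FALSE)
  v_ds <- if ("v_ds" %in% names(dat)) dat$v_ds[1] else
    if (!is.null(meta$v_ds)) meta$v_ds else -80
  transfer_curve(dat$v_g, dat$i_ds, v_ds = v_ds,
                 W = meta$W, L = meta$L, C_i = meta$C_i,
                 polarity = if (is.null(meta$polarity)) "p" else meta$polarity,
                 device_id = if (is.null(meta$device_id)) basename(file)
                             else meta$device_id)
}

#' @rdname read_iv
#' @param curve A [transfer_curve()].
#' @param write_meta Write the YAML sidecar `<file>.yml` (default TRUE).
#' @export
write_iv <- function(curve, file, sep = "\t", write_meta = TRUE) {
  stopifnot(inherits(curve, "transfer_curve"))
  dat <- data.frame(v_g = curve$v_g, i_ds = curve$i_ds, v_ds = curve$v_ds)
  utils::write.table(dat, file, sep = sep, row.names = FALSE, quote = FALSE)
  if (write_meta) {
    meta <- list(W = curve$W, L = curve$L, C_i = curve$C_i,
                 polarity = curve$polarity, device_id = curve$device_id,
                 v_ds = curve$v_ds)
    yaml::write_yaml(meta, paste0(file, ".yml"))
  }
  invisible(file)
}

#' Current at a given gate voltage, by lookup or interpolation
#'
#' @param curve A [transfer_curve()].
#' @param v_g Gate voltage at which to evaluate (must lie inside the sweep).
#' @return Current in amperes.
#' @export
current_at <- function(curve, v_g) {
  stopifnot(inherits(curve, "transfer_curve"))
  rng <- range(curve$v_g)
  if (v_g < rng[1] || v_g > rng[2])
    stop(sprintf("V_G = %g V outside the sweep of '%s'", v_g, curve$device_id),
         call. = FALSE)
  ord <- order(curve$v_g)
  stats::approx(curve$v_g[ord], curve$i_ds[ord], xout = v_g,
                ties = "ordered")$y
}
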