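# run `code` under a fixed seed without disturbing the caller's RNG stream;
# a NULL seed draws from the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic transfer curve with known ground truth
#'
#' Forward model: the saturation-regime current for the requested
#' `(V_T, mu)`, multiplied by lognormal noise of a given relative spread
#' (device-to-device gain variation dominates in these transistors), plus a
#' constant gate-leakage floor, and — optionally — a soft contact-resistance
#' roll-off that compresses the current beyond a gate-voltage onset, as seen
#' in real devices where electrode wetting raises the injection barrier.
#'
#' Deterministic under a fixed `seed`; with `seed = NULL` the current RNG
#' stream is used (so batch generators can derive many curves from one
#' seed).
#'
#' @param v_t True threshold voltage (V).
#' @param mu True mobility (m^2/Vs; 0.01 cm^2/Vs = 1e-6).
#' @param W,L,C_i Geometry and capacitance; defaults are the study device
#'   (W = 4 mm, L = 200 um, C_i = 9 nF/cm^2 = 9e-5 F/m^2).
#' @param sweep Either a full V_G vector or `c(start, stop, step)`;
#'   default `c(20, -100, -10)`, the study sweep.
#' @param v_ds Drain bias (default -80 V).
#' @param polarity `"p"` (default) or `"n"`.
#' @param noise_rel Relative SD of the multiplicative noise (default 0).
#' @param leakage Gate-leakage floor magnitude (A), added with the channel
#'   sign (default 0).
#' @param rolloff_onset Gate voltage beyond which contact roll-off sets in
#'   (NULL = none).
#' @param rolloff_strength Fraction of the above-onset current increment
#'   retained (default 0.2; smaller = harder saturation).
#' @param seed Integer seed or NULL.
#' @param device_id Label.
#' @return A [transfer_curve()].
#' @export
#' @examples
#' tc <- gen_transfer_curve(v_t = -10, mu = 1e-6, seed = 1)
#' coef(otft_fit(tc))
gen_transfer_curve <- function(v_t, mu, W = 4e-3, L = 200e-6, C_i = 9e-5,
                               sweep = c(20, -100, -10), v_ds = -80,
                               polarity = c("p", "n"), noise_rel = 0,
                               leakage = 0, rolloff_onset = NULL,
                               rolloff_strength = 0.2, seed = NULL,
                               device_id = "synthetic") {
  polarity <- match.arg(polarity)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  v_g <- if (length(sweep) == 3L && sign(sweep[2] - sweep[1]) ==
               sign(sweep[3])) seq(sweep[1], sweep[2], by = sweep[3])
         else if (length(sweep) > 3L) sweep
         else stop("sweep must be c(start, stop, step) with consistent sign ",
                   "or a full V_G vector", call. = FALSE)
  with_seed(seed, {
    mag <- abs(saturation_current(v_g, v_t, mu, W, L, C_i, polarity))
    if (!is.null(rolloff_onset)) {
      past <- if (polarity == "p") v_g < rolloff_onset else v_g > rolloff_onset
      mag_on <- abs(saturation_current(rolloff_onset, v_t, mu, W, L, C_i,
                                       polarity))
      mag[past] <- mag_on + rolloff_strength * (mag[past] - mag_on)
    }
    if (noise_rel > 0) {
      sdlog <- sqrt(log1p(noise_rel^2))
      mag <- mag * stats::rlnorm(length(mag), -sdlog^2 / 2, sdlog)
    }
    mag <- mag + abs(leakage)
    i <- if (polarity == "p") -mag else mag
    transfer_curve(v_g, i, v_ds = v_ds, W = W, L = L, C_i = C_i,
                   polarity = polarity, device_id = device_id)
  })
}

#' Generate a baseline/signal curve pair with injected binding effects
#'
#' Draws two sweeps from one RNG stream: the baseline at `(v_t0, mu0)` and
#' the signal at `(v_t0 + delta_vt, mu0 * (1 + delta_mu_rel))`, emulating a
#' binding event that shifts the threshold voltage (electrostatic channel)
#' and/or scales the mobility (conformational channel).
#'
#' @param v_t0,mu0 Baseline figures of merit.
#' @param delta_vt Injected threshold shift (V, signed).
#' @param delta_mu_rel Injected fractional mobility change.
#' @param seed Integer seed (both curves derive from it) or NULL.
#' @param device_id Pair label.
#' @param ... Passed to [gen_transfer_curve()] (noise, geometry, roll-off).
#' @return List with elements `baseline` and `signal`
#'   ([transfer_curve()]s) and the injected truth `truth`.
#' @export
gen_paired_curves <- function(v_t0, mu0, delta_vt = 0, delta_mu_rel = 0,
                              seed = NULL, device_id = "pair", ...) {
  with_seed(seed, {
    base <- gen_transfer_curve(v_t0, mu0, seed = NULL,
                               device_id = paste0(device_id, "_baseline"), ...)
    sig <- gen_transfer_curve(v_t0 + delta_vt, mu0 * (1 + delta_mu_rel),
                              seed = NULL,
                              device_id = paste0(device_id, "_signal"), ...)
    list(baseline = base, signal = sig,
         truth = list(v_t0 = v_t0, mu0 = mu0, delta_vt = delta_vt,
                      delta_mu_rel = delta_mu_rel))
  })
}

#' Generate a bead-model tetramer with prescribed per-monomer dipoles
#'
#' A coarse stand-in for a homotetrameric biotin-binding protein: each
#' monomer is a compact Gaussian cluster of C-alpha-like beads carrying
#' balanced +1/-1 formal charges, plus one corrective charge pair placed so
#' the per-monomer dipole equals `target_dipole` exactly (the monomer is
#' net-neutral, so its dipole is origin-independent and the correction is
#' closed-form). Beads have unit mass, making the center of mass the
#' centroid. The corrective pair carries residue name `"DPC"` and atom name
#' `"DP"` so it stays out of C-alpha selections.
#'
#' @param n_monomers Number of monomers (default 4).
#' @param n_residues Beads per monomer (default 128, an avidin-sized
#'   monomer so the 35-45 and 70-75 loop ranges exist).
#' @param n_charged_pairs Number of +1/-1 bead pairs per monomer; the
#'   default scales as `min(12, n_residues %/% 4)` so small test beads stay
#'   feasible.
#' @param target_dipole Per-monomer dipole magnitude (debye, >= 0).
#' @param dipole_direction Unit 3-vector for the dipole axis (default +z,
#'   the axis facing the semiconductor in the layer picture).
#' @param cluster_sd Bead spread within a monomer (angstrom, default 8).
#' @param spacing Monomer center spacing (angstrom, default 40).
#' @param seed Integer seed or NULL.
#' @return A [charged_structure()] with provenance `"synthetic"`.
#' @export
#' @examples
#' s <- gen_bead_tetramer(target_dipole = 154, seed = 1)
#' monomer_dipoles(s)
gen_bead_tetramer <- function(n_monomers = 4, n_residues = 128,
                              n_charged_pairs = NULL, target_dipole = 154,
                              dipole_direction = c(0, 0, 1),
                              cluster_sd = 8, spacing = 40, seed = NULL) {
  if (target_dipole < 0) stop("target_dipole must be >= 0", call. = FALSE)
  if (is.null(n_charged_pairs))
    n_charged_pairs <- min(12L, n_residues %/% 4L)
  if (2 * n_charged_pairs > n_residues)
    stop("more charged beads than beads", call. = FALSE)
  u <- dipole_direction / sqrt(sum(dipole_direction^2))
  centers <- rbind(c(0, 0, 0), c(spacing, 0, 0), c(0, spacing, 0),
                   c(spacing / 2, spacing / 2, spacing))
  centers <- centers[rep_len(seq_len(nrow(centers)), n_monomers), ,
                     drop = FALSE]
  with_seed(seed, {
    rows <- vector("list", n_monomers)
    for (m in seq_len(n_monomers)) {
      xyz <- sweep(matrix(stats::rnorm(n_residues * 3, 0, cluster_sd),
                          ncol = 3), 2, centers[m, ], `+`)
      q <- numeric(n_residues)
      picked <- sample.int(n_residues, 2 * n_charged_pairs)
      q[picked] <- rep(c(1, -1), n_charged_pairs)
      d0 <- colSums(q * xyz)                         # e*angstrom
      delta <- target_dipole / .const$e_ang_to_D * u - d0
      qp <- max(1, ceiling(sqrt(sum(delta^2)) / 8))  # keep the pair compact
      sep <- delta / qp
      com <- colMeans(xyz)
      pair <- rbind(com + sep / 2, com - sep / 2)
      lab <- LETTERS[m]
      rows[[m]] <- data.frame(
        serial = 0L,
        elety = c(rep("CA", n_residues), "DP", "DP"),
        resid = c(rep("BEA", n_residues), "DPC", "DPC"),
        resno = c(seq_len(n_residues), n_residues + 1L, n_residues + 2L),
        monomer = lab,
        x = c(xyz[, 1], pair[, 1]), y = c(xyz[, 2], pair[, 2]),
        z = c(xyz[, 3], pair[, 3]),
        mass = 1, charge = c(q, qp, -qp), element = "C",
        stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    charged_structure(atoms, provenance = "synthetic")
  })
}

#' Generate a harmonic-wobble trajectory with prescribed fluctuations
#'
#' Each frame displaces every bead independently by an isotropic Gaussian
#' of its residue's per-axis sigma — a white-noise stand-in for thermal
#' fluctuation whose analytic RMSF is `sigma * sqrt(3)`. Loop residues can
#' be given their own sigma to emulate the open (large-fluctuation) versus
#' closed (clamped) conformational regimes of the binding-pocket loops.
#' Optionally a slow rigid rotation+drift is applied to whole frames to
#' exercise the alignment step, and the per-monomer dipole magnitude can be
#' given Gaussian jitter (realized by sliding the corrective charge pair of
#' [gen_bead_tetramer()] structures along the dipole axis), so that
#' trajectory dipole statistics have a known mean and spread.
#'
#' Frames are independent (white) rather than autocorrelated — sufficient
#' for fluctuation-amplitude targets, though unlike real dynamics.
#'
#' @param structure Base [charged_structure()].
#' @param n_frames Number of frames (>= 2).
#' @param sigma Default per-axis displacement SD (angstrom).
#' @param loops Optional list of [loop_definition()]s.
#' @param loop_sigma Per-axis sigma for each loop in `loops` (recycled).
#' @param per_residue_sigma Optional named vector (names = residue numbers)
#'   overriding sigma residue-by-residue; applied across all monomers.
#' @param dipole_sigma_D SD of the per-frame, per-monomer dipole-magnitude
#'   jitter (debye, default 0; needs `"DPC"` corrective-pair beads).
#' @param rigid_motion Apply a slowly ramping global rotation and drift
#'   (default FALSE).
#' @param frame_spacing_ps Frame spacing (default 10 ps).
#' @param seed Integer seed or NULL.
#' @return A [trajectory()].
#' @export
gen_wobble_trajectory <- function(structure, n_frames = 500, sigma = 0.5,
                                  loops = NULL, loop_sigma = NULL,
                                  per_residue_sigma = NULL,
                                  dipole_sigma_D = 0, rigid_motion = FALSE,
                                  frame_spacing_ps = 10, seed = NULL) {
  stopifnot(inherits(structure, "charged_structure"))
  if (n_frames < 2) stop("need n_frames >= 2", call. = FALSE)
  atoms <- structure$atoms
  nat <- nrow(atoms)
  sig_atom <- rep(sigma, nat)
  if (!is.null(loops)) {
    loop_sigma <- rep_len(loop_sigma, length(loops))
    for (j in seq_along(loops)) {
      lp <- loops[[j]]
      sel <- atoms$resno >= lp$first & atoms$resno <= lp$last
      if (!identical(lp$monomers, "all"))
        sel <- sel & atoms$monomer %in% lp$monomers
      sig_atom[sel] <- loop_sigma[j]
    }
  }
  if (!is.null(per_residue_sigma)) {
    m <- match(as.character(atoms$resno), names(per_residue_sigma))
    sig_atom[!is.na(m)] <- per_residue_sigma[m[!is.na(m)]]
  }
  if (any(sig_atom < 0)) stop("sigma must be >= 0", call. = FALSE)

  base <- coords(structure)
  monos <- unique(atoms$monomer)
  # dipole axis and corrective-pair bookkeeping per monomer
  pair_info <- NULL
  if (dipole_sigma_D > 0) {
    pair_info <- lapply(monos, function(mn) {
      idx <- which(atoms$monomer == mn & atoms$resid == "DPC")
      if (length(idx) != 2)
        stop("dipole jitter needs the corrective pair ('DPC' beads) of ",
             "gen_bead_tetramer() in monomer '", mn, "'", call. = FALSE)
      v <- dipole_moment(structure, mn)$vector
      nv <- sqrt(sum(v^2))
      list(plus = idx[which.max(atoms$charge[idx])],
           minus = idx[which.min(atoms$charge[idx])],
           q = abs(atoms$charge[idx[1]]),
           u = if (nv > 0) v / nv else c(0, 0, 1))
    })
    names(pair_info) <- monos
  }

  with_seed(seed, {
    arr <- array(NA_real_, c(nat, 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- base + matrix(stats::rnorm(nat * 3), ncol = 3) * sig_atom
      if (!is.null(pair_info)) {
        for (mn in monos) {
          pi_ <- pair_info[[mn]]
          delta <- stats::rnorm(1, 0, dipole_sigma_D)
          shift <- delta / (2 * .const$e_ang_to_D * pi_$q) * pi_$u
          xyz[pi_$plus, ] <- xyz[pi_$plus, ] + shift
          xyz[pi_$minus, ] <- xyz[pi_$minus, ] - shift
        }
      }
      if (rigid_motion) {
        th <- 0.4 * f / n_frames            # up to ~23 degrees
        Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                     3, 3, byrow = TRUE)
        xyz <- xyz %*% t(Rz) + matrix(0.02 * f, nat, 3)
      }
      arr[, , f] <- xyz
    }
    trajectory(structure, arr, frame_spacing_ps = frame_spacing_ps)
  })
}
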