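#' Construct a trajectory
#'
#' An ordered frame series over a fixed topology. Coordinates are stored as
#' an `n_atoms x 3 x n_frames` array in angstrom.
#'
#' @param topology A [charged_structure()].
#' @param coords Either an `n x 3 x n_frames` array or a list of `n x 3`
#'   matrices.
#' @param frame_spacing_ps Time between saved frames in picoseconds
#'   (default 10, the study's save interval).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, frame_spacing_ps = 10) {
  stopifnot(inherits(topology, "charged_structure"))
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("`coords` must be an n x 3 x n_frames array", call. = FALSE)
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("frame atom count does not match topology", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 frame_spacing_ps = frame_spacing_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (%g ps spacing, %g ns total)\n",
              d[3], d[1], x$frame_spacing_ps,
              d[3] * x$frame_spacing_ps / 1000))
  invisible(x)
}

#' @export
#' @rdname trajectory
#' @param x A trajectory.
#' @param i Frame index.
frame_coords <- function(x, i) {
  stopifnot(inherits(x, "trajectory"))
  x$coords[, , i, drop = TRUE]
}

n_frames <- function(x) dim(x$coords)[3]

# selection -> integer atom indices. NULL/"all" = everything, "calpha" = CA
# atoms, logical/integer passed through.
resolve_selection <- function(topology, selection) {
  atoms <- topology$atoms
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.character(selection) && length(selection) == 1L) {
    if (selection == "all") return(seq_len(nrow(atoms)))
    if (selection == "calpha") {
      idx <- which(atoms$elety == "CA")
      if (!length(idx)) stop("no C-alpha atoms in topology", call. = FALSE)
      return(idx)
    }
  }
  if (is.character(selection)) return(which(atoms$monomer %in% selection))
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD between two paired coordinate sets. Reflections are rejected: the
#' returned rotation always has determinant +1, since mirror fits are
#' unphysical for proteins.
#'
#' @param reference,mobile `n x 3` matrices, `n >= 3`, not all collinear.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (angstrom, post-fit over the fitted atoms) and a helper
#'   `transform(xyz)` applying the fit to arbitrary coordinates.
#' @export
superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3)
    stop("coordinate sets must be matching n x 3 matrices", call. = FALSE)
  n <- nrow(reference)
  if (n < 3) stop("superposition error: need >= 3 atoms", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0)
    stop("invalid superposition weights", call. = FALSE)
  w <- weights / sum(weights)
  cref <- colSums(reference * w); cmob <- colSums(mobile * w)
  P <- sweep(reference, 2, cref); Q <- sweep(mobile, 2, cmob)
  A <- t(Q * w) %*% P                       # 3 x 3 covariance
  sv <- svd(A)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-12)
    stop("superposition error: rank-deficient (collinear) coordinates",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cref - R %*% cmob)
  fitted <- Q %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((P - fitted)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       transform = function(xyz) sweep(as.matrix(xyz) %*% t(R), 2, tr, `+`))
}

#' Plain coordinate RMSD (no fitting)
#' @param a,b Matching `n x 3` matrices.
#' @return RMSD in the coordinate units.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD series
#'
#' Superposes every frame on a reference over the alignment selection and
#' reports the RMSD over the analysis selection, the standard diagnostic
#' for conformational drift along a trajectory.
#'
#' @param traj A [trajectory()].
#' @param reference Frame index (default 1) or an `n x 3` matrix.
#' @param align Alignment selection (default `"calpha"`; see
#'   [rmsf()] for selection forms).
#' @param select Analysis selection (default: the alignment selection).
#' @return Numeric vector, one RMSD (angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1, align = "calpha",
                        select = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ai <- resolve_selection(traj$topology, align)
  si <- if (is.null(select)) ai else resolve_selection(traj$topology, select)
  if (!length(si)) stop("empty analysis selection", call. = FALSE)
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    fit <- superpose(ref[ai, , drop = FALSE], xyz[ai, , drop = FALSE])
    coord_rmsd(ref[si, , drop = FALSE], fit$transform(xyz[si, , drop = FALSE]))
  }, numeric(1))
}

trim_count <- function(n, trim) {
  k <- if (trim < 1) floor(trim * n) else as.integer(trim)
  if (k >= n) stop("empty analysis: equilibration trim >= trajectory length",
                   call. = FALSE)
  k
}

# align all frames of `arr` to `ref` over atom indices `ai`
align_frames <- function(arr, ref, ai) {
  for (f in seq_len(dim(arr)[3])) {
    fit <- superpose(ref[ai, , drop = FALSE], arr[ai, , f])
    arr[, , f] <- fit$transform(arr[, , f])
  }
  arr
}

#' Per-residue and per-atom root-mean-square fluctuations
#'
#' After discarding the equilibration segment, every frame is aligned to
#' the first retained frame over the alignment selection, the time-mean
#' structure is formed, and the frames are re-aligned to that mean (one
#' iteration). The per-atom RMSF is
#' `sqrt(mean_t |x(t) - mean_t x|^2)`; per-residue values are the C-alpha
#' values by default (or the mean over the residue's atoms).
#'
#' @param traj A [trajectory()].
#' @param align Alignment selection: `"calpha"` (default), `"all"`, monomer
#'   labels, or logical/integer atom indices. Align to one monomer's
#'   C-alphas by passing the intersection index, mirroring per-monomer
#'   analyses.
#' @param trim Equilibration trim: fraction of frames when `< 1` (default
#'   0.1, i.e. the first tenth discarded, the study's 5-of-50 ns
#'   convention), else an absolute frame count.
#' @param per_residue `"calpha"` (default) or `"heavy"` (mean over the
#'   residue's atoms).
#' @return An `"rmsf_profile"`: list with `per_atom` (angstrom),
#'   `per_residue` data.frame (`monomer`, `resno`, `rmsf`),
#'   `alignment_selection`, `n_frames_used`.
#' @export
rmsf <- function(traj, align = "calpha", trim = 0.1,
                 per_residue = c("calpha", "heavy")) {
  stopifnot(inherits(traj, "trajectory"))
  per_residue <- match.arg(per_residue)
  nf <- n_frames(traj)
  k <- trim_count(nf, trim)
  if (nf - k < 2)
    stop("fluctuation analysis needs >= 2 frames after trimming",
         call. = FALSE)
  ai <- resolve_selection(traj$topology, align)
  arr <- traj$coords[, , (k + 1):nf, drop = FALSE]
  arr <- align_frames(arr, arr[, , 1], ai)
  mean1 <- apply(arr, c(1, 2), mean)
  arr <- align_frames(arr, mean1, ai)
  xbar <- apply(arr, c(1, 2), mean)
  disp2 <- apply((arr - as.vector(xbar))^2, c(1, 3), sum)  # atoms x frames
  per_atom <- sqrt(rowMeans(disp2))

  atoms <- traj$topology$atoms
  key <- paste(atoms$monomer, atoms$resno, sep = ":")
  if (per_residue == "calpha") {
    ca <- which(atoms$elety == "CA")
    if (!length(ca)) stop("no C-alpha atoms for per-residue RMSF",
                          call. = FALSE)
    pr <- data.frame(monomer = atoms$monomer[ca], resno = atoms$resno[ca],
                     rmsf = per_atom[ca], stringsAsFactors = FALSE)
  } else {
    agg <- tapply(per_atom, key, mean)
    parts <- strsplit(names(agg), ":", fixed = TRUE)
    pr <- data.frame(monomer = vapply(parts, `[`, "", 1),
                     resno = as.integer(vapply(parts, `[`, "", 2)),
                     rmsf = as.numeric(agg), stringsAsFactors = FALSE)
  }
  pr <- pr[order(pr$monomer, pr$resno), ]
  rownames(pr) <- NULL
  structure(list(per_atom = per_atom, per_residue = pr,
                 alignment_selection = paste(deparse(align), collapse = ""),
                 n_frames_used = nf - k),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile over %d frames (alignment: %s)\n",
              x$n_frames_used, x$alignment_selection))
  cat(sprintf("  %d residues, per-residue RMSF %.3g to %.3g angstrom\n",
              nrow(x$per_residue), min(x$per_residue$rmsf),
              max(x$per_residue$rmsf)))
  invisible(x)
}

#' Define a binding-pocket loop
#'
#' @param name Loop label (e.g. `"L3,4"`).
#' @param first,last Inclusive residue-number range.
#' @param monomers Monomer scope: `"all"` or a vector of labels.
#' @return A `"loop_definition"` list.
#' @export
loop_definition <- function(name, first, last, monomers = "all") {
  if (first > last) stop("loop range reversed", call. = FALSE)
  structure(list(name = name, first = first, last = last,
                 monomers = monomers), class = "loop_definition")
}

#' The beta-barrel loops flanking the biotin pocket
#'
#' L3,4 spans residues 35-45 and L5,6 residues 70-75; these loops close
#' over bound biotin and their fluctuation drop is the conformational
#' signature the mobility channel of the biosensor reports.
#'
#' @return List of two [loop_definition()]s.
#' @export
default_loops <- function() {
  list(loop_definition("L3,4", 35, 45), loop_definition("L5,6", 70, 75))
}

#' Per-loop RMSF summaries
#'
#' @param profile An [rmsf()] result.
#' @param loops List of [loop_definition()]s (default [default_loops()]).
#' @return Named numeric vector: mean per-residue RMSF over each loop's
#'   residue range and monomer scope.
#' @export
loop_rmsf <- function(profile, loops = default_loops()) {
  stopifnot(inherits(profile, "rmsf_profile"))
  pr <- profile$per_residue
  out <- vapply(loops, function(lp) {
    sel <- pr$resno >= lp$first & pr$resno <= lp$last
    if (!identical(lp$monomers, "all")) sel <- sel & pr$monomer %in% lp$monomers
    if (!any(sel)) return(NA_real_)
    mean(pr$rmsf[sel])
  }, numeric(1))
  names(out) <- vapply(loops, `[[`, "", "name")
  out
}

#' Trajectory statistics of the per-monomer dipole moment
#'
#' Evaluates the partial-charge dipole of each monomer (ligand atoms
#' included via their monomer label) in every retained frame and pools the
#' magnitudes over monomers: time-mean, standard deviation and the full
#' per-frame series.
#'
#' @param traj A [trajectory()] whose topology carries charges.
#' @param monomers Monomer labels in scope (default: all).
#' @param trim Equilibration trim as in [rmsf()] (default 0.1).
#' @return List with `mean` (debye), `sd`, `series` (frames x monomers
#'   matrix of magnitudes), `monomers`, `n_frames_used`.
#' @export
trajectory_dipole_stats <- function(traj, monomers = NULL, trim = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  atoms <- traj$topology$atoms
  if (all(atoms$charge == 0))
    stop("configuration error: topology carries no partial charges; run ",
         "assign_residue_charges() or read_charge_file() first",
         call. = FALSE)
  if (is.null(monomers)) monomers <- unique(atoms$monomer)
  nf <- n_frames(traj)
  k <- trim_count(nf, trim)
  keep <- (k + 1):nf
  series <- matrix(NA_real_, length(keep), length(monomers),
                   dimnames = list(NULL, monomers))
  for (j in seq_along(monomers)) {
    idx <- which(atoms$monomer == monomers[j])
    if (!length(idx)) stop("no atoms in monomer '", monomers[j], "'",
                           call. = FALSE)
    for (fi in seq_along(keep)) {
      a <- atoms[idx, , drop = FALSE]
      a[, c("x", "y", "z")] <- traj$coords[idx, , keep[fi]]
      series[fi, j] <- dipole_moment(a, frame_index = keep[fi])$magnitude
    }
  }
  list(mean = mean(series), sd = stats::sd(as.vector(series)),
       series = series, monomers = monomers, n_frames_used = length(keep))
}
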