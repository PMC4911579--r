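# Independent quaternion (Horn) superposition RMSD: the maximal eigenvalue
# of the 4x4 profile matrix gives the optimal proper rotation without ever
# forming it, so it shares no code path with the SVD-based Kabsch fit.
quaternion_rmsd <- function(reference, mobile) {
  P <- sweep(as.matrix(reference), 2, colMeans(reference))
  Q <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  S <- t(Q) %*% P
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimal all-atom-ish structure with ionizable residues, one per residue
# type, each residue carrying a CA plus its side-chain reference atom
mini_protein <- function() {
  res <- c("ARG", "LYS", "HIS", "ASP", "GLU", "GLY", "XYZ")
  ref <- c(ARG = "CZ", LYS = "NZ", HIS = "ND1", ASP = "CG", GLU = "CD")
  rows <- list()
  for (i in seq_along(res)) {
    rows[[length(rows) + 1L]] <- data.frame(
      serial = 0L, elety = "CA", resid = res[i], resno = i, monomer = "A",
      x = i * 3.8, y = 0, z = 0, mass = 12.011, charge = 0, element = "C",
      stringsAsFactors = FALSE)
    if (res[i] %in% names(ref))
      rows[[length(rows) + 1L]] <- data.frame(
        serial = 0L, elety = ref[[res[i]]], resid = res[i], resno = i,
        monomer = "A", x = i * 3.8, y = 2.5, z = 0, mass = 14.007,
        charge = 0, element = "N", stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  charged_structure(atoms)
}
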