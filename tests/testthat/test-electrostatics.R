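test_that("rule-based charges reproduce the pH 7.5 picture", {
  s <- suppressWarnings(assign_residue_charges(mini_protein(), pH = 7.5))
  a <- s$atoms
  q_of <- function(res) sum(a$charge[a$resid == res])
  expect_equal(q_of("ARG"), 1)
  expect_equal(q_of("LYS"), 1)
  expect_equal(q_of("ASP"), -1)
  expect_equal(q_of("GLU"), -1)
  expect_equal(q_of("HIS"), 0)   # pKa 6.0 < pH 7.5
  expect_equal(q_of("GLY"), 0)
  expect_equal(s$provenance, "rule-based-at-pH")
  # the formal charge sits on the side-chain reference atom
  expect_equal(a$charge[a$resid == "ARG" & a$elety == "CZ"], 1)
  # histidine protonates below its pKa
  s5 <- suppressWarnings(assign_residue_charges(mini_protein(), pH = 5.0))
  expect_equal(sum(s5$atoms$charge[s5$atoms$resid == "HIS"]), 1)
  expect_warning(assign_residue_charges(mini_protein(), 7.5), "XYZ")
  expect_error(assign_residue_charges(mini_protein(), pH = 15), "pH")
})

test_that("dipole moment matches the e-angstrom conversion oracle", {
  two <- charged_structure(data.frame(
    serial = 1:2, elety = "CA", resid = "BEA", resno = 1:2, monomer = "A",
    x = 0, y = 0, z = c(0.5, -0.5), mass = 1, charge = c(1, -1),
    element = "C", stringsAsFactors = FALSE))
  d <- dipole_moment(two)
  expect_equal(d$magnitude, 4.80320, tolerance = 1e-12)
  expect_equal(d$vector, c(0, 0, 4.80320), tolerance = 1e-12)

  none <- two; none$atoms$charge <- 0
  expect_equal(dipole_moment(none)$magnitude, 0)
  expect_error(dipole_moment(two, group = "Z"), "selection")
})

test_that("dipole origin dependence follows the net charge", {
  set.seed(7)
  n <- 20
  a <- data.frame(serial = 1:n, elety = "CA", resid = "BEA", resno = 1:n,
                  monomer = "A", x = rnorm(n), y = rnorm(n), z = rnorm(n),
                  mass = runif(n, 1, 16), charge = 0, element = "C",
                  stringsAsFactors = FALSE)
  # neutral group: translation leaves the dipole unchanged
  a$charge <- c(rep(1, 10), rep(-1, 10))
  s <- charged_structure(a)
  shift <- c(3.2, -1.1, 7.5)
  s2 <- s; s2$atoms[, c("x", "y", "z")] <-
    sweep(coords(s), 2, shift, `+`)
  expect_equal(dipole_moment(s)$vector, dipole_moment(s2)$vector,
               tolerance = 1e-10)
  # charged group: the vector moves by -(total charge) x (COM shift of the
  # origin), i.e. changing the origin by delta changes p by -Q * delta
  a$charge <- c(rep(1, 11), rep(-1, 9))  # net +2
  sq <- charged_structure(a)
  com <- colSums(coords(sq) * sq$atoms$mass) / sum(sq$atoms$mass)
  p_com <- dipole_moment(sq)$vector
  # recompute about a shifted origin directly from the definition
  delta <- c(1, 0, 0)
  p_shifted <- colSums(sq$atoms$charge *
                         sweep(coords(sq), 2, com + delta)) * 4.80320
  expect_equal(unname(p_shifted), p_com - 2 * delta * 4.80320,
               tolerance = 1e-10)
})

test_that("dipole is additive over disjoint groups sharing one origin", {
  set.seed(8)
  mk <- function(mono, n) {
    xy <- matrix(rnorm(n * 3), ncol = 3)
    xy <- rbind(xy, -xy)  # symmetric: COM at the origin for any equal masses
    data.frame(serial = 0L, elety = "CA", resid = "BEA",
               resno = seq_len(2 * n), monomer = mono,
               x = xy[, 1], y = xy[, 2], z = xy[, 3], mass = 1,
               charge = rnorm(2 * n), element = "C",
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk("A", 8), mk("B", 8))
  atoms$serial <- seq_len(nrow(atoms))
  s <- charged_structure(atoms)
  expect_equal(dipole_moment(s)$vector,
               dipole_moment(s, "A")$vector + dipole_moment(s, "B")$vector,
               tolerance = 1e-10)
})

test_that("Helmholtz shift equals hand-evaluated SI arithmetic", {
  expected <- 283 * 3.33564e-30 / (8.8541878128e-12 * 3 * 1.50e-18)
  expect_equal(helmholtz_vt_shift(283, eps_r = 3, area_nm2 = 1.50),
               expected, tolerance = 1e-12)
  expect_equal(helmholtz_vt_shift(0), 0)
  expect_equal(helmholtz_vt_shift(283, area_nm2 = 3.0),
               helmholtz_vt_shift(283, area_nm2 = 1.5) / 2)
  expect_equal(helmholtz_vt_shift(283, eps_r = 6),
               helmholtz_vt_shift(283, eps_r = 3) / 2)
  expect_error(helmholtz_vt_shift(283, area_nm2 = 0), "positive")
})

test_that("Debye cutoff matches a root-bracketing oracle and its scaling laws", {
  kT <- thermal_energy(297)
  rc <- debye_cutoff(1, polarizability_A3 = 1, eps_r = 1, threshold = kT)
  # independent numeric root of |U(r)| = kT
  oracle <- uniroot(function(r) debye_energy(r, 1, 1, 1) - kT,
                    c(1e-4, 10), tol = 1e-14)$root
  expect_equal(rc, oracle, tolerance = 1e-8)

  # sixth-root scaling: mu^2, alpha, 1/threshold each enter to the 1/6
  expect_equal(debye_cutoff(4, 1, threshold = kT),
               rc * 4^(1 / 3), tolerance = 1e-12)
  expect_equal(debye_cutoff(1, 64, threshold = kT), rc * 2, tolerance = 1e-12)
  expect_equal(debye_cutoff(1, 1, threshold = 64 * kT), rc / 2,
               tolerance = 1e-12)
  # eps_r^2 in the denominator: eps_r = 8 halves the cutoff
  expect_equal(debye_cutoff(1, 1, eps_r = 8, threshold = kT), rc / 2,
               tolerance = 1e-12)
  # huge threshold drives the cutoff to zero
  expect_lt(debye_cutoff(1, 1, threshold = 1e13 * kT), 0.01 * rc)
  expect_error(debye_cutoff(1, 1, threshold = 0), "divergence")
  # force criterion is also available and positive
  expect_gt(debye_cutoff(1, 1, threshold = 1e-12, criterion = "force"), 0)
})
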