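test_that("12-6 potential has its closed-form minimum and asymptotics", {
  expect_lt(abs(lj_12_6(50, 1, 1)), 1e-6)
  expect_equal(lj_12_6(2^(1 / 6), 1, 1), -0.25)
  for (AB in list(c(2, 1), c(10, 3), c(0.5, 0.2))) {
    A <- AB[1]; B <- AB[2]
    r_min <- (2 * A / B)^(1 / 6)
    expect_equal(lj_12_6(r_min, A, B), -B^2 / (4 * A), tolerance = 1e-12)
    # one-sided check that it is a minimum
    expect_gt(lj_12_6(r_min * 0.99, A, B), -B^2 / (4 * A))
    expect_gt(lj_12_6(r_min * 1.01, A, B), -B^2 / (4 * A))
  }
  expect_error(lj_12_6(0, 1, 1), "positive")
})

test_that("12-10 hydrogen-bond well sits at sqrt(6C/5D) and respects E(t)", {
  expect_equal(hb_12_10(2.0, 1, 1, t = 90), 0)
  expect_equal(hb_12_10(1.5, 4, 6, t = 0), 2 * hb_12_10(1.5, 2, 3, t = 0))
  r_min <- sqrt(6 / 5)
  eps <- 1e-4
  expect_lt(hb_12_10(r_min, 1, 1), hb_12_10(r_min - eps, 1, 1))
  expect_lt(hb_12_10(r_min, 1, 1), hb_12_10(r_min + eps, 1, 1))
  expect_equal(directionality_weight(0), 1)
  expect_equal(directionality_weight(90), 0)
  expect_equal(directionality_weight(30), 0.75)
})

test_that("sigmoidal dielectric has correct limits and is monotone", {
  expect_equal(sigmoidal_dielectric(0), 1.3466, tolerance = 1e-3)
  expect_equal(sigmoidal_dielectric(100), 78.4, tolerance = 1.0)
  r <- seq(0, 50, by = 0.25)
  expect_true(all(diff(sigmoidal_dielectric(r)) >= 0))
})

test_that("Coulomb term matches hand evaluation and sign conventions", {
  expect_equal(coulomb_energy(0, 0.4, 3), 0)
  expect_gt(coulomb_energy(0.3, 0.3, 3), 0)
  expect_lt(coulomb_energy(0.3, -0.3, 3), 0)
  expected <- 332.0 * 0.25 / (sigmoidal_dielectric(3) * 3)
  expect_equal(coulomb_energy(0.5, 0.5, 3), expected, tolerance = 1e-12)
})

test_that("torsional penalty is linear in the rotatable-bond count", {
  expect_equal(torsion_penalty(0), 0)
  expect_equal(torsion_penalty(10, 0.3113), 2 * torsion_penalty(5, 0.3113))
  expect_equal(torsion_penalty(3, 0.3113), 0.9339)
})

test_that("occupancy follows the Gaussian envelope", {
  sigma <- default_energy_params()$sigma
  hyd <- default_hydration_params()
  two <- ligand_mol(
    data.frame(serial = 1:2, element = c("C", "C"),
               x = c(0, sigma), y = 0, z = 0),
    data.frame(i = 1L, j = 2L, order = 1L), retype = FALSE)
  two$atoms$atom_type <- c("C", "C")
  vC <- hyd$V[hyd$type == "C"]
  expect_equal(ligand_occupancy(1, two), vC * exp(-0.5), tolerance = 1e-12)
  two$atoms$x <- c(0, 0)
  expect_equal(ligand_occupancy(1, two), vC, tolerance = 1e-12)
  one <- point_ligand("C")
  expect_equal(dehydration_term(one),
               hyd$S[hyd$type == "C"] * hyd$O_max[hyd$type == "C"])
})

test_that("dehydration equals the brute-force double loop and ignores the receptor", {
  for (seed in 1:10) {
    sys <- make_random_system(seed)
    expect_equal(dehydration_term(sys$mol), naive_dehydration(sys$mol),
                 tolerance = 1e-10)
  }
  # zero hydration energy densities kill the term
  hyd0 <- default_hydration_params()
  hyd0$S <- 0
  sys <- make_random_system(3)
  expect_identical(dehydration_term(sys$mol, hyd0), 0)
  # receptor coordinates never enter: same breakdown term bit for bit
  sb1 <- binding_free_energy(sys$receptor, sys$mol)
  moved <- sys$receptor
  moved$atoms$x <- moved$atoms$x + 5
  sb2 <- binding_free_energy(moved, sys$mol)
  expect_identical(sb1$e_dehydration, sb2$e_dehydration)
})

test_that("vectorized scoring equals the naive double-loop oracle", {
  for (seed in 1:50) {
    sys <- make_random_system(seed)
    sb <- binding_free_energy(sys$receptor, sys$mol)
    expect_equal(sb$total, naive_score(sys$receptor, sys$mol),
                 tolerance = 1e-8)
  }
})

test_that("breakdown terms sum to the total and scale with their weights", {
  sys <- make_random_system(11)
  sb <- binding_free_energy(sys$receptor, sys$mol)
  expect_equal(sb$total,
               sb$e_vdw + sb$e_hbond + sb$e_elec + sb$e_tor +
                 sb$e_dehydration, tolerance = 1e-12)
  p2 <- default_energy_params()
  p2$w_vdw <- 3 * p2$w_vdw
  sb2 <- binding_free_energy(sys$receptor, sys$mol, params = p2)
  expect_equal(sb2$e_vdw, 3 * sb$e_vdw, tolerance = 1e-12)
  # all weights and hydration energies zero -> exactly zero
  p0 <- default_energy_params()
  p0$w_vdw <- p0$w_hbond <- p0$w_elec <- p0$w_tor <- 0
  hyd0 <- default_hydration_params(); hyd0$S <- 0
  sb0 <- binding_free_energy(sys$receptor, sys$mol, params = p0,
                             hydration = hyd0)
  expect_identical(sb0$total, 0)
})

test_that("scores are invariant under a shared rigid motion", {
  rot <- selectiscreen:::quat_to_matrix(
    selectiscreen:::axis_angle_quat(c(1, 2, 3), 37))
  shift <- c(2.5, -1.0, 4.0)
  for (seed in c(4, 17, 23)) {
    sys <- make_random_system(seed)
    sb <- binding_free_energy(sys$receptor, sys$mol)
    r2 <- sys$receptor
    rx <- as.matrix(r2$atoms[, c("x", "y", "z")]) %*% t(rot)
    r2$atoms$x <- rx[, 1] + shift[1]
    r2$atoms$y <- rx[, 2] + shift[2]
    r2$atoms$z <- rx[, 3] + shift[3]
    m2 <- sys$mol
    lx <- coords(sys$mol) %*% t(rot)
    m2 <- selectiscreen:::set_coords(m2, sweep(lx, 2, shift, "+"))
    sb2 <- binding_free_energy(r2, m2)
    for (term in c("e_vdw", "e_hbond", "e_elec", "e_tor", "e_dehydration",
                   "total"))
      expect_equal(sb2[[term]], sb[[term]], tolerance = 1e-8)
  }
})

test_that("parameter tables round-trip through their TSV contracts", {
  pt <- default_pair_potentials()
  tmp <- tempfile(fileext = ".tsv")
  write_pair_potentials(pt, tmp)
  back <- read_pair_potentials(tmp)
  ty <- pt$types
  expect_equal(back$A[ty, ty], pt$A, tolerance = 1e-9)
  expect_equal(back$D[ty, ty], pt$D, tolerance = 1e-9)
  expect_identical(back$is_hbond[ty, ty], pt$is_hbond)
  hyd <- default_hydration_params()
  write_hydration_params(hyd, tmp)
  expect_equal(read_hydration_params(tmp), hyd, tolerance = 1e-12)
  unlink(tmp)
})

test_that("energy config overrides merge onto defaults", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("w_vdw: 0.2", "sigma: 2.5", "dielectric:", "  k: 8.0"), tmp)
  p <- read_energy_config(tmp)
  expect_equal(p$w_vdw, 0.2)
  expect_equal(p$sigma, 2.5)
  expect_equal(unname(p$dielectric[["k"]]), 8.0)
  expect_equal(p$w_tor, 0.3113)  # untouched default
  unlink(tmp)
})
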