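test_that("molecular-weight window bounds are inclusive", {
  mk <- function(mw) list(id = as.character(mw), mw = mw, violations = 0)
  entries <- lapply(c(299.9, 300, 350, 400, 400.1), mk)
  kept <- mw_window_filter(entries)
  expect_equal(vapply(kept, `[[`, "", "id"), c("300", "350", "400"))
})

test_that("rule-of-five filter keeps at most one violation and is idempotent", {
  mk <- function(v) list(id = as.character(v), mw = 350, violations = v)
  entries <- lapply(c(0, 1, 2, 3), mk)
  kept <- ro5_filter(entries)
  expect_equal(vapply(kept, `[[`, "", "id"), c("0", "1"))
  expect_identical(ro5_filter(kept), kept)
})

test_that("leader clustering follows input order and strict cutoff", {
  # engineered bit sets: T(A,B) = T(B,C) = 47/53 > 0.8, T(A,C) = 44/56 < 0.8
  mkfp <- function(idx) { v <- logical(80); v[idx] <- TRUE; v }
  A <- list(id = "A", fingerprint = mkfp(1:50))
  B <- list(id = "B", fingerprint = mkfp(4:53))
  C <- list(id = "C", fingerprint = mkfp(7:56))
  expect_equal(tanimoto(A$fingerprint, B$fingerprint), 47 / 53)
  expect_equal(tanimoto(A$fingerprint, C$fingerprint), 44 / 56)
  reps <- cluster_by_tanimoto(list(A, B, C), cutoff = 0.8)
  expect_equal(vapply(reps, `[[`, "", "id"), c("A", "C"))
  expect_equal(vapply(reps, `[[`, integer(1), "cluster_size"), c(2L, 1L))
  # exact duplicates always collapse; all-dissimilar sets are kept whole
  reps2 <- cluster_by_tanimoto(list(A, A, A), cutoff = 0.8)
  expect_length(reps2, 1)
  D <- list(id = "D", fingerprint = mkfp(60:80))
  expect_length(cluster_by_tanimoto(list(A, D), cutoff = 0.8), 2)
})

test_that("fingerprints are identical for identical structures", {
  mols <- smi_mols(c("c1ccccc1CCO a", "c1ccccc1CCO b", "CC(C)(C)O c"))
  expect_identical(path_fingerprint(mols[[1]]), path_fingerprint(mols[[2]]))
  expect_equal(tanimoto(path_fingerprint(mols[[1]]),
                        path_fingerprint(mols[[2]])), 1)
  expect_lt(tanimoto(path_fingerprint(mols[[1]]),
                     path_fingerprint(mols[[3]])), 0.8)
})

test_that("pass rules implement the strict two-track inequalities", {
  grid <- expand.grid(dg_mut = c(-10.5, -10.0, -9.9),
                      dg_wt = c(-6.1, -6.0, -5.9),
                      hinge_hbonds = c(0L, 1L, 2L))
  out <- apply_screen_rules(grid)
  expect_equal(out$pass_energy, grid$dg_mut < -10 & grid$dg_wt > -6)
  expect_equal(out$pass_hinge, grid$hinge_hbonds >= 2)
  expect_equal(out$pass, out$pass_energy & out$pass_hinge)
  # the canonical cases
  one <- apply_screen_rules(data.frame(dg_mut = -10.5, dg_wt = -5.5,
                                       hinge_hbonds = 2L))
  expect_true(one$pass)
  expect_false(apply_screen_rules(data.frame(dg_mut = -9.9, dg_wt = -5.5,
                                             hinge_hbonds = 2L))$pass)
  expect_false(apply_screen_rules(data.frame(dg_mut = -12.0, dg_wt = -6.0,
                                             hinge_hbonds = 2L))$pass)
  # every passing record has a gap forced above 4 kcal/mol
  passing <- out[out$pass, ]
  if (nrow(passing))
    expect_true(all(passing$dg_wt - passing$dg_mut > 4.0))
})

test_that("hinge hydrogen-bond detection is strict and role-aware", {
  rp <- make_receptor_pair(fixture_spec())
  pb <- make_planted_binder(rp$mut, fixture_spec())
  hb <- detect_hinge_hbonds(rp$mut, pb$mol)
  expect_equal(hb$count, 2)
  expect_setequal(hb$contacts$resno, c(791L, 793L))
  expect_true(all(hb$contacts$distance < 3.5))
  # apolar decoy cannot hydrogen bond
  expect_equal(detect_hinge_hbonds(rp$mut, make_apolar_decoy())$count, 0)
  # a contact at exactly the threshold does not count (strict <)
  ra <- rp$mut$atoms
  n793 <- which(ra$resno == 793 & ra$atom_name == "N")
  probe <- point_ligand("NA", pos = c(ra$x[n793], ra$y[n793] - 3.5,
                                      ra$z[n793]))
  expect_equal(detect_hinge_hbonds(rp$mut, probe)$count, 0)
  probe2 <- point_ligand("NA", pos = c(ra$x[n793], ra$y[n793] - 3.499,
                                       ra$z[n793]))
  expect_equal(detect_hinge_hbonds(rp$mut, probe2)$count, 1)
  # missing hinge residues are a named error
  bare <- toy_receptor(c(0, 0, 0))
  expect_error(detect_hinge_hbonds(bare, pb$mol), "791")
})

test_that("threshold constructor rejects inconsistent bounds", {
  expect_error(screen_thresholds(dg_mut_max = -5, dg_wt_min = -6))
  expect_error(screen_thresholds(hbond_distance_max = 0))
})
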