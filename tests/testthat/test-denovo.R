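pick_aromatic_ch <- function(mol, n = 2) {
  el <- mol$atoms$element
  adj <- selectiscreen:::adjacency(mol)
  cand <- which(mol$atoms$atom_type == "A" &
                  vapply(adj, function(nb) any(el[nb] == "H"), logical(1)))
  cand[seq_len(n)]
}

test_that("enumeration produces (f+1)^s - 1 derivatives before dedup", {
  core <- smi_mols("O=C1c2ccccc2OC1=Cc1ccc(O)cc1 core")[[1]]
  sites <- pick_aromatic_ch(core, 2)
  res <- enumerate_derivatives(core, sites, c(methyl = "C", fluoro = "F",
                                              methoxy = "OC"))
  expect_equal(res$n_enumerated, (3 + 1)^2 - 1)
  expect_length(res$derivatives, 15)  # all distinct at distinct sites
  # single site, single fragment: exactly one derivative
  res1 <- enumerate_derivatives(core, sites[1], c(methyl = "C"))
  expect_equal(res1$n_enumerated, 1L)
  expect_length(res1$derivatives, 1)
  # grafting preserves composition: parent + CH2 for a methyl
  parent_f <- core$formula
  deriv_f <- res1$derivatives[[1]]$formula
  expect_equal(deriv_f[["C"]], parent_f[["C"]] + 1L)
  expect_equal(deriv_f[["H"]], parent_f[["H"]] + 2L)
})

test_that("identical products collapse under canonical de-duplication", {
  core <- smi_mols("c1ccccc1 benzene")[[1]]
  sites <- pick_aromatic_ch(core, 2)
  # benzene with one methyl at either position is the same toluene
  res <- enumerate_derivatives(core, sites, c(methyl = "C"))
  expect_equal(res$n_enumerated, 3L)      # (1+1)^2 - 1
  smis <- canonical_smiles(res$derivatives)
  expect_equal(length(res$derivatives), length(unique(smis)))
  expect_lt(length(res$derivatives), 3L)  # the two mono-methyls merged
})

test_that("empty fragment libraries exit cleanly", {
  core <- smi_mols("c1ccccc1 benzene")[[1]]
  res <- enumerate_derivatives(core, pick_aromatic_ch(core, 1),
                               character(0))
  expect_length(res$derivatives, 0)
  expect_equal(res$n_enumerated, 0L)
})

test_that("the selectivity-gap rule uses strict inequalities and sign", {
  df <- data.frame(id = c("exact", "above", "wrongway", "good"),
                   dg_mut = c(-12.0, -12.1, -6.0, -13.0),
                   dg_wt = c(-7.0, -7.0, -12.5, -6.5))
  out <- apply_gap_rule(df, denovo_config(selectivity_gap_min = 5.0))
  sel <- out$id[out$selected]
  expect_setequal(sel, c("above", "good"))      # gap 5.0 exactly excluded
  expect_false("wrongway" %in% sel)             # dg_mut > dg_wt excluded
  expect_equal(out$id[1], "good")               # ranked by dg_mut ascending
  # idempotent and order preserving on reapplication
  expect_identical(apply_gap_rule(out, denovo_config()), out)
})

test_that("prefilter keeps only strictly-better, rule-of-five-clean derivatives", {
  rp <- make_receptor_pair(fixture_spec())
  core <- smi_mols("Oc1ccccc1 phenol")[[1]]
  sites <- pick_aromatic_ch(core, 1)
  res <- enumerate_derivatives(core, sites, c(methyl = "C", amino = "N"))
  box <- grid_box(c(0.5, -8, -3), 0.75, c(15, 12, 10))
  maps <- build_grid_maps(rp$mut, box)
  pf <- empirical_prefilter(res$derivatives, core, rp$mut, maps,
                            config = search_config(seed = 8, n_starts = 3,
                                                   n_steps = 80,
                                                   n_greedy = 20))
  expect_equal(nrow(pf$table), length(res$derivatives))
  expect_true(all(pf$table$gas_score[pf$table$kept] < pf$parent_gas))
  expect_true(all(pf$table$ro5_violations[pf$table$kept] <= 1))
  expect_length(pf$kept, sum(pf$table$kept))
})
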