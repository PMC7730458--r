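test_that("SMILES reading yields explicit-H 3D molecules, reproducibly", {
  mols <- smi_mols(c("c1ccccc1 benzene", "CCO ethanol"))
  expect_length(mols, 2)
  benzene <- mols[[1]]
  expect_equal(nrow(benzene$atoms), 12)  # 6 C + 6 explicit H
  expect_equal(sum(benzene$atoms$element == "H"), 6)
  expect_false(all(abs(coords(benzene)[, 3]) < 1e-8))  # truly 3D
  # same input and seed give identical coordinates
  mols2 <- smi_mols(c("c1ccccc1 benzene", "CCO ethanol"))
  expect_identical(coords(mols[[2]]), coords(mols2[[2]]))
})

test_that("empty and partially invalid inputs are handled gracefully", {
  tmp <- tempfile(fileext = ".smi")
  writeLines(character(0), tmp)
  expect_length(read_ligands(tmp), 0)
  writeLines(c("CCO ok", "not_a_smiles((( bad", "c1ccccc1 ok2"), tmp)
  expect_warning(mols <- read_ligands(tmp), "skipped")
  expect_length(mols, 2)
  unlink(tmp)
})

test_that("SDF round-trip preserves atoms, bonds and rotatable count", {
  mols <- smi_mols(c("CCCC butane", "c1ccccc1-c1ccccc1 biphenyl",
                     "O=C(O)c1ccccc1 benzoic"))
  tmp <- tempfile(fileext = ".sdf")
  write_ligands(mols, tmp)
  back <- suppressWarnings(read_ligands(tmp))
  expect_length(back, length(mols))
  for (k in seq_along(mols)) {
    expect_equal(nrow(back[[k]]$atoms), nrow(mols[[k]]$atoms))
    expect_equal(nrow(back[[k]]$bonds), nrow(mols[[k]]$bonds))
    expect_equal(back[[k]]$n_tor, mols[[k]]$n_tor)
  }
  unlink(tmp)
})

test_that("rotatable-bond counting follows the stated definition", {
  mols <- smi_mols(c("CC ethane", "CCCC butane",
                     "c1ccccc1-c1ccccc1 biphenyl", "CC(=O)NC acetamide"))
  n <- vapply(mols, `[[`, integer(1), "n_tor")
  # ethane: both carbons terminal-heavy; butane: one central C-C;
  # biphenyl: the aryl-aryl bond; N-methylacetamide: amide C-N excluded
  expect_equal(n, c(0L, 1L, 1L, 0L))
})

test_that("Gasteiger charges conserve charge and match the published iteration", {
  mols <- smi_mols(c("O water", "C methane", "CCO ethanol"))
  for (m in mols)
    expect_lt(abs(sum(m$atoms$charge)), 1e-6)
  water <- mols[[1]]
  ref <- peoe_reference_water()
  expect_equal(water$atoms$charge[water$atoms$element == "O"],
               unname(ref["O"]), tolerance = 1e-9)
  # independent Open Babel implementation agrees to 1e-3 e (frozen values)
  expect_lt(abs(water$atoms$charge[water$atoms$element == "O"] - (-0.4105)),
            1e-3)
  methane <- mols[[2]]
  hq <- methane$atoms$charge[methane$atoms$element == "H"]
  expect_equal(max(hq) - min(hq), 0, tolerance = 1e-12)  # symmetry
})

test_that("rule-of-five profiles count donors/acceptors as N/O rules", {
  mols <- smi_mols(c("c1ccccc1 benzene", "OCC1OC(O)C(O)C(O)C1O glucose"))
  b <- ro5_profile(mols[[1]])
  expect_equal(c(b$hbd, b$hba, b$violations), c(0, 0, 0))
  g <- ro5_profile(mols[[2]])
  expect_equal(c(g$hbd, g$hba, g$violations), c(5, 6, 0))
})

test_that("PDB receptors preserve residue numbering and report bad records", {
  rp <- make_receptor_pair(fixture_spec())
  tmp <- tempfile(fileext = ".pdb")
  write_receptor_pdb(rp$mut, tmp)
  rec <- read_receptor(tmp, charge_scheme = "bfactor")
  expect_equal(length(rec$residue_index), length(rp$mut$residue_index))
  expect_equal(rec$hinge_residues, 791:795)
  expect_equal(sort(unique(rec$atoms$resno)),
               sort(unique(rp$mut$atoms$resno)))
  expect_equal(rec$atoms$charge, rp$mut$atoms$charge, tolerance = 0.005)
  # truncated ATOM record names its line
  lines <- readLines(tmp)
  lines[3] <- substr(lines[3], 1, 40)
  writeLines(lines, tmp)
  expect_error(read_receptor(tmp), "line 3")
  unlink(tmp)
})
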