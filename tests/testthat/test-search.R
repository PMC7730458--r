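shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rp <- make_receptor_pair(fixture_spec())
      pb <- make_planted_binder(rp$mut, fixture_spec())
      box <- grid_box(c(0.5, -8, -3), 0.375, c(29, 24, 20))
      maps <- build_grid_maps(rp$mut, box,
                              probe_types = unique(pb$mol$atoms$atom_type))
      cache <<- list(rp = rp, pb = pb, maps = maps)
    }
    cache
  }
})

test_that("pose genomes normalize and apply as torsions-then-rigid", {
  p <- pose_genome(quaternion = c(2, 0, 0, 0))
  expect_equal(sum(p$quaternion^2), 1)
  expect_equal(pose_genome(torsions = 365)$torsions, 5)
  fx <- shared_fixture()
  mol <- fx$pb$mol
  # identity pose leaves coordinates unchanged
  id <- pose_genome(torsions = rep(0, mol$n_tor))
  expect_equal(coords(apply_pose(mol, id)), coords(mol), tolerance = 1e-12)
  # translation moves the centroid by exactly the translation vector
  tr <- pose_genome(translation = c(1, -2, 3), torsions = rep(0, mol$n_tor))
  expect_equal(unname(colMeans(coords(apply_pose(mol, tr))) -
                        colMeans(coords(mol))),
               c(1, -2, 3), tolerance = 1e-12)
  # torsions never change bond lengths
  tw <- pose_genome(torsions = c(67, -110))
  posed <- apply_pose(mol, tw)
  d0 <- sqrt(rowSums((coords(mol)[mol$bonds$i, ] -
                        coords(mol)[mol$bonds$j, ])^2))
  d1 <- sqrt(rowSums((coords(posed)[posed$bonds$i, ] -
                        coords(posed)[posed$bonds$j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("search is deterministic and respects the identity contract", {
  fx <- shared_fixture()
  cfg <- search_config(seed = 5, n_starts = 3, n_steps = 60, n_greedy = 15)
  r1 <- optimize_pose(fx$pb$mol, fx$maps, cfg)
  r2 <- optimize_pose(fx$pb$mol, fx$maps, cfg)
  expect_identical(r1$pose, r2$pose)
  expect_identical(r1$energy, r2$energy)
  # n_steps = 0 with a start pose returns that pose, scored
  id <- pose_genome(torsions = rep(0, fx$pb$mol$n_tor))
  r0 <- optimize_pose(fx$pb$mol, fx$maps,
                      search_config(seed = 1, n_starts = 1, n_steps = 0),
                      start_pose = id)
  expect_identical(r0$pose, id)
})

test_that("the reported best never exceeds any start's score", {
  fx <- shared_fixture()
  cfg <- search_config(seed = 9, n_starts = 6, n_steps = 50, n_greedy = 10)
  r <- optimize_pose(fx$pb$mol, fx$maps, cfg)
  starts <- vapply(r$starts, `[[`, numeric(1), "energy")
  expect_true(all(r$energy <= starts + 1e-12))
})

test_that("a single-atom probe converges into an engineered well", {
  # quadratic-well map with minimum at a known node
  box <- grid_box(c(0, 0, 0), 0.5, c(17, 17, 17))
  nodes <- selectiscreen:::grid_nodes(box)
  ctr <- c(4, 4, 4)
  well <- array(0.5 * rowSums(sweep(nodes, 2, ctr)^2) - 5, dim = box$npts)
  maps <- structure(list(box = box, vdw = list(C = well), hbond = list(),
                         elec = array(0, box$npts), probe_types = "C",
                         provenance = "well"), class = "grid_maps")
  probe <- point_ligand("C", pos = c(1, 1, 1))
  hyd0 <- default_hydration_params(); hyd0$S <- 0
  res <- optimize_pose(probe, maps,
                       search_config(seed = 3, n_starts = 4, n_steps = 150))
  posed <- apply_pose(probe, res$pose)
  expect_lt(sqrt(sum((coords(posed) - ctr)^2)), box$spacing)
})

test_that("direct rescoring is repeatable and finite for clashes", {
  fx <- shared_fixture()
  id <- pose_genome(torsions = rep(0, fx$pb$mol$n_tor))
  s1 <- rescore_direct(fx$rp$mut, fx$pb$mol, id)
  s2 <- rescore_direct(fx$rp$mut, fx$pb$mol, id)
  expect_identical(s1, s2)
  # grid and direct agree reasonably away from box walls
  g <- optimize_pose(fx$pb$mol, fx$maps,
                     search_config(seed = 1, n_starts = 1, n_steps = 0),
                     start_pose = id)
  expect_lt(abs(g$energy - s1$total), 0.7)
  # a pose rammed into the receptor stays finite and large
  clash <- pose_genome(translation = c(0, -2.2, 0),
                       torsions = rep(0, fx$pb$mol$n_tor))
  sc <- rescore_direct(fx$rp$mut, fx$pb$mol, clash)
  expect_true(is.finite(sc$total))
  expect_gt(sc$total, 10)
})

test_that("peripheral-site scan finds engineered pockets and nothing else", {
  # repulsive-only system: a polar probe with like-charged receptor atoms
  # pays its full dehydration penalty everywhere, so no site scores < 0
  rep_rec <- toy_receptor(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                          charges = 0.5)
  probe <- point_ligand("OA", charge = 0.5)
  box <- whole_domain_box(rep_rec, margin = 3, spacing = 1)
  maps <- build_grid_maps(rep_rec, box, probe_types = "OA")
  hits <- peripheral_site_scan(rep_rec, probe, maps,
                               config = search_config(seed = 2, n_starts = 1,
                                                      n_steps = 40,
                                                      n_greedy = 10),
                               lattice_spacing = 5)
  expect_equal(nrow(hits), 0)
  # an engineered attractive cavity is detected by a probe atom: the
  # fixture pocket is the deepest site for an apolar probe, which can
  # enter it from any lattice start
  fx <- shared_fixture()
  wbox <- whole_domain_box(fx$rp$mut, margin = 3, spacing = 1)
  wmaps <- build_grid_maps(fx$rp$mut, wbox, probe_types = "C")
  probe2 <- point_ligand("C")
  scan_cfg <- search_config(seed = 4, n_starts = 2, n_steps = 300,
                            n_greedy = 60)
  sites <- peripheral_site_scan(fx$rp$mut, probe2, wmaps,
                                config = scan_cfg, lattice_spacing = 5)
  expect_gt(nrow(sites), 0)
  best <- as.numeric(sites[1, c("x", "y", "z")])
  expect_lt(sqrt(sum((best - fx$rp$mut$pocket_center)^2)), 4)
  sites2 <- peripheral_site_scan(fx$rp$mut, probe2, wmaps,
                                 config = scan_cfg, lattice_spacing = 5)
  expect_identical(sites, sites2)
})
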