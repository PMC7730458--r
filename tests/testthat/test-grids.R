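test_that("whole-domain box contains every receptor atom", {
  rp <- make_receptor_pair(fixture_spec())
  box <- whole_domain_box(rp$mut, margin = 5, spacing = 1)
  xyz <- as.matrix(rp$mut$atoms[, c("x", "y", "z")])
  hi <- box$origin + (box$npts - 1) * box$spacing
  expect_true(all(t(xyz) >= box$origin - 1e-9))
  expect_true(all(t(xyz) <= hi + 1e-9))
  # single atom, margin 5, spacing 1: 11 nodes per axis
  one <- toy_receptor(c(0, 0, 0))
  b1 <- whole_domain_box(one, margin = 5, spacing = 1)
  expect_equal(b1$npts, c(11L, 11L, 11L))
})

test_that("zero-charge receptors give identically zero electrostatic maps", {
  rec <- toy_receptor(rbind(c(0, 0, 0), c(2, 1, 0)), charges = 0)
  maps <- build_grid_maps(rec, grid_box(c(-2, -2, -2), 1, c(5, 5, 5)),
                          probe_types = "C")
  expect_true(all(maps$elec == 0))
})

test_that("map nodes reproduce direct scoring exactly for an apolar probe", {
  # single receptor atom: map value at a node is the weighted 12-6 energy
  params <- default_energy_params()
  pt <- default_pair_potentials()
  rec <- toy_receptor(c(0.1, 0.2, 0.3))
  box <- grid_box(c(2, 2, 2), 0.5, c(8, 8, 8))
  maps <- build_grid_maps(rec, box, params, pt, probe_types = "C")
  nodes <- selectiscreen:::grid_nodes(box)
  d <- sqrt(rowSums(sweep(nodes, 2, c(0.1, 0.2, 0.3))^2))
  expected <- params$w_vdw * lj_12_6(d, pt$A["C", "C"], pt$B["C", "C"])
  expected[d > params$nb_cutoff] <- 0
  expect_equal(as.numeric(maps$vdw[["C"]]), expected, tolerance = 1e-10)
  # interpolation at a node returns the stored value
  node <- nodes[137, ]
  expect_identical(interpolate(maps, node, "C"),
                   as.numeric(maps$vdw[["C"]])[137])
})

test_that("trilinear interpolation reproduces a linear field exactly", {
  box <- grid_box(c(0, 0, 0), 0.5, c(9, 9, 9))
  nodes <- selectiscreen:::grid_nodes(box)
  lin <- array(2 * nodes[, 1] - 3 * nodes[, 2] + 0.5 * nodes[, 3] + 1,
               dim = box$npts)
  maps <- structure(list(box = box, vdw = list(C = lin), hbond = list(),
                         elec = array(0, box$npts), probe_types = "C",
                         provenance = "test"), class = "grid_maps")
  set.seed(1)
  pts <- matrix(runif(60, 0.1, 3.9), ncol = 3)
  expect_equal(interpolate(maps, pts, "C"),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 1,
               tolerance = 1e-10)
  # outside the box: the documented penalty
  expect_equal(interpolate(maps, c(50, 0, 0), "C"),
               default_energy_params()$oob_penalty)
})

test_that("grid error is small at fine spacing and shrinks on refinement", {
  # fidelity on a smooth fixture: a small apolar receptor, test points
  # kept outside the steep repulsive wall
  rec <- toy_receptor(rbind(c(0, 0, 0), c(2.5, 1.2, -0.8), c(-1.5, 2.0, 1.0)))
  probe <- point_ligand("C")
  scorer <- make_direct_scorer(rec, probe)
  set.seed(7)
  pts <- matrix(runif(3 * 900, -4.5, 4.5), ncol = 3)
  rxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  mind <- apply(pts, 1, function(p) min(sqrt(colSums((t(rxyz) - p)^2))))
  pts <- pts[mind >= 3.5, , drop = FALSE]
  expect_gt(nrow(pts), 50)
  err_at <- function(spacing) {
    box <- grid_box(c(-5, -5, -5), spacing,
                    rep(ceiling(10 / spacing) + 1, 3))
    maps <- build_grid_maps(rec, box, probe_types = "C")
    direct <- apply(pts, 1, function(p) scorer(matrix(p, 1, 3))$e_vdw)
    max(abs(interpolate(maps, pts, "C") - direct))
  }
  e_fine <- err_at(0.375)
  expect_lt(e_fine, 0.05)
  e_mid <- err_at(0.75)
  e_coarse <- err_at(1.5)
  expect_lt(e_fine, e_mid)
  expect_lt(e_mid, e_coarse)
})

test_that("maps depend only on receptor, box and parameters", {
  rec <- toy_receptor(rbind(c(0, 0, 0), c(1, 2, 0)), charges = c(0.2, -0.2))
  box <- grid_box(c(-2, -2, -2), 1, c(5, 5, 5))
  m1 <- build_grid_maps(rec, box, probe_types = c("C", "OA"))
  m2 <- build_grid_maps(rec, box, probe_types = c("C", "OA"))
  expect_identical(m1$vdw, m2$vdw)
  expect_identical(m1$elec, m2$elec)
  expect_identical(m1$provenance, m2$provenance)
})

test_that("map files round-trip through the plain-text dialect", {
  rec <- toy_receptor(rbind(c(0, 0, 0), c(1, 2, 0)), charges = c(0.2, -0.2))
  box <- grid_box(c(-2, -2, -2), 0.5, c(6, 7, 8))
  maps <- build_grid_maps(rec, box, probe_types = c("C", "OA", "HD"))
  dir <- tempfile()
  write_grid_maps(maps, dir, stem = "toy")
  back <- read_grid_maps(dir, stem = "toy")
  expect_equal(back$box$origin, maps$box$origin, tolerance = 1e-6)
  expect_equal(back$box$npts, maps$box$npts)
  for (ty in names(maps$vdw))
    expect_equal(back$vdw[[ty]], maps$vdw[[ty]], tolerance = 1e-9)
  expect_equal(back$elec, maps$elec, tolerance = 1e-9)
  expect_equal(sort(names(back$hbond)), sort(names(maps$hbond)))
  unlink(dir, recursive = TRUE)
})

test_that("a box far from the receptor warns but still builds", {
  rec <- toy_receptor(c(0, 0, 0))
  box <- grid_box(c(100, 100, 100), 1, c(3, 3, 3))
  expect_warning(maps <- build_grid_maps(rec, box, probe_types = "C"),
                 "cutoff")
  expect_true(all(maps$vdw[["C"]] == 0))
})
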