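# Independent reference implementations used as oracles: plain scalar
# loops, written directly from the model definitions, sharing no code
# with the package's vectorized paths.

naive_dehydration <- function(mol, hydration = default_hydration_params(),
                              sigma = default_energy_params()$sigma) {
  at <- mol$atoms
  total <- 0
  for (i in seq_len(nrow(at))) {
    hi <- hydration[hydration$type == at$atom_type[i], ]
    occ <- 0
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      hj <- hydration[hydration$type == at$atom_type[j], ]
      r2 <- (at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
        (at$z[i] - at$z[j])^2
      occ <- occ + hj$V * exp(-r2 / (2 * sigma^2))
    }
    total <- total + hi$S * max(0, hi$O_max - occ)
  }
  total
}

# full scoring function as an explicit scalar double loop
naive_score <- function(receptor, mol,
                        params = default_energy_params(),
                        pt = default_pair_potentials(),
                        hydration = default_hydration_params()) {
  ra <- receptor$atoms
  la <- mol$atoms
  dc <- params$dielectric
  e_vdw <- e_hb <- e_el <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      r <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (r > params$nb_cutoff) next
      rc <- max(r, params$r_clamp)
      ti <- ra$atom_type[i]; tj <- la$atom_type[j]
      eps_r <- dc[["A"]] + dc[["B"]] /
        (1 + dc[["k"]] * exp(-dc[["lambda"]] * dc[["B"]] * rc))
      e_el <- e_el + params$coulomb_constant * ra$charge[i] * la$charge[j] /
        (eps_r * rc)
      if (pt$is_hbond[ti, tj]) {
        # find the donor hydrogen's heavy atom for the angle
        if (ti == "HD") {
          dh <- nearest_heavy(ra, i)
          dd <- sqrt((ra$x[dh] - ra$x[i])^2 + (ra$y[dh] - ra$y[i])^2 +
                       (ra$z[dh] - ra$z[i])^2)
          if (is.na(dh) || dd > 1.6) next  # no resolvable donor heavy atom
          tdeg <- dev_angle(c(ra$x[dh], ra$y[dh], ra$z[dh]),
                            c(ra$x[i], ra$y[i], ra$z[i]),
                            c(la$x[j], la$y[j], la$z[j]))
        } else {
          dh <- bonded_heavy(mol, j)
          tdeg <- dev_angle(c(la$x[dh], la$y[dh], la$z[dh]),
                            c(la$x[j], la$y[j], la$z[j]),
                            c(ra$x[i], ra$y[i], ra$z[i]))
        }
        et <- if (tdeg < params$hbond_angle_cutoff)
          cos(tdeg * pi / 180)^2 else 0
        e_hb <- e_hb + et * (pt$C[ti, tj] / rc^12 - pt$D[ti, tj] / rc^10)
      } else {
        e_vdw <- e_vdw + pt$A[ti, tj] / rc^12 - pt$B[ti, tj] / rc^6
      }
    }
  }
  params$w_vdw * e_vdw + params$w_hbond * e_hb + params$w_elec * e_el +
    params$w_tor * mol$n_tor + naive_dehydration(mol, hydration,
                                                 params$sigma)
}

nearest_heavy <- function(atoms, i) {
  heavy <- which(atoms$element != "H")
  d2 <- (atoms$x[heavy] - atoms$x[i])^2 + (atoms$y[heavy] - atoms$y[i])^2 +
    (atoms$z[heavy] - atoms$z[i])^2
  heavy[which.min(d2)]
}

bonded_heavy <- function(mol, j) {
  nb <- c(mol$bonds$j[mol$bonds$i == j], mol$bonds$i[mol$bonds$j == j])
  nb[mol$atoms$element[nb] != "H"][1]
}

dev_angle <- function(dxyz, hxyz, axyz) {
  u <- hxyz - dxyz; v <- axyz - hxyz
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# independent transliteration of the published PEOE iteration (water /
# simple molecules): chi(q) = a + b q + c q^2, damping (1/2)^k, charge
# flows to the more electronegative atom scaled by the cation
# electronegativity of the less electronegative one (20.02 for H)
peoe_reference_water <- function(n_iter = 8) {
  a <- c(O = 14.18, H = 7.17); b <- c(O = 12.92, H = 6.24)
  cc <- c(O = 1.39, H = -0.56)
  q <- c(O = 0, H1 = 0, H2 = 0)
  el <- c("O", "H", "H")
  bonds <- list(c(1, 2), c(1, 3))
  for (k in seq_len(n_iter)) {
    damp <- 0.5^k
    chi <- a[el] + b[el] * q + cc[el] * q^2
    dq <- numeric(3)
    for (bd in bonds) {
      i <- bd[1]; j <- bd[2]
      if (chi[j] > chi[i]) {
        denom <- if (el[i] == "H") 20.02 else sum(a[el[i]], b[el[i]], cc[el[i]])
        t <- (chi[j] - chi[i]) / denom * damp
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else if (chi[i] > chi[j]) {
        denom <- if (el[j] == "H") 20.02 else sum(a[el[j]], b[el[j]], cc[el[j]])
        t <- (chi[i] - chi[j]) / denom * damp
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  q
}

# small random receptor/ligand systems for oracle-equivalence sweeps
make_random_system <- function(seed) {
  set.seed(seed)
  n_r <- sample(4:8, 1)
  rel <- sample(c("C", "N", "O", "S", "H"), n_r, replace = TRUE)
  ratoms <- data.frame(
    serial = seq_len(n_r), element = rel,
    atom_name = ifelse(rel == "H", "H", "CB"),
    resno = 700L + seq_len(n_r), resname = "TOY", chain = "A",
    x = runif(n_r, -4, 4), y = runif(n_r, -4, 4), z = runif(n_r, -4, 4),
    charge = round(runif(n_r, -0.5, 0.5), 3), is_backbone = FALSE)
  ratoms$atom_type <- selectiscreen:::receptor_atom_types(ratoms)
  receptor <- structure(
    list(atoms = ratoms,
         residue_index = split(seq_len(n_r), ratoms$resno),
         hinge_residues = integer(0), pocket_center = NULL),
    class = "receptor")
  n_l <- sample(2:5, 1)
  lel <- c(sample(c("C", "N", "O"), 1),
           sample(c("C", "N", "O", "S", "H", "Cl"), n_l - 1, replace = TRUE))
  latoms <- data.frame(
    serial = seq_len(n_l), element = lel,
    x = runif(n_l, 3, 8), y = runif(n_l, 3, 8), z = runif(n_l, 3, 8))
  lbonds <- if (n_l > 1)
    data.frame(i = seq_len(n_l - 1), j = 2:n_l, order = 1L)
  else data.frame(i = integer(0), j = integer(0), order = integer(0))
  mol <- ligand_mol(latoms, lbonds, name = sprintf("toy%d", seed))
  mol$atoms$charge <- round(runif(n_l, -0.4, 0.4), 3)
  list(receptor = receptor, mol = mol)
}

# minimal single-type receptor helper for grid tests
toy_receptor <- function(xyz, types = "C", charges = 0,
                         names = "CB", resno = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  types <- rep_len(types, n); charges <- rep_len(charges, n)
  names <- rep_len(names, n)
  if (is.null(resno)) resno <- 700L + seq_len(n)
  el <- ifelse(types %in% c("H", "HD"), "H",
               ifelse(types == "A", "C",
                      ifelse(types == "NA", "N",
                             ifelse(types == "OA", "O",
                                    ifelse(types == "SA", "S", types)))))
  atoms <- data.frame(
    serial = seq_len(n), element = el, atom_name = names,
    resno = resno, resname = "TOY", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charges, is_backbone = names %in% c("N", "CA", "C", "O", "H"),
    atom_type = types)
  structure(list(atoms = atoms,
                 residue_index = split(seq_len(n), atoms$resno),
                 hinge_residues = integer(0), pocket_center = NULL),
            class = "receptor")
}

# single-atom ligand of a given type at a position
point_ligand <- function(type = "C", pos = c(0, 0, 0), charge = 0) {
  el <- switch(type, A = "C", `NA` = "N", OA = "O", SA = "S",
               HD = "H", type)
  mol <- ligand_mol(
    data.frame(serial = 1L, element = el,
               x = pos[1], y = pos[2], z = pos[3]),
    data.frame(i = integer(0), j = integer(0), order = integer(0)),
    name = "probe", retype = FALSE)
  mol$atoms$atom_type <- type
  mol$atoms$charge <- charge
  mol$n_tor <- 0L
  mol
}

smi_mols <- function(smiles, seed = 1L) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(smiles, tmp)
  suppressWarnings(read_ligands(tmp, embed_seed = seed))
}
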