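#' 12-6 Lennard-Jones pair energy
#'
#' `A/r^12 - B/r^6`.  Distances below the inner clamp are evaluated at
#' the clamp radius so that clashed poses stay finite.
#'
#' @param r Interatomic distance(s), Angstrom; must be > 0.
#' @param A,B Pair coefficients (> 0 for real pairs).
#' @param r_clamp Inner clamp radius (default 0.5 A).
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
lj_12_6 <- function(r, A, B, r_clamp = 0.5) {
  if (any(r <= 0)) stop("lj_12_6: distance must be positive")
  r <- pmax(r, r_clamp)
  A / r^12 - B / r^6
}

#' Angular directionality weight of a hydrogen bond
#'
#' `cos^2(t)` for deviation angles up to the cutoff, zero beyond: unity
#' for ideal linear donor-H...acceptor geometry, falling smoothly to
#' zero at 90 degrees.
#'
#' @param t Deviation angle(s) from linearity, degrees, in \[0, 180\].
#' @param cutoff Cutoff angle in degrees (default 90).
#' @return Weight(s) in \[0, 1\].
#' @export
directionality_weight <- function(t, cutoff = 90) {
  stopifnot(all(t >= 0 & t <= 180))
  ifelse(t < cutoff, cos(t * pi / 180)^2, 0)
}

#' 12-10 hydrogen-bond pair energy
#'
#' `E(t) * (C/r^12 - D/r^10)` where `E(t)` is the directionality weight.
#'
#' @param r Distance(s), Angstrom.
#' @param C,D 12-10 coefficients.
#' @param t Deviation angle(s) from ideal linear geometry, degrees.
#' @param cutoff Angular cutoff, degrees.
#' @param r_clamp Inner clamp radius.
#' @return Energy in kcal/mol.
#' @export
hb_12_10 <- function(r, C, D, t = 0, cutoff = 90, r_clamp = 0.5) {
  if (any(r <= 0)) stop("hb_12_10: distance must be positive")
  r <- pmax(r, r_clamp)
  directionality_weight(t, cutoff) * (C / r^12 - D / r^10)
}

#' Distance-dependent sigmoidal dielectric
#'
#' `eps(r) = A + B / (1 + k exp(-lambda B r))`, a monotone screening
#' function rising from ~1.35 at contact to the bulk-water value of
#' ~78.4 at long range.
#'
#' @param r Distance(s), Angstrom, >= 0.
#' @param dc Named constants `A`, `B`, `k`, `lambda`.
#' @return Dielectric value(s).
#' @export
sigmoidal_dielectric <- function(r, dc = default_energy_params()$dielectric) {
  dc[["A"]] + dc[["B"]] / (1 + dc[["k"]] * exp(-dc[["lambda"]] * dc[["B"]] * r))
}

#' Screened Coulomb pair energy
#'
#' `k_c * q_i q_j / (eps(r) r)` with the sigmoidal dielectric.
#'
#' @param qi,qj Partial charges, e.
#' @param r Distance(s), Angstrom, > 0.
#' @param params Energy parameter list.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(qi, qj, r, params = default_energy_params()) {
  if (any(r <= 0)) stop("coulomb_energy: distance must be positive")
  r <- pmax(r, params$r_clamp)
  params$coulomb_constant * qi * qj / (sigmoidal_dielectric(r, params$dielectric) * r)
}

#' Torsional entropy penalty
#'
#' `W_tor * N_tor`: a constant cost per rotatable bond frozen on binding.
#'
#' @param n_tor Rotatable-bond count (>= 0).
#' @param w_tor Weight, kcal/mol per bond.
#' @return Energy in kcal/mol.
#' @export
torsion_penalty <- function(n_tor, w_tor = default_energy_params()$w_tor) {
  stopifnot(n_tor >= 0)
  w_tor * n_tor
}

#' Gaussian hydration-shell occupancy of one ligand atom
#'
#' `sum_{j != i} V_j exp(-r_ij^2 / 2 sigma^2)` over the other atoms of
#' the same molecule: the solute volume crowding atom i's hydration
#' shell.  An isolated atom has occupancy zero.
#'
#' @param i Atom index.
#' @param mol A `ligand_mol`.
#' @param hydration Hydration parameter table (type, S, V, O_max).
#' @param sigma Gaussian width, Angstrom.
#' @return Occupancy in A^3.
#' @export
ligand_occupancy <- function(i, mol, hydration = default_hydration_params(),
                             sigma = default_energy_params()$sigma) {
  v <- hydration_lookup(mol$atoms$atom_type, hydration)$V
  xyz <- coords(mol)
  d2 <- colSums((t(xyz) - xyz[i, ])^2)
  sum(v[-i] * exp(-d2[-i] / (2 * sigma^2)))
}

hydration_lookup <- function(types, hydration) {
  idx <- match(types, hydration$type)
  if (anyNA(idx))
    stop("no hydration parameters for atom type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "))
  hydration[idx, , drop = FALSE]
}

#' Ligand dehydration free energy term
#'
#' `sum_i S_i * max(0, O_i^max - occupancy_i)`: the negative of the
#' ligand hydration free energy in the solvent-contact model.  It
#' depends only on the ligand's own conformation — receptor coordinates
#' never enter — and the residual exposure is clamped at zero.
#'
#' @param mol A `ligand_mol`.
#' @param hydration Hydration parameter table.
#' @param sigma Gaussian width, Angstrom.
#' @return Energy in kcal/mol.
#' @export
dehydration_term <- function(mol, hydration = default_hydration_params(),
                             sigma = default_energy_params()$sigma) {
  hp <- hydration_lookup(mol$atoms$atom_type, hydration)
  xyz <- coords(mol)
  n <- nrow(xyz)
  if (n == 1L) return(hp$S[1] * hp$O_max[1])
  d2 <- as.matrix(stats::dist(xyz))^2
  g <- exp(-d2 / (2 * sigma^2))
  diag(g) <- 0
  occ <- as.numeric(g %*% hp$V)
  sum(hp$S * pmax(0, hp$O_max - occ))
}

new_breakdown <- function(e_vdw, e_hbond, e_elec, e_tor, e_dehydration) {
  structure(list(e_vdw = e_vdw, e_hbond = e_hbond, e_elec = e_elec,
                 e_tor = e_tor, e_dehydration = e_dehydration,
                 total = e_vdw + e_hbond + e_elec + e_tor + e_dehydration),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "dG_b(aq) = %8.3f kcal/mol  [vdW %7.3f | H-bond %7.3f | elec %7.3f | tor %6.3f | dehyd %6.3f]\n",
    x$total, x$e_vdw, x$e_hbond, x$e_elec, x$e_tor, x$e_dehydration))
  invisible(x)
}

#' @export
format.score_breakdown <- function(x, ...) {
  sprintf("total=%.4f vdw=%.4f hbond=%.4f elec=%.4f tor=%.4f dehyd=%.4f",
          x$total, x$e_vdw, x$e_hbond, x$e_elec, x$e_tor, x$e_dehydration)
}

# index of the covalently attached heavy atom for each HD hydrogen
donor_heavy_index <- function(atoms, bonds = NULL) {
  n <- nrow(atoms)
  dh <- rep(NA_integer_, n)
  hd <- which(atoms$atom_type == "HD")
  if (!length(hd)) return(dh)
  if (!is.null(bonds) && nrow(bonds)) {
    for (i in hd) {
      nb <- c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
      nb <- nb[atoms$element[nb] != "H"]
      if (length(nb)) dh[i] <- nb[1]
    }
  } else {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    heavy <- which(atoms$element != "H")
    for (i in hd) {
      d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[i, ])^2)
      j <- heavy[which.min(d2)]
      if (d2[which.min(d2)] < 1.6^2) dh[i] <- j
    }
  }
  dh
}

# deviation from linear D-H...A geometry, degrees
hb_deviation_angle <- function(d_xyz, h_xyz, a_xyz) {
  u <- h_xyz - d_xyz
  v <- a_xyz - h_xyz
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Protein-ligand binding free energy
#'
#' Evaluates the full scoring function over all receptor-ligand atom
#' pairs within the nonbonded cutoff: weighted 12-6 van der Waals,
#' angle-weighted 12-10 hydrogen bonds, sigmoidally screened Coulomb
#' electrostatics, the torsional entropy penalty, and the ligand
#' dehydration term (a pure ligand property).
#'
#' @param receptor A `receptor`.
#' @param mol A typed, charged `ligand_mol`, already posed in the
#'   receptor frame (or supply `pose`).
#' @param pose Optional `pose_genome` applied to `mol` first.
#' @param params Energy parameter list.
#' @param pair_table Pair-potential table.
#' @param hydration Hydration parameter table.
#' @return A `score_breakdown` with the five terms and their sum.
#' @export
binding_free_energy <- function(receptor, mol, pose = NULL,
                                params = default_energy_params(),
                                pair_table = default_pair_potentials(),
                                hydration = default_hydration_params()) {
  if (!is.null(pose)) mol <- apply_pose(mol, pose)
  scorer <- make_direct_scorer(receptor, mol, params, pair_table, hydration)
  scorer(coords(mol))
}
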