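# Precomputed-closure scorers: all pairwise coefficient matrices, donor
# indices and hydration vectors are resolved once per (receptor, ligand)
# pair, so pose evaluation inside search loops touches only numeric
# matrices.  binding_free_energy() is a thin wrapper over these, so the
# fast path and the public API share one arithmetic.

#' Build a direct scorer for one receptor-ligand pair
#'
#' Returns a function of ligand coordinates (n x 3 matrix) evaluating
#' the full scoring function and returning a `score_breakdown`.
#'
#' @param receptor A `receptor`.
#' @param mol A typed, charged `ligand_mol`.
#' @param params,pair_table,hydration Scoring parameters.
#' @return `function(xyz)` -> `score_breakdown`.
#' @export
make_direct_scorer <- function(receptor, mol,
                               params = default_energy_params(),
                               pair_table = default_pair_potentials(),
                               hydration = default_hydration_params()) {
  rt <- receptor$atoms$atom_type
  lt <- mol$atoms$atom_type
  miss <- setdiff(c(rt, lt), pair_table$types)
  if (length(miss))
    stop("atom types missing from pair table: ", paste(miss, collapse = ", "))
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  nr <- nrow(rxyz); nl <- length(lt)
  ri <- match(rt, pair_table$types)
  li <- match(lt, pair_table$types)
  IJ <- cbind(rep(ri, nl), rep(li, each = nr))
  Amat <- matrix(pair_table$A[IJ], nr, nl)
  Bmat <- matrix(pair_table$B[IJ], nr, nl)
  Cmat <- matrix(pair_table$C[IJ], nr, nl)
  Dmat <- matrix(pair_table$D[IJ], nr, nl)
  hbmat <- matrix(pair_table$is_hbond[IJ], nr, nl)
  qq <- outer(receptor$atoms$charge, mol$atoms$charge)
  dh_rec <- donor_heavy_index(receptor$atoms)
  dh_lig <- donor_heavy_index(mol$atoms, mol$bonds)
  hp <- hydration_lookup(lt, hydration)
  Sv <- hp$S; Vv <- hp$V; Ov <- hp$O_max
  rsq <- rowSums(rxyz^2)
  n_tor <- mol$n_tor
  cutoff <- params$nb_cutoff; rcl <- params$r_clamp
  dc <- params$dielectric
  kc <- params$coulomb_constant
  acut <- params$hbond_angle_cutoff
  two_sig2 <- 2 * params$sigma^2
  e_tor <- params$w_tor * n_tor
  function(xyz) {
    d2 <- outer(rsq, rowSums(xyz^2), "+") - 2 * rxyz %*% t(xyz)
    d <- sqrt(pmax(d2, 0))
    within <- d <= cutoff
    dcl <- pmax(d, rcl)
    inv2 <- 1 / (dcl * dcl)
    inv6 <- inv2 * inv2 * inv2
    inv12 <- inv6 * inv6
    e_vdw <- params$w_vdw *
      sum(((Amat * inv12 - Bmat * inv6) * within)[!hbmat])
    eps <- dc[["A"]] + dc[["B"]] /
      (1 + dc[["k"]] * exp(-dc[["lambda"]] * dc[["B"]] * dcl))
    e_elec <- params$w_elec * sum((kc * qq / (eps * dcl)) * within)
    e_hbond <- 0
    hb_idx <- which(hbmat & within, arr.ind = TRUE)
    if (nrow(hb_idx)) {
      for (k in seq_len(nrow(hb_idx))) {
        i <- hb_idx[k, 1]; j <- hb_idx[k, 2]
        if (rt[i] == "HD") {
          dhv <- dh_rec[i]
          if (is.na(dhv)) next
          t <- hb_deviation_angle(rxyz[dhv, ], rxyz[i, ], xyz[j, ])
        } else {
          dhv <- dh_lig[j]
          if (is.na(dhv)) next
          t <- hb_deviation_angle(xyz[dhv, ], xyz[j, ], rxyz[i, ])
        }
        e_hbond <- e_hbond + directionality_weight(t, acut) *
          (Cmat[i, j] * inv12[i, j] - Dmat[i, j] * inv2[i, j]^5)
      }
      e_hbond <- params$w_hbond * e_hbond
    }
    ld2 <- as.matrix(stats::dist(xyz))^2
    g <- exp(-ld2 / two_sig2)
    diag(g) <- 0
    occ <- as.numeric(g %*% Vv)
    e_dehyd <- sum(Sv * pmax(0, Ov - occ))
    new_breakdown(e_vdw, e_hbond, e_elec, e_tor, e_dehyd)
  }
}

#' Build a grid scorer for one ligand over precomputed maps
#'
#' Returns a function of ligand coordinates evaluating the
#' grid-interpolated interaction energy plus the torsional and
#' dehydration terms (the quantity the pose search minimizes).
#'
#' @param mol A `ligand_mol`.
#' @param maps A `grid_maps`.
#' @param params,hydration Scoring parameters.
#' @return `function(xyz)` -> numeric total (kcal/mol).
#' @export
make_grid_scorer <- function(mol, maps,
                             params = default_energy_params(),
                             hydration = default_hydration_params()) {
  lt <- mol$atoms$atom_type
  q <- mol$atoms$charge
  n <- length(lt)
  box <- maps$box
  np <- box$npts
  npts_total <- prod(np)
  # combined per-atom array: vdw + bound hbond + w_elec * q * elec
  M <- matrix(0, npts_total, n)
  for (i in seq_len(n)) {
    ty <- lt[i]
    if (is.null(maps$vdw[[ty]]))
      stop("no grid map for probe type '", ty, "'")
    a <- as.numeric(maps$vdw[[ty]])
    if (!is.null(maps$hbond[[ty]])) a <- a + as.numeric(maps$hbond[[ty]])
    if (q[i] != 0) a <- a + params$w_elec * q[i] * as.numeric(maps$elec)
    M[, i] <- a
  }
  Mflat <- as.numeric(M)
  hp <- hydration_lookup(lt, hydration)
  Sv <- hp$S; Vv <- hp$V; Ov <- hp$O_max
  two_sig2 <- 2 * params$sigma^2
  e_tor <- params$w_tor * mol$n_tor
  pen <- params$oob_penalty
  origin <- box$origin; spacing <- box$spacing
  nx <- np[1]; ny <- np[2]; nz <- np[3]
  col_off <- (seq_len(n) - 1L) * npts_total
  function(xyz) {
    u1 <- (xyz[, 1] - origin[1]) / spacing
    u2 <- (xyz[, 2] - origin[2]) / spacing
    u3 <- (xyz[, 3] - origin[3]) / spacing
    ok <- u1 >= 0 & u1 <= nx - 1 & u2 >= 0 & u2 <= ny - 1 &
          u3 >= 0 & u3 <= nz - 1
    e <- pen * sum(!ok)
    if (any(ok)) {
      i1 <- pmin(floor(u1[ok]), nx - 2); f1 <- u1[ok] - i1
      i2 <- pmin(floor(u2[ok]), ny - 2); f2 <- u2[ok] - i2
      i3 <- pmin(floor(u3[ok]), nz - 2); f3 <- u3[ok] - i3
      base <- i1 + nx * (i2 + ny * i3) + col_off[ok] + 1
      g1 <- 1 - f1; g2 <- 1 - f2; g3 <- 1 - f3
      v <- g1 * g2 * g3 * Mflat[base] +
           f1 * g2 * g3 * Mflat[base + 1] +
           g1 * f2 * g3 * Mflat[base + nx] +
           f1 * f2 * g3 * Mflat[base + nx + 1] +
           g1 * g2 * f3 * Mflat[base + nx * ny] +
           f1 * g2 * f3 * Mflat[base + nx * ny + 1] +
           g1 * f2 * f3 * Mflat[base + nx * ny + nx] +
           f1 * f2 * f3 * Mflat[base + nx * ny + nx + 1]
      e <- e + sum(v)
    }
    d2m <- tcrossprod(xyz)
    sq <- diag(d2m)
    ld2 <- outer(sq, sq, "+") - 2 * d2m
    g <- exp(-ld2 / two_sig2)
    diag(g) <- 0
    occ <- as.numeric(g %*% Vv)
    e + e_tor + sum(Sv * pmax(0, Ov - occ))
  }
}

#' Build a pose-to-coordinates transformer
#'
#' Precomputes the rotatable-bond partition once; the returned function
#' maps a `pose_genome` to transformed coordinates.
#'
#' @param mol A `ligand_mol`.
#' @return `function(pose)` -> n x 3 coordinate matrix.
#' @export
make_pose_transformer <- function(mol) {
  xyz0 <- coords(mol)
  rb <- rotatable_bonds(mol)
  nt <- length(rb)
  function(pose) {
    xyz <- xyz0
    if (length(pose$torsions) > 0) {
      if (length(pose$torsions) != nt)
        stop("pose has ", length(pose$torsions), " torsions but molecule has ",
             nt, " rotatable bonds")
      for (k in seq_len(nt)) {
        if (pose$torsions[k] != 0)
          xyz <- rotate_torsion(xyz, rb[[k]]$i, rb[[k]]$j, rb[[k]]$moving,
                                pose$torsions[k])
      }
    }
    ctr <- colMeans(xyz)
    R <- quat_to_matrix(pose$quaternion)
    sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + pose$translation, "+")
  }
}
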