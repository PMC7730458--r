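#' Construct a pose genome
#'
#' Rigid-body translation, orientation quaternion and one dihedral per
#' rotatable bond — the search-space encoding of a ligand pose.
#'
#' @param translation 3-vector, Angstrom, applied to the ligand centroid.
#' @param quaternion Unit quaternion (w, x, y, z); renormalized on entry.
#' @param torsions Angles in degrees, wrapped into \[-180, 180).
#' @return A `pose_genome`.
#' @export
pose_genome <- function(translation = c(0, 0, 0),
                        quaternion = c(1, 0, 0, 0),
                        torsions = numeric(0)) {
  nq <- sqrt(sum(quaternion^2))
  stopifnot(nq > 0)
  structure(list(translation = as.numeric(translation),
                 quaternion = quaternion / nq,
                 torsions = wrap_angle(torsions)),
            class = "pose_genome")
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

axis_angle_quat <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

random_unit_quat <- function() {
  # Shoemake's method from three uniforms (uses the session RNG stream)
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

# rotate `moving` atoms of xyz about the bond axis (i -> j) by angle degrees
rotate_torsion <- function(xyz, i, j, moving, angle_deg) {
  axis <- xyz[j, ] - xyz[i, ]
  R <- quat_to_matrix(axis_angle_quat(axis, angle_deg))
  pivot <- xyz[j, ]
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, pivot) %*%
                           t(R), 2, pivot, "+")
  xyz
}

#' Apply a pose genome to a molecule
#'
#' Torsions are applied first (in the ligand frame, in the order given
#' by [rotatable_bonds()], as offsets from the input conformation), then
#' the rigid rotation about the ligand centroid, then the translation.
#'
#' @param mol A `ligand_mol`.
#' @param pose A `pose_genome`; `length(pose$torsions)` must equal
#'   `mol$n_tor` (or 0 to leave torsions untouched).
#' @return The molecule with transformed coordinates.
#' @export
apply_pose <- function(mol, pose) {
  xyz <- coords(mol)
  nt <- length(pose$torsions)
  if (nt > 0) {
    rb <- rotatable_bonds(mol)
    if (nt != length(rb))
      stop("pose has ", nt, " torsions but molecule has ", length(rb),
           " rotatable bonds")
    for (k in seq_len(nt)) {
      if (pose$torsions[k] != 0)
        xyz <- rotate_torsion(xyz, rb[[k]]$i, rb[[k]]$j, rb[[k]]$moving,
                              pose$torsions[k])
    }
  }
  ctr <- colMeans(xyz)
  R <- quat_to_matrix(pose$quaternion)
  xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + pose$translation, "+")
  set_coords(mol, xyz)
}

#' Search configuration
#'
#' @param seed Integer RNG seed; identical (inputs, seed) give identical
#'   results.
#' @param n_starts Independent restarts.
#' @param n_steps Metropolis steps per start.
#' @param step_translation Move scale, Angstrom.
#' @param step_rotation,step_torsion Move scales, degrees.
#' @param t_start,t_final Metropolis temperature schedule (kcal/mol,
#'   geometric cooling).
#' @param n_greedy Greedy terminal-descent steps appended to each start.
#' @return A `search_config` list.
#' @export
search_config <- function(seed = 1L, n_starts = 4L, n_steps = 150L,
                          step_translation = 1.0, step_rotation = 30,
                          step_torsion = 30, t_start = 2.0, t_final = 0.1,
                          n_greedy = 50L) {
  stopifnot(n_starts >= 1, n_steps >= 0)
  list(seed = as.integer(seed), n_starts = as.integer(n_starts),
       n_steps = as.integer(n_steps),
       step_translation = step_translation, step_rotation = step_rotation,
       step_torsion = step_torsion, t_start = t_start, t_final = t_final,
       n_greedy = as.integer(n_greedy))
}

perturb_pose <- function(pose, config, scale = 1) {
  which_move <- sample.int(3L, 1L)
  if (which_move == 1L || length(pose$torsions) == 0L && which_move == 3L) {
    pose$translation <- pose$translation +
      stats::rnorm(3, sd = config$step_translation * scale)
  } else if (which_move == 2L) {
    ax <- stats::rnorm(3)
    dq <- axis_angle_quat(ax, stats::rnorm(1, sd = config$step_rotation * scale))
    pose$quaternion <- quat_multiply(dq, pose$quaternion)
    pose$quaternion <- pose$quaternion / sqrt(sum(pose$quaternion^2))
  } else {
    k <- sample.int(length(pose$torsions), 1L)
    pose$torsions[k] <- wrap_angle(pose$torsions[k] +
      stats::rnorm(1, sd = config$step_torsion * scale))
  }
  pose
}

#' Optimize a ligand pose over grid maps
#'
#' Multi-start Metropolis annealing with a greedy terminal descent: each
#' start draws a random orientation, torsion vector and translation
#' inside the box, then anneals on the grid-interpolated energy (plus
#' torsional and dehydration terms).  A deliberately simple, fully
#' seeded optimizer: the scientific content lives in the scoring
#' function, not the engine.
#'
#' @param mol A typed, charged `ligand_mol`.
#' @param maps A `grid_maps` of the target receptor.
#' @param config A [search_config()].
#' @param params Energy parameters.
#' @param start_pose Optional `pose_genome` used as the first start
#'   (with `n_steps = 0` it is returned scored, unchanged).
#' @return List with `pose` (best genome), `energy` (its grid score,
#'   kcal/mol), `n_eval`, and `starts`: the best (pose, energy) of every
#'   restart, for candidate rescoring.
#' @export
optimize_pose <- function(mol, maps, config = search_config(),
                          params = default_energy_params(),
                          start_pose = NULL) {
  box <- maps$box
  lo <- box$origin; hi <- box_max(box)
  if (any(hi - lo <= 0)) stop("degenerate search box")
  ctr0 <- colMeans(coords(mol))
  nt <- mol$n_tor
  to_xyz <- make_pose_transformer(mol)
  grid_score <- make_grid_scorer(mol, maps, params)
  score_pose <- function(pose) grid_score(to_xyz(pose))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  best <- NULL; best_e <- Inf; n_eval <- 0L
  start_results <- vector("list", config$n_starts)
  cool <- if (config$n_steps > 1)
    (config$t_final / config$t_start)^(1 / (config$n_steps - 1)) else 1
  for (s in seq_len(config$n_starts)) {
    if (s == 1L && !is.null(start_pose)) {
      pose <- start_pose
    } else {
      pose <- pose_genome(
        translation = stats::runif(3, lo, hi) - ctr0,
        quaternion = random_unit_quat(),
        torsions = if (nt > 0) stats::runif(nt, -180, 180) else numeric(0))
    }
    e <- score_pose(pose); n_eval <- n_eval + 1L
    sbest <- pose; sbest_e <- e
    temp <- config$t_start
    cur <- pose; cur_e <- e
    for (k in seq_len(config$n_steps)) {
      cand <- perturb_pose(cur, config)
      ce <- score_pose(cand); n_eval <- n_eval + 1L
      if (ce <= cur_e || stats::runif(1) < exp((cur_e - ce) / temp)) {
        cur <- cand; cur_e <- ce
        if (ce < sbest_e) { sbest <- cand; sbest_e <- ce }
      }
      temp <- temp * cool
    }
    # greedy descent from the best-so-far of this start
    cur <- sbest; cur_e <- sbest_e
    ng <- if (config$n_steps == 0L) 0L else config$n_greedy
    for (k in seq_len(ng)) {
      cand <- perturb_pose(cur, config, scale = 0.25)
      ce <- score_pose(cand); n_eval <- n_eval + 1L
      if (ce < cur_e) { cur <- cand; cur_e <- ce }
    }
    if (cur_e < sbest_e) { sbest <- cur; sbest_e <- cur_e }
    start_results[[s]] <- list(pose = sbest, energy = sbest_e)
    if (sbest_e < best_e) { best <- sbest; best_e <- sbest_e }
  }
  list(pose = best, energy = best_e, n_eval = n_eval,
       starts = start_results)
}

#' Rescore a pose with the full direct scoring function
#'
#' The exact evaluation — including true angular hydrogen-bond
#' directionality — used by every downstream filter; grid scores only
#' guide the search.
#'
#' @param receptor A `receptor`.
#' @param mol A `ligand_mol`.
#' @param pose A `pose_genome`.
#' @param params,pair_table,hydration Scoring parameters.
#' @return A `score_breakdown`.
#' @export
rescore_direct <- function(receptor, mol, pose,
                           params = default_energy_params(),
                           pair_table = default_pair_potentials(),
                           hydration = default_hydration_params()) {
  binding_free_energy(receptor, mol, pose = pose, params = params,
                      pair_table = pair_table, hydration = hydration)
}

#' Scan the whole domain for peripheral binding sites
#'
#' Runs independent seeded pose searches from a coarse lattice of start
#' points covering the box, rescores the best pose of each start
#' directly, clusters results by proximity, and reports representatives
#' with negative total binding free energy, sorted ascending.
#'
#' @param receptor A `receptor`.
#' @param mol A `ligand_mol`.
#' @param maps Whole-domain `grid_maps`.
#' @param config A [search_config()]; one annealing run per lattice site.
#' @param params,pair_table,hydration Scoring parameters.
#' @param lattice_spacing Start-lattice spacing, Angstrom.
#' @param exclude_center,exclude_radius Optionally drop sites within a
#'   radius (A) of an annotated pocket center.
#' @param cluster_radius Sites closer than this merge, Angstrom.
#' @return data.frame with columns x, y, z (site center) and dg (best
#'   total, kcal/mol); zero rows when no site scores negative.
#' @export
peripheral_site_scan <- function(receptor, mol, maps,
                                 config = search_config(n_starts = 1L),
                                 params = default_energy_params(),
                                 pair_table = default_pair_potentials(),
                                 hydration = default_hydration_params(),
                                 lattice_spacing = 6,
                                 exclude_center = NULL, exclude_radius = 8,
                                 cluster_radius = 4) {
  box <- maps$box
  lo <- box$origin; hi <- box_max(box)
  ax <- lapply(1:3, function(k) {
    n <- max(1L, floor((hi[k] - lo[k]) / lattice_spacing))
    lo[k] + (seq_len(n) - 0.5) * (hi[k] - lo[k]) / n
  })
  starts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ctr0 <- colMeans(coords(mol))
  hits <- list()
  for (s in seq_len(nrow(starts))) {
    cfg <- config
    cfg$seed <- config$seed + s
    sp <- pose_genome(translation = starts[s, ] - ctr0,
                      torsions = rep(0, mol$n_tor))
    res <- optimize_pose(mol, maps, cfg, params, start_pose = sp)
    sb <- rescore_direct(receptor, mol, res$pose, params, pair_table,
                         hydration)
    if (sb$total < 0) {
      posed <- apply_pose(mol, res$pose)
      hits[[length(hits) + 1L]] <-
        c(colMeans(coords(posed)), dg = sb$total)
    }
  }
  if (!length(hits))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      dg = numeric(0)))
  df <- as.data.frame(do.call(rbind, hits))
  names(df) <- c("x", "y", "z", "dg")
  df <- df[order(df$dg), , drop = FALSE]
  if (!is.null(exclude_center)) {
    d <- sqrt((df$x - exclude_center[1])^2 + (df$y - exclude_center[2])^2 +
                (df$z - exclude_center[3])^2)
    df <- df[d > exclude_radius, , drop = FALSE]
  }
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- df[keep, , drop = FALSE]
    d <- sqrt((prev$x - df$x[i])^2 + (prev$y - df$y[i])^2 +
                (prev$z - df$z[i])^2)
    if (all(d > cluster_radius)) keep[i] <- TRUE
  }
  rownames(df) <- NULL
  df[keep, , drop = FALSE]
}

#' Locally refine a pose against the direct scoring function
#'
#' Greedy stochastic descent with progressively shrinking rigid-body
#' and torsion moves, accepting only improvements of the exact (direct)
#' total.  The standard final step after a grid-guided search: it
#' removes the interpolation bias of steep wells near hydrogen-bond
#' contacts.
#'
#' @param receptor A `receptor`.
#' @param mol A `ligand_mol`.
#' @param pose Starting `pose_genome`.
#' @param params,pair_table,hydration Scoring parameters.
#' @param n_steps Moves per shrink stage.
#' @param stages Number of shrink stages (scale halves each stage).
#' @param seed RNG seed.
#' @param polish Run a final derivative-free simplex minimization of
#'   the pose parameters (deterministic, tight convergence to the local
#'   minimum).
#' @return List with `pose` and `score` (a `score_breakdown`).
#' @export
refine_pose <- function(receptor, mol, pose,
                        params = default_energy_params(),
                        pair_table = default_pair_potentials(),
                        hydration = default_hydration_params(),
                        n_steps = 40L, stages = 3L, seed = 1L,
                        polish = TRUE) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cfg <- search_config(seed = seed, step_translation = 0.4,
                       step_rotation = 10, step_torsion = 10)
  to_xyz <- make_pose_transformer(mol)
  scorer <- make_direct_scorer(receptor, mol, params, pair_table, hydration)
  cur <- pose
  cur_sb <- scorer(to_xyz(cur))
  scale <- 1
  for (st in seq_len(stages)) {
    for (k in seq_len(n_steps)) {
      cand <- perturb_pose(cur, cfg, scale = scale)
      sb <- scorer(to_xyz(cand))
      if (sb$total < cur_sb$total) { cur <- cand; cur_sb <- sb }
    }
    scale <- scale / 2
  }
  if (polish) {
    nt <- length(cur$torsions)
    obj <- function(par) {
      scorer(to_xyz(pose_with_delta(cur, par)))$total
    }
    # restart the simplex once from its own optimum: recovers from
    # premature convergence of a degenerate simplex
    for (round in 1:2) {
      op <- stats::optim(rep(0, 6 + nt), obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
      if (op$value < cur_sb$total) {
        cur <- pose_with_delta(cur, op$par)
        cur_sb <- scorer(to_xyz(cur))
      }
    }
  }
  list(pose = cur, score = cur_sb)
}

# apply a small parameter increment (dt xyz A, rotation vector in
# degrees, torsion offsets in degrees) to a pose genome
pose_with_delta <- function(pose, par) {
  nt <- length(pose$torsions)
  dt <- par[1:3]
  rv <- par[4:6]
  ang <- sqrt(sum(rv^2))
  q <- pose$quaternion
  if (ang > 1e-12) q <- quat_multiply(axis_angle_quat(rv / ang, ang), q)
  tors <- pose$torsions
  if (nt > 0) tors <- wrap_angle(tors + par[7:(6 + nt)])
  pose_genome(pose$translation + dt, q, tors)
}


#' Dock a ligand: grid search, candidate rescoring, local refinement
#'
#' The full docking driver: a multi-start grid search, direct rescoring
#' of the best pose of the top `n_refine` starts (the grid hydrogen-bond
#' maps are an upper bound, so grid rank and exact rank can differ),
#' local refinement of each candidate against the exact function, and
#' selection of the lowest direct total.
#'
#' @param mol A `ligand_mol`.
#' @param receptor The target `receptor`.
#' @param maps Its `grid_maps`.
#' @param config A [search_config()].
#' @param params,pair_table,hydration Scoring parameters.
#' @param n_refine Candidates taken from the grid ranking.
#' @param refine_steps,refine_stages Refinement effort per candidate.
#' @param n_hops Finisher effort: `100 * n_hops` low-temperature
#'   Metropolis steps on the direct score from the best refined pose,
#'   followed by re-polishing; escapes shallow neighbouring minima.
#'   0 disables the finisher.
#' @return List with `pose` and `score` (a `score_breakdown`).
#' @export
dock_ligand <- function(mol, receptor, maps, config = search_config(),
                        params = default_energy_params(),
                        pair_table = default_pair_potentials(),
                        hydration = default_hydration_params(),
                        n_refine = 5L, refine_steps = 60L,
                        refine_stages = 4L, n_hops = 4L) {
  opt <- optimize_pose(mol, maps, config, params)
  es <- vapply(opt$starts, `[[`, numeric(1), "energy")
  ord <- order(es)[seq_len(min(n_refine, length(es)))]
  best <- NULL
  for (i in ord) {
    r <- refine_pose(receptor, mol, opt$starts[[i]]$pose, params,
                     pair_table, hydration, n_steps = refine_steps,
                     stages = refine_stages, seed = config$seed + i)
    if (is.null(best) || r$score$total < best$score$total) best <- r
  }
  if (n_hops > 0L) {
    # low-temperature Metropolis finisher on the direct score: samples
    # across shallow neighbouring minima, then polishes the best visit
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed + 7919L)
    to_xyz <- make_pose_transformer(mol)
    scorer <- make_direct_scorer(receptor, mol, params, pair_table,
                                 hydration)
    cfg <- search_config(seed = config$seed, step_translation = 0.35,
                         step_rotation = 8, step_torsion = 8)
    temp <- 0.25
    cur <- best$pose; cur_e <- best$score$total
    mc_best <- cur; mc_best_e <- cur_e
    for (h in seq_len(100L * n_hops)) {
      cand <- perturb_pose(cur, cfg)
      ce <- scorer(to_xyz(cand))$total
      if (ce <= cur_e || stats::runif(1) < exp((cur_e - ce) / temp)) {
        cur <- cand; cur_e <- ce
        if (ce < mc_best_e) { mc_best <- cand; mc_best_e <- ce }
      }
    }
    r <- refine_pose(receptor, mol, mc_best, params, pair_table, hydration,
                     n_steps = 20L, stages = 2L, seed = config$seed + 7919L)
    if (r$score$total < best$score$total) best <- r
  }
  best
}
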