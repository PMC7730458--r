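#' Screening thresholds
#'
#' Defaults encode the two-track selection rule: candidates must score
#' strictly below -10 kcal/mol against the mutant and strictly above
#' -6 kcal/mol against the wild type (together forcing a selectivity
#' gap above 4 kcal/mol), and form at least two hydrogen bonds with
#' hinge backbone groups at heavy-atom distance strictly below 3.5 A.
#'
#' @param dg_mut_max Mutant-track upper bound, kcal/mol.
#' @param dg_wt_min Wild-type-track lower bound, kcal/mol.
#' @param hbond_distance_max Heavy-atom H-bond distance bound, Angstrom.
#' @param min_hinge_hbonds Minimum hinge hydrogen-bond count.
#' @param hinge_residues Hinge residue numbers.
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(dg_mut_max = -10.0, dg_wt_min = -6.0,
                              hbond_distance_max = 3.5,
                              min_hinge_hbonds = 2L,
                              hinge_residues = 791:795) {
  stopifnot(dg_mut_max < dg_wt_min, hbond_distance_max > 0)
  list(dg_mut_max = dg_mut_max, dg_wt_min = dg_wt_min,
       hbond_distance_max = hbond_distance_max,
       min_hinge_hbonds = as.integer(min_hinge_hbonds),
       hinge_residues = as.integer(hinge_residues))
}

#' Build library entries from molecules
#'
#' Computes per-molecule molecular weight, rule-of-five violation count
#' and path fingerprint; logP is evaluated in one batched call.
#'
#' @param mols List of `ligand_mol` objects.
#' @return List of entries: `id`, `mol`, `mw`, `logp`, `hbd`, `hba`,
#'   `violations`, `fingerprint`.
#' @export
build_library_entries <- function(mols) {
  if (!length(mols)) return(list())
  logp <- batch_logp(mols)
  lapply(seq_along(mols), function(k) {
    mol <- mols[[k]]
    mw <- molecular_weight(mol$formula)
    el <- mol$atoms$element
    adj <- adjacency(mol)
    no <- which(el %in% c("N", "O"))
    hbd <- sum(vapply(no, function(i) any(el[adj[[i]]] == "H"), logical(1)))
    hba <- length(no)
    viol <- sum(mw > 500, logp[k] > 5, hbd > 5, hba > 10)
    list(id = mol$name, mol = mol, mw = mw, logp = logp[k],
         hbd = hbd, hba = hba, violations = viol,
         fingerprint = path_fingerprint(mol))
  })
}

batch_logp <- function(mols) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_ligands(mols, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  pr <- ChemmineR::propOB(sdfs)
  as.numeric(pr$logP)
}

#' Molecular-weight window filter
#'
#' Keeps entries with `low <= MW <= high` (both bounds inclusive).
#'
#' @param entries List from [build_library_entries()].
#' @param low,high Window bounds, amu (defaults 300 and 400).
#' @return Filtered entry list, order preserved.
#' @export
mw_window_filter <- function(entries, low = 300, high = 400) {
  Filter(function(e) e$mw >= low && e$mw <= high, entries)
}

#' Rule-of-five compliance filter
#'
#' Keeps entries with at most one Lipinski violation.
#'
#' @param entries Entry list.
#' @param max_violations Maximum violations allowed (default 1).
#' @return Filtered entry list.
#' @export
ro5_filter <- function(entries, max_violations = 1L) {
  Filter(function(e) e$violations <= max_violations, entries)
}

#' Greedy Tanimoto leader clustering
#'
#' In input order, each entry joins the first existing representative
#' whose fingerprint Tanimoto similarity strictly exceeds the cutoff;
#' otherwise it opens a new cluster.  Returns the representatives,
#' deterministic for a fixed input order.
#'
#' @param entries Entry list with fingerprints.
#' @param cutoff Similarity cutoff (default 0.8).
#' @return Representative entries, each with a `cluster_size` field.
#' @export
cluster_by_tanimoto <- function(entries, cutoff = 0.8) {
  reps <- list()
  for (e in entries) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (tanimoto(e$fingerprint, reps[[r]]$fingerprint) > cutoff) {
        reps[[r]]$cluster_size <- reps[[r]]$cluster_size + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      e$cluster_size <- 1L
      reps[[length(reps) + 1L]] <- e
    }
  }
  reps
}

#' Detect hinge hydrogen bonds for a posed ligand
#'
#' Counts complementary donor-acceptor contacts between ligand N/O
#' atoms (donor when bearing a hydrogen, acceptor otherwise) and hinge
#' backbone amide nitrogens (donors) or carbonyl oxygens (acceptors),
#' at heavy-atom distance strictly below the threshold.  Purely a
#' distance criterion — no angle term.
#'
#' @param receptor A `receptor` whose hinge residues are present.
#' @param mol A `ligand_mol`.
#' @param pose Optional `pose_genome` applied first.
#' @param thresholds A [screen_thresholds()].
#' @return List with `count` and `contacts` (data.frame: ligand_atom,
#'   hinge_atom, resno, distance).
#' @export
detect_hinge_hbonds <- function(receptor, mol, pose = NULL,
                                thresholds = screen_thresholds()) {
  hr <- thresholds$hinge_residues
  present <- hr %in% as.integer(names(receptor$residue_index))
  if (!any(present))
    stop("hinge residues absent from receptor: ",
         paste(hr[!present], collapse = ", "))
  if (!is.null(pose)) mol <- apply_pose(mol, pose)
  ra <- receptor$atoms
  hinge_n <- which(ra$resno %in% hr & ra$is_backbone & ra$atom_name == "N")
  hinge_o <- which(ra$resno %in% hr & ra$is_backbone & ra$atom_name == "O")
  el <- mol$atoms$element
  adj <- adjacency(mol)
  lig_no <- which(el %in% c("N", "O"))
  lig_has_h <- vapply(lig_no, function(i) any(el[adj[[i]]] == "H"),
                      logical(1))
  contacts <- data.frame(ligand_atom = integer(0), hinge_atom = integer(0),
                         resno = integer(0), distance = numeric(0))
  lxyz <- coords(mol)
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  add_contacts <- function(lig_idx, rec_idx) {
    for (i in lig_idx) for (j in rec_idx) {
      d <- sqrt(sum((lxyz[i, ] - rxyz[j, ])^2))
      if (d < thresholds$hbond_distance_max)
        contacts[nrow(contacts) + 1L, ] <<- list(i, j, ra$resno[j], d)
    }
  }
  add_contacts(lig_no[lig_has_h], hinge_o)   # ligand donor -> backbone C=O
  add_contacts(lig_no[!lig_has_h], hinge_n)  # ligand acceptor <- backbone N-H
  list(count = nrow(contacts), contacts = contacts)
}

#' Two-track selectivity screen
#'
#' For every molecule: seeded pose optimization and direct rescoring
#' against both the mutant and the wild-type receptor, hinge
#' hydrogen-bond detection on the best mutant-track pose, and the
#' strict-inequality pass rules.  Per-molecule failures are logged and
#' recorded as non-passing; the batch never aborts.  Molecule k of a
#' batch uses seed `seed + k`, so results are independent of batch
#' composition order only through the molecule order itself.
#'
#' @param mols List of `ligand_mol` (e.g. cluster representatives).
#' @param receptor_mut,receptor_wt Prepared receptors.
#' @param params,pair_table,hydration Scoring parameters.
#' @param thresholds A [screen_thresholds()].
#' @param config A [search_config()]; `config$seed` is the batch base
#'   seed.
#' @param maps_mut,maps_wt Optional prebuilt grid maps (built from the
#'   receptor bounding box when omitted).
#' @param box Optional shared `grid_box` for map building.
#' @return data.frame of screen records: id, dg_mut, dg_wt,
#'   hinge_hbonds, pass_energy, pass_hinge, pass, seed, error.
#' @export
two_track_screen <- function(mols, receptor_mut, receptor_wt,
                             params = default_energy_params(),
                             pair_table = default_pair_potentials(),
                             hydration = default_hydration_params(),
                             thresholds = screen_thresholds(),
                             config = search_config(),
                             maps_mut = NULL, maps_wt = NULL, box = NULL) {
  if (is.null(box))
    box <- whole_domain_box(receptor_mut, margin = 4, spacing = 0.75)
  probe_types <- sort(unique(unlist(lapply(mols, function(m)
    m$atoms$atom_type))))
  if (!length(probe_types)) probe_types <- pair_table$types
  if (is.null(maps_mut))
    maps_mut <- build_grid_maps(receptor_mut, box, params, pair_table,
                                probe_types = probe_types)
  if (is.null(maps_wt))
    maps_wt <- build_grid_maps(receptor_wt, box, params, pair_table,
                               probe_types = probe_types)
  rows <- lapply(seq_along(mols), function(k) {
    mol <- mols[[k]]
    seed_k <- config$seed + k
    rec <- list(id = mol$name, dg_mut = NA_real_, dg_wt = NA_real_,
                hinge_hbonds = NA_integer_, pass_energy = FALSE,
                pass_hinge = FALSE, pass = FALSE, seed = seed_k,
                error = "")
    tryCatch({
      cfg <- config; cfg$seed <- seed_k
      d_m <- dock_ligand(mol, receptor_mut, maps_mut, cfg, params,
                         pair_table, hydration, n_refine = 3L,
                         refine_steps = 40L, refine_stages = 3L,
                         n_hops = 2L)
      d_w <- dock_ligand(mol, receptor_wt, maps_wt, cfg, params,
                         pair_table, hydration, n_refine = 3L,
                         refine_steps = 40L, refine_stages = 3L,
                         n_hops = 2L)
      hb <- detect_hinge_hbonds(receptor_mut, mol, d_m$pose, thresholds)
      rec$dg_mut <- d_m$score$total
      rec$dg_wt <- d_w$score$total
      rec$hinge_hbonds <- hb$count
      rec$pass_energy <- (rec$dg_mut < thresholds$dg_mut_max) &&
        (rec$dg_wt > thresholds$dg_wt_min)
      rec$pass_hinge <- hb$count >= thresholds$min_hinge_hbonds
      rec$pass <- rec$pass_energy && rec$pass_hinge
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Apply the pass rules to precomputed screen records
#'
#' Recomputes `pass_energy`, `pass_hinge` and `pass` from `dg_mut`,
#' `dg_wt` and `hinge_hbonds` columns under the strict-inequality
#' rules.  Useful for re-thresholding a finished screen.
#'
#' @param records data.frame with `dg_mut`, `dg_wt`, `hinge_hbonds`.
#' @param thresholds A [screen_thresholds()].
#' @return The records with pass flags filled.
#' @export
apply_screen_rules <- function(records, thresholds = screen_thresholds()) {
  records$pass_energy <- (records$dg_mut < thresholds$dg_mut_max) &
    (records$dg_wt > thresholds$dg_wt_min)
  records$pass_hinge <- records$hinge_hbonds >= thresholds$min_hinge_hbonds
  records$pass <- records$pass_energy & records$pass_hinge
  records
}

#' Run the full library funnel
#'
#' Library filtration (molecular-weight window, rule-of-five, Tanimoto
#' leader clustering) followed by the two-track screen of the cluster
#' representatives.  Stage survivor counts are returned alongside the
#' screen records.
#'
#' @param mols List of `ligand_mol` (a parsed library).
#' @param receptor_mut,receptor_wt Prepared receptors.
#' @param mw_low,mw_high Molecular-weight window, amu.
#' @param tanimoto_cutoff Clustering cutoff.
#' @param ... Passed to [two_track_screen()].
#' @return List with `funnel` (named stage counts), `records`
#'   (data.frame), `representatives` (entry list).
#' @export
screen_library <- function(mols, receptor_mut, receptor_wt,
                           mw_low = 300, mw_high = 400,
                           tanimoto_cutoff = 0.8, ...) {
  entries <- build_library_entries(mols)
  e_mw <- mw_window_filter(entries, mw_low, mw_high)
  e_ro5 <- ro5_filter(e_mw)
  reps <- cluster_by_tanimoto(e_ro5, tanimoto_cutoff)
  records <- two_track_screen(lapply(reps, `[[`, "mol"),
                              receptor_mut, receptor_wt, ...)
  funnel <- c(library = length(entries), mw_window = length(e_mw),
              ro5 = length(e_ro5), cluster = length(reps),
              energy = sum(records$pass_energy, na.rm = TRUE),
              hinge = sum(records$pass, na.rm = TRUE))
  list(funnel = funnel, records = records, representatives = reps)
}
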