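#' De novo design configuration
#'
#' @param max_sites Maximum substitution positions (default 2).
#' @param selectivity_gap_min Minimum mutant-over-wild-type binding free
#'   energy difference, kcal/mol (default 5.0; strict inequality).
#' @param max_ro5_violations Bioavailability rule: maximum Lipinski
#'   violations for a derivative to survive the prefilter.
#' @return A `denovo_config` list.
#' @export
denovo_config <- function(max_sites = 2L, selectivity_gap_min = 5.0,
                          max_ro5_violations = 1L) {
  stopifnot(max_sites >= 1, selectivity_gap_min >= 0)
  list(max_sites = as.integer(max_sites),
       selectivity_gap_min = selectivity_gap_min,
       max_ro5_violations = as.integer(max_ro5_violations))
}

# remove atom `idx`, reindexing bonds; returns list(mol-parts, map)
drop_atom <- function(atoms, bonds, idx) {
  keep <- setdiff(seq_len(nrow(atoms)), idx)
  map <- integer(nrow(atoms))
  map[keep] <- seq_along(keep)
  bonds <- bonds[bonds$i != idx & bonds$j != idx, , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  list(atoms = atoms[keep, , drop = FALSE], bonds = bonds, map = map)
}

# attach fragment to core at heavy atom `site`: one H leaves each side,
# a single bond joins site to the fragment's first heavy atom
graft_fragment <- function(core, site, frag) {
  el <- core$atoms$element
  adj <- adjacency(core)
  hs <- adj[[site]][el[adj[[site]]] == "H"]
  if (!length(hs)) return(NULL)  # no free valence
  fa <- which(frag$atoms$element != "H")[1]
  fadj <- adjacency(frag)
  fhs <- fadj[[fa]][frag$atoms$element[fadj[[fa]]] == "H"]
  if (!length(fhs)) return(NULL)
  c1 <- drop_atom(core$atoms, core$bonds, min(hs))
  f1 <- drop_atom(frag$atoms, frag$bonds, min(fhs))
  off <- nrow(c1$atoms)
  f1$bonds$i <- f1$bonds$i + off
  f1$bonds$j <- f1$bonds$j + off
  atoms <- rbind(c1$atoms[, c("element", "x", "y", "z")],
                 f1$atoms[, c("element", "x", "y", "z")])
  # displace fragment far from the core; geometry is rebuilt afterwards
  atoms[(off + 1):nrow(atoms), c("x", "y", "z")] <-
    atoms[(off + 1):nrow(atoms), c("x", "y", "z")] + 50
  bonds <- rbind(c1$bonds[, c("i", "j", "order")],
                 f1$bonds[, c("i", "j", "order")],
                 data.frame(i = c1$map[site], j = fa + off, order = 1L))
  list(atoms = atoms, bonds = bonds, site_map = c1$map)
}

#' Enumerate substituted derivatives of a core
#'
#' Deterministic exhaustive enumeration: every combination of (fragment
#' or unmodified hydrogen) at each substitution site, minus the parent,
#' giving `(f+1)^s - 1` raw derivatives for `f` fragments and `s`
#' sites.  Each raw derivative is canonicalized (SMILES) for
#' de-duplication, then rebuilt in 3D with explicit hydrogens, typed and
#' charged.  Fragments attach through their first heavy atom, which
#' must carry at least one hydrogen; a site without a free valence
#' skips that combination with a log entry.
#'
#' @param core A `ligand_mol`.
#' @param sites Integer vector of core heavy-atom indices (labelled R1,
#'   R2, ... in enumeration order); at most `config$max_sites`.
#' @param fragments Character vector of fragment SMILES (first heavy
#'   atom = attachment point) or list of `ligand_mol`.
#' @param config A [denovo_config()].
#' @return List: `derivatives` (de-duplicated `ligand_mol` list, each
#'   with a `provenance` attribute), `n_enumerated` (count before
#'   de-duplication), `skipped` (valence-violation log).
#' @export
enumerate_derivatives <- function(core, sites, fragments,
                                  config = denovo_config()) {
  stopifnot(length(sites) >= 1, length(sites) <= config$max_sites)
  if (is.character(fragments)) {
    frag_names <- if (!is.null(names(fragments))) names(fragments)
                  else fragments
    fragments <- parse_fragment_smiles(fragments)
    for (k in seq_along(fragments)) fragments[[k]]$name <- frag_names[k]
  }
  if (!length(fragments))
    return(list(derivatives = list(), n_enumerated = 0L,
                skipped = character(0)))
  f <- length(fragments)
  choice <- expand.grid(rep(list(0:f), length(sites)))
  choice <- choice[rowSums(choice) > 0, , drop = FALSE]  # drop parent
  raw <- list(); skipped <- character(0)
  for (r in seq_len(nrow(choice))) {
    atoms <- core$atoms; bonds <- core$bonds
    cur <- list(atoms = atoms, bonds = bonds)
    map <- seq_len(nrow(atoms))
    ok <- TRUE; tags <- character(0)
    for (s in seq_along(sites)) {
      ci <- choice[r, s]
      if (ci == 0) next
      g <- graft_fragment(
        structure(list(atoms = cur$atoms, bonds = cur$bonds),
                  class = "ligand_mol"),
        map[sites[s]], fragments[[ci]])
      if (is.null(g)) {
        ok <- FALSE
        skipped <- c(skipped, sprintf("combo %d: no free valence at R%d",
                                      r, s))
        break
      }
      map <- g$site_map[map]
      cur <- g
      tags <- c(tags, sprintf("R%d=%s", s, fragments[[ci]]$name))
    }
    if (!ok) next
    nm <- paste0(core$name, "|", paste(tags, collapse = ","))
    raw[[length(raw) + 1L]] <-
      ligand_mol(cur$atoms, cur$bonds, name = nm)
  }
  n_enumerated <- length(raw)
  if (!n_enumerated)
    return(list(derivatives = list(), n_enumerated = 0L, skipped = skipped))
  # canonical SMILES de-duplication, then deterministic 3D rebuild
  smi <- canonical_smiles(raw)
  keep <- !duplicated(smi)
  kept <- raw[keep]; smi <- smi[keep]
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste(smi, vapply(kept, `[[`, "", "name")), tmp)
  derivs <- read_ligands(tmp)
  for (k in seq_along(derivs))
    attr(derivs[[k]], "provenance") <- derivs[[k]]$name
  list(derivatives = derivs, n_enumerated = n_enumerated, skipped = skipped)
}

parse_fragment_smiles <- function(smiles) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(smiles, tmp)
  read_ligands(tmp)
}

#' Canonical SMILES of molecules
#'
#' @param mols List of `ligand_mol`.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(mols) {
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".smi")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_ligands(mols, tmp_in)
  run_obabel(c(shQuote(tmp_in), "-ocan", "-O", shQuote(tmp_out)))
  lines <- readLines(tmp_out, warn = FALSE)
  vapply(strsplit(lines, "[ \t]"), `[[`, "", 1)
}

dock_and_rescore <- function(mol, receptor, maps, config, params,
                             pair_table, hydration) {
  dock_ligand(mol, receptor, maps, config, params, pair_table, hydration,
              n_refine = 3L, refine_steps = 40L, refine_stages = 3L,
              n_hops = 2L)
}

#' Gas-phase empirical prefilter of derivatives
#'
#' Docks each derivative against the mutant receptor and keeps those
#' whose gas-phase score — the scoring function without the dehydration
#' term — is strictly better (lower) than the parent's, and whose
#' rule-of-five profile passes the bioavailability rule.  Order
#' preserving and idempotent.
#'
#' @param derivatives List of `ligand_mol`.
#' @param parent The hit compound (`ligand_mol`).
#' @param receptor_mut Mutant receptor.
#' @param maps Grid maps for the mutant (built if NULL).
#' @param config A [search_config()]; derivative k uses seed
#'   `config$seed + k`.
#' @param params,pair_table,hydration Scoring parameters.
#' @param dn_config A [denovo_config()].
#' @return List: `kept` (molecule list), `table` (data.frame of
#'   gas-phase scores), `parent_gas` (the parent's gas-phase score).
#' @export
empirical_prefilter <- function(derivatives, parent, receptor_mut,
                                maps = NULL, config = search_config(),
                                params = default_energy_params(),
                                pair_table = default_pair_potentials(),
                                hydration = default_hydration_params(),
                                dn_config = denovo_config()) {
  if (is.null(maps)) {
    box <- whole_domain_box(receptor_mut, margin = 4, spacing = 0.75)
    maps <- build_grid_maps(receptor_mut, box, params, pair_table)
  }
  gas <- function(sb) sb$total - sb$e_dehydration
  p <- dock_and_rescore(parent, receptor_mut, maps, config, params,
                        pair_table, hydration)
  parent_gas <- gas(p$score)
  rows <- list(); kept <- list()
  for (k in seq_along(derivatives)) {
    mol <- derivatives[[k]]
    cfg <- config; cfg$seed <- config$seed + k
    d <- dock_and_rescore(mol, receptor_mut, maps, cfg, params,
                          pair_table, hydration)
    g <- gas(d$score)
    viol <- ro5_profile(mol)$violations
    keep <- (g < parent_gas) && (viol <= dn_config$max_ro5_violations)
    rows[[k]] <- data.frame(id = mol$name, gas_score = g,
                            ro5_violations = viol, kept = keep)
    if (keep) kept[[length(kept) + 1L]] <- mol
  }
  list(kept = kept, table = do.call(rbind, rows), parent_gas = parent_gas)
}

#' Two-track selection of derivatives by selectivity gap
#'
#' Full scoring (with the dehydration term) against both receptors;
#' keeps candidates binding more tightly to the mutant than the wild
#' type with a gap strictly larger than `selectivity_gap_min`, ranked
#' by mutant-track energy ascending.
#'
#' @param candidates List of `ligand_mol`.
#' @param receptor_mut,receptor_wt Prepared receptors.
#' @param maps_mut,maps_wt Optional prebuilt grid maps.
#' @param config A [search_config()].
#' @param params,pair_table,hydration Scoring parameters.
#' @param dn_config A [denovo_config()].
#' @return data.frame: id, dg_mut, dg_wt, gap, selected — selected rows
#'   first, ranked by dg_mut.
#' @export
two_track_select <- function(candidates, receptor_mut, receptor_wt,
                             maps_mut = NULL, maps_wt = NULL,
                             config = search_config(),
                             params = default_energy_params(),
                             pair_table = default_pair_potentials(),
                             hydration = default_hydration_params(),
                             dn_config = denovo_config()) {
  if (is.null(maps_mut) || is.null(maps_wt)) {
    box <- whole_domain_box(receptor_mut, margin = 4, spacing = 0.75)
    if (is.null(maps_mut))
      maps_mut <- build_grid_maps(receptor_mut, box, params, pair_table)
    if (is.null(maps_wt))
      maps_wt <- build_grid_maps(receptor_wt, box, params, pair_table)
  }
  rows <- lapply(seq_along(candidates), function(k) {
    mol <- candidates[[k]]
    cfg <- config; cfg$seed <- config$seed + k
    m <- dock_and_rescore(mol, receptor_mut, maps_mut, cfg, params,
                          pair_table, hydration)
    w <- dock_and_rescore(mol, receptor_wt, maps_wt, cfg, params,
                          pair_table, hydration)
    data.frame(id = mol$name, dg_mut = m$score$total, dg_wt = w$score$total,
               gap = w$score$total - m$score$total)
  })
  apply_gap_rule(do.call(rbind, rows), dn_config)
}

#' Apply the selectivity-gap selection rule
#'
#' Marks candidates selected when they bind the mutant more tightly than
#' the wild type (`dg_mut < dg_wt`) with a gap strictly larger than the
#' configured minimum, and ranks selected rows first by `dg_mut`
#' ascending.
#'
#' @param df data.frame with columns `dg_mut`, `dg_wt` (and optionally
#'   `gap`, recomputed here).
#' @param dn_config A [denovo_config()].
#' @return The data.frame with `gap` and `selected` columns, reordered.
#' @export
apply_gap_rule <- function(df, dn_config = denovo_config()) {
  df$gap <- df$dg_wt - df$dg_mut
  df$selected <- df$dg_mut < df$dg_wt &
    df$gap > dn_config$selectivity_gap_min
  df[order(!df$selected, df$dg_mut), , drop = FALSE]
}
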