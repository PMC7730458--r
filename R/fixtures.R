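#' Specification for deterministic synthetic fixtures
#'
#' Every fixture is a pure function of its spec: the same spec yields
#' byte-identical receptors, libraries and ground-truth tables.
#'
#' @param seed Integer seed for library composition shuffling.
#' @param n_library Total library size.
#' @param n_out Molecules outside the 300-400 amu window.
#' @param n_viol In-window molecules violating the rule of five.
#' @param copies Planted near-duplicate cluster size for in-window
#'   molecules (exact duplicates, Tanimoto 1).
#' @param mutation Apply the mutant-vs-wild-type atom swaps (gatekeeper
#'   polar-to-nonpolar at residue 790, thiol-to-hydroxyl at 797).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_library = 200L, n_out = 50L,
                         n_viol = 30L, copies = 6L, mutation = TRUE) {
  n_in <- n_library - n_out - n_viol
  stopifnot(n_in > 0, n_in %% copies == 0)
  list(seed = as.integer(seed), n_library = as.integer(n_library),
       n_out = as.integer(n_out), n_viol = as.integer(n_viol),
       copies = as.integer(copies), n_in = as.integer(n_in),
       mutation = isTRUE(mutation))
}

hinge_x <- function(resno) (resno - 791) * 3.8

fixture_atom <- function(element, name, resno, resname, x, y, z, charge,
                         backbone = FALSE) {
  data.frame(element = element, atom_name = name, resno = resno,
             resname = resname, chain = "A", x = x, y = y, z = z,
             charge = charge, is_backbone = backbone,
             stringsAsFactors = FALSE)
}

# five-residue hinge mimic with the alternating exposure of real kinase
# hinges: residue 793's amide N-H and residue 791's carbonyl C=O point
# into the pocket (-y); all other polar backbone groups face away
hinge_block <- function() {
  rows <- list()
  for (r in 791:795) {
    x <- hinge_x(r)
    h <- if (r == 793) c(x, -0.95, 0.35) else c(x, 0.70, -0.68)
    o <- if (r == 791) c(x + 2.2, -1.05, 0.25) else c(x + 2.2, 0.60, 1.10)
    hq <- if (r == 793) 0.40 else 0.25
    oq <- if (r == 791) -0.60 else -0.50
    rows[[length(rows) + 1L]] <- rbind(
      fixture_atom("N", "N", r, "HNG", x, 0.00, 0.00, -0.35, TRUE),
      fixture_atom("H", "H", r, "HNG", h[1], h[2], h[3], hq, TRUE),
      fixture_atom("C", "CA", r, "HNG", x + 1.0, 0.80, 0.00, 0.05, TRUE),
      fixture_atom("C", "C", r, "HNG", x + 2.2, 0.15, 0.00, 0.50, TRUE),
      fixture_atom("O", "O", r, "HNG", o[1], o[2], o[3], oq, TRUE))
  }
  do.call(rbind, rows)
}

# nonpolar pocket lining below the hinge (Gly-loop / interdomain mimic):
# a complementary carbon cage near the 12-6 equilibrium distance from
# the planted-binder heavy atoms, on the face away from the hinge, so
# the construction pose sits at the engineered energy minimum
pocket_block <- function() {
  pts <- cbind(
    x = c(10.440, 7.600, 4.900, 4.900, 3.550, 1.550, -0.640, 2.200,
          2.200, 6.600, 9.440, 6.600, 6.600, 5.300),
    y = c(-5.560, -5.560, -6.240, -6.240, -7.650, -7.130, -6.630, -6.630,
          -6.630, -8.600, -7.440, -7.440, -7.440, -1.500),
    z = c(1.000, 3.840, 3.740, -1.940, 0.850, 0.850, 0.810, 3.650,
          -2.030, 0.600, 0.600, 3.440, -2.240, 3.800))
  do.call(rbind, lapply(seq_len(nrow(pts)), function(k) {
    fixture_atom("C", "CB", 717L + k, "POC",
                 pts[k, 1], pts[k, 2], pts[k, 3], 0.02)
  }))
}

# the two mutation-site atoms (wild type vs triple-mutant mimic):
# residue 790 polar hydroxyl (wt) -> nonpolar carbon (mut);
# residue 797 thiol sulfur (wt) -> hydroxyl oxygen (mut)
mutation_block <- function(mutant) {
  g_el <- if (mutant) "C" else "O"
  g_q <- if (mutant) 0.02 else -0.40
  gh_q <- if (mutant) 0.03 else 0.40
  s_el <- if (mutant) "O" else "S"
  s_q <- if (mutant) -0.40 else -0.15
  sh_q <- if (mutant) 0.40 else 0.15
  rbind(
    fixture_atom(g_el, "OG1", 790L, "GTK", 7.0, -7.0, 2.8, g_q),
    fixture_atom("H", "HG1", 790L, "GTK", 7.0, -6.1, 3.1, gh_q),
    fixture_atom(s_el, "SG", 797L, "CYS", 3.5, -6.8, -2.5, s_q),
    fixture_atom("H", "HG", 797L, "CYS", 3.5, -5.9, -2.2, sh_q))
}

assemble_receptor <- function(atoms, hinge_residues = 791:795) {
  atoms$serial <- seq_len(nrow(atoms))
  atoms$atom_type <- receptor_atom_types(atoms)
  atoms <- atoms[, c("serial", "element", "atom_name", "resno", "resname",
                     "chain", "x", "y", "z", "charge", "is_backbone",
                     "atom_type")]
  res <- split(seq_len(nrow(atoms)), atoms$resno)
  structure(list(atoms = atoms, residue_index = res,
                 hinge_residues = intersect(hinge_residues,
                                            as.integer(names(res))),
                 pocket_center = c(5.5, -4.5, 0.5)),
            class = "receptor")
}

#' Build the synthetic mutant / wild-type receptor pair
#'
#' Two toy kinase-pocket receptors, atom-for-atom identical except at
#' the two designated mutation-site atoms when `spec$mutation` is on: a
#' polar-for-nonpolar swap at the gatekeeper position (residue 790) and
#' a thiol-for-hydroxyl swap at residue 797.  Both carry the
#' five-residue hinge mimic numbered 791-795 with exposed backbone N-H
#' and C=O groups, and a nonpolar pocket lining.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `mut` and `wt`, both `receptor` objects.
#' @export
make_receptor_pair <- function(spec = fixture_spec()) {
  base <- rbind(hinge_block(), pocket_block())
  mut <- assemble_receptor(rbind(base, mutation_block(spec$mutation)))
  wt <- assemble_receptor(rbind(base, mutation_block(FALSE)))
  list(mut = mut, wt = wt)
}

planted_binder_atoms <- function() {
  # N1 accepts from the 793 backbone N-H; O5-H6 donates to the 791
  # carbonyl O; an sp2 chain spans the two, with a methyl dipping into
  # the nonpolar pocket
  list(
    atoms = data.frame(
      element = c("N", "C", "C", "C", "O", "H", "C", "H", "H", "H"),
      x = c(7.811, 6.540, 5.154, 3.820, 2.480, 2.455, 6.920, 6.649, 5.104,
            3.795),
      y = c(-2.724, -3.221, -3.450, -3.727, -3.897, -2.939, -4.480, -5.436,
            -2.513, -4.756),
      z = c(1.113, 0.874, 0.698, 0.524, 0.379, 0.348, 0.208, 0.262, 1.035,
            0.600),
      charge = c(-0.45, 0.15, 0.00, 0.05, -0.50, 0.45, 0.03, 0.05, 0.05,
                 0.05)),
    bonds = data.frame(
      i = c(1, 2, 3, 4, 5, 2, 7, 3, 4),
      j = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
      order = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  )
}

#' Build the planted hinge binder and its construction pose
#'
#' A small rigid ligand whose acceptor nitrogen sits 2.9 A from the
#' backbone amide nitrogen of residue 793 and whose hydroxyl donor sits
#' within 3 A of the carbonyl oxygen of residue 791, so that two hinge
#' hydrogen bonds are satisfied at the construction pose.  Gasteiger
#' charges are deliberately not reassigned: the fixture's hand-set
#' charges are part of its ground truth.
#'
#' @param receptor A receptor from [make_receptor_pair()] (used only to
#'   record the expected pose region).
#' @param spec A [fixture_spec()].
#' @return List: `mol` (the binder, already at its construction pose),
#'   `expected_center` (its centroid), `pose_radius` (how far a search
#'   result may drift and still count as recovered, A).
#' @export
make_planted_binder <- function(receptor, spec = fixture_spec()) {
  pb <- planted_binder_atoms()
  mol <- ligand_mol(pb$atoms, pb$bonds, name = "planted_binder")
  mol$atoms$charge <- pb$atoms$charge
  list(mol = mol, expected_center = colMeans(coords(mol)),
       pose_radius = 1.0)
}

#' An apolar decoy ligand of the same size
#'
#' Same scaffold as the planted binder with every polar atom replaced
#' by carbon: no hinge hydrogen bonds are possible.
#'
#' @return A `ligand_mol`.
#' @export
make_apolar_decoy <- function() {
  pb <- planted_binder_atoms()
  a <- pb$atoms
  a$element[a$element %in% c("N", "O")] <- "C"
  a$charge <- ifelse(a$element == "H", 0.01, 0.0)
  mol <- ligand_mol(a, pb$bonds, name = "apolar_decoy")
  mol$atoms$charge <- a$charge
  mol
}

read_library_pool <- function() {
  path <- system.file("extdata", "library_pool.tsv",
                      package = "selectiscreen")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Generate a synthetic compound library with ground truth
#'
#' Draws from the curated pool shipped with the package: `n_in`
#' in-window rule-of-five-compliant molecules (as exact-duplicate
#' clusters of `spec$copies`, so Tanimoto leader clustering must
#' collapse each cluster to one representative), `n_out` molecules
#' outside the 300-400 amu window, and `n_viol` in-window molecules
#' with at least two Lipinski violations.  The entry order is shuffled
#' with `spec$seed`.  The ground-truth table makes every funnel stage's
#' survivor count computable in advance.
#'
#' @param spec A [fixture_spec()].
#' @param smiles_path Output SMILES file (one `SMILES id` per line).
#' @param truth_path Optional output TSV for the ground-truth table.
#' @return Invisibly, a list: `truth` (data.frame: id, smiles, pool,
#'   cluster_id, expected columns), `expected` (named funnel counts).
#' @export
make_library <- function(spec = fixture_spec(), smiles_path,
                         truth_path = NULL) {
  pool <- read_library_pool()
  p_in <- pool[pool$pool == "in", , drop = FALSE]
  p_out <- pool[pool$pool == "out", , drop = FALSE]
  p_viol <- pool[pool$pool == "viol", , drop = FALSE]
  n_uni <- spec$n_in %/% spec$copies
  stopifnot(n_uni <= nrow(p_in), spec$n_out <= nrow(p_out) * 50,
            spec$n_viol <= nrow(p_viol) * 50)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  sel_in <- p_in[sample.int(nrow(p_in), n_uni), , drop = FALSE]
  rows <- list()
  for (k in seq_len(n_uni)) {
    for (cpy in seq_len(spec$copies)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("IN%03d_c%d", k, cpy), smiles = sel_in$smiles[k],
        pool = "in", cluster_id = sprintf("CL%03d", k))
    }
  }
  for (k in seq_len(spec$n_out)) {
    src <- p_out[(k - 1L) %% nrow(p_out) + 1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("OUT%03d", k), smiles = src$smiles, pool = "out",
      cluster_id = NA_character_)
  }
  for (k in seq_len(spec$n_viol)) {
    src <- p_viol[(k - 1L) %% nrow(p_viol) + 1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("VIO%03d", k), smiles = src$smiles, pool = "viol",
      cluster_id = NA_character_)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
  rownames(truth) <- NULL
  writeLines(paste(truth$smiles, truth$id), smiles_path)
  expected <- c(library = nrow(truth),
                mw_window = sum(truth$pool %in% c("in", "viol")),
                ro5 = sum(truth$pool == "in"),
                cluster = n_uni)
  if (!is.null(truth_path)) {
    out <- truth
    out$expected_mw_window <- out$pool %in% c("in", "viol")
    out$expected_ro5 <- out$pool == "in"
    utils::write.table(out, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(truth = truth, expected = expected))
}
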