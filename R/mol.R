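#' Construct a ligand molecule
#'
#' The ligand container used throughout the package: a typed, charged
#' all-atom topology with 3D coordinates.  Atom types follow a compact
#' docking-style scheme (see [assign_atom_types()]); partial charges are
#' Gasteiger-Marsili PEOE charges in units of the elementary charge.
#'
#' @param atoms data.frame with columns `serial`, `element`, `x`, `y`,
#'   `z`, and optionally `atom_type`, `charge`, `formal_charge`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3; use 1
#'   for the kekulized rendering of aromatic bonds) and optionally
#'   `in_ring`.
#' @param name Identifier carried through pipelines.
#' @param retype If `TRUE` (default), perceive rings and (re)assign atom
#'   types and rotatable-bond count.
#' @return An object of class `ligand_mol` with elements `atoms`,
#'   `bonds`, `n_tor`, `formula`, `name`.
#' @export
ligand_mol <- function(atoms, bonds, name = "mol", retype = TRUE) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (nrow(bonds)) {
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1L
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond indices out of range")
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  mol <- structure(list(atoms = atoms, bonds = bonds, name = name),
                   class = "ligand_mol")
  if (retype) {
    mol$bonds$in_ring <- perceive_ring_bonds(mol)
    mol$atoms$atom_type <- assign_atom_types(mol)
    mol$n_tor <- count_rotatable_bonds(mol)
  } else {
    if (is.null(mol$bonds$in_ring))
      mol$bonds$in_ring <- logical(nrow(mol$bonds))
    mol$n_tor <- mol$n_tor %||% 0L
  }
  mol$formula <- mol_formula(mol)
  mol
}

#' @export
print.ligand_mol <- function(x, ...) {
  cat(sprintf("<ligand_mol '%s': %d atoms, %d bonds, N_tor = %d, %s>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$n_tor,
              format_formula(x$formula)))
  invisible(x)
}

#' Coordinates of a molecule as an n x 3 matrix
#' @param mol A `ligand_mol` or receptor.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Molecular formula of a molecule's atom list
#' @param mol A `ligand_mol`.
#' @return A `molecular_formula`.
#' @export
mol_formula <- function(mol) {
  tab <- table(mol$atoms$element)
  new_formula(stats::setNames(as.integer(tab), names(tab)),
              sum(mol$atoms$formal_charge %||% 0L))
}

# adjacency list of heavy+H graph
adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# ring membership per bond: an edge is in a ring iff it is not a bridge
perceive_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(
    cbind(mol$bonds$i, mol$bonds$j), directed = FALSE)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

#' Assign docking-style atom types
#'
#' A finite typing scheme distinguishing the interaction classes the
#' energy model needs: `C` aliphatic carbon, `A` aromatic/sp2 ring
#' carbon, `N` nitrogen bearing a hydrogen (donor heavy atom), `NA`
#' nitrogen without hydrogens (acceptor), `OA` oxygen (acceptor), `SA`
#' sulfur, `HD` hydrogen bonded to N/O/S (donatable), `H` carbon-bound
#' hydrogen, and the halogens `F`, `Cl`, `Br`, `I`.  Phosphorus maps to
#' `P`, boron and silicon to `C` (rare, treated as generic heavy atoms).
#'
#' @param mol A `ligand_mol` (ring perception already done).
#' @return Character vector of type codes, one per atom.
#' @export
assign_atom_types <- function(mol) {
  el <- mol$atoms$element
  n <- length(el)
  adj <- adjacency(mol)
  has_h <- vapply(seq_len(n), function(i) any(el[adj[[i]]] == "H"), logical(1))
  # per-atom: any ring bond of order >= 2 => aromatic-like sp2 ring carbon
  ring_sp2 <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    sel <- mol$bonds$in_ring & mol$bonds$order >= 2
    ring_at <- unique(c(mol$bonds$i[mol$bonds$in_ring],
                        mol$bonds$j[mol$bonds$in_ring]))
    sp2_at <- unique(c(mol$bonds$i[sel], mol$bonds$j[sel]))
    ring_sp2[intersect(ring_at, sp2_at)] <- TRUE
  }
  vapply(seq_len(n), function(i) {
    e <- el[i]
    switch(e,
      H = {
        nb <- adj[[i]]
        if (length(nb) && any(el[nb] %in% c("N", "O", "S"))) "HD" else "H"
      },
      C = if (ring_sp2[i]) "A" else "C",
      N = if (has_h[i]) "N" else "NA",
      O = "OA",
      S = "SA",
      P = "P",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      B = "C", Si = "C",
      stop("no atom type rule for element '", e, "'")
    )
  }, character(1))
}

#' Count rotatable bonds
#'
#' A bond is rotatable when it is an acyclic single bond between two
#' heavy atoms that are both non-terminal (each has at least one further
#' heavy-atom neighbour), excluding amide C-N bonds.  Bonds whose
#' rotation moves only hydrogens (terminal -CH3, -NH2, -OH) are excluded
#' by the non-terminal rule.
#'
#' @param mol A `ligand_mol`.
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  length(rotatable_bonds(mol))
}

#' Identify rotatable bonds and their moving atom sets
#'
#' @param mol A `ligand_mol`.
#' @return List of lists with elements `i`, `j` (atom indices of the
#'   rotation axis) and `moving` (indices of atoms displaced when the
#'   torsion turns; the side not containing atom 1).
#' @export
rotatable_bonds <- function(mol) {
  el <- mol$atoms$element
  adj <- adjacency(mol)
  heavy_deg <- vapply(seq_along(el), function(i)
    sum(el[adj[[i]]] != "H"), integer(1))
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 1L || b$in_ring) next
    i <- b$i; j <- b$j
    if (el[i] == "H" || el[j] == "H") next
    # non-terminal: each end bonded to >= 2 heavy atoms (incl. the other end)
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next
    if (is_amide_cn(mol, i, j, adj)) next
    moving <- component_excluding(adj, start = j, cut_i = i, cut_j = j)
    if (1L %in% moving) {
      moving <- component_excluding(adj, start = i, cut_i = j, cut_j = i)
      axis <- c(j, i)
    } else axis <- c(i, j)
    out[[length(out) + 1L]] <-
      list(i = axis[1], j = axis[2], moving = setdiff(moving, axis[2]))
  }
  out
}

# amide C-N: C double-bonded to O on one end, N on the other
is_amide_cn <- function(mol, i, j, adj) {
  el <- mol$atoms$element
  pair <- c(i, j)
  cc <- pair[el[pair] == "C"]
  nn <- pair[el[pair] == "N"]
  if (length(cc) != 1L || length(nn) != 1L) return(FALSE)
  dbl_o <- with(mol$bonds,
    (i == cc & order == 2L & el[j] == "O") |
    (j == cc & order == 2L & el[i] == "O"))
  any(dbl_o)
}

# BFS from `start` over the graph with edge (cut_i, cut_j) removed
component_excluding <- function(adj, start, cut_i, cut_j) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (v == cut_i && w == cut_j) next
      if (v == cut_j && w == cut_i) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}
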