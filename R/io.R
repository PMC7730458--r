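run_obabel <- function(args) {
  out <- suppressWarnings(
    system2("obabel", args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("obabel failed (exit ", status, "): ", paste(out, collapse = "\n"))
  out
}

#' Read a ligand library from SMILES or SDF
#'
#' SMILES files (one molecule per line, optional whitespace-separated id)
#' are embedded in 3D with explicit hydrogens by ETKDG distance geometry
#' under a fixed per-molecule random seed followed by an MMFF94
#' relaxation, so the same input and seed always yield the same
#' coordinates.  SDF input is taken as given; molecules without explicit
#' hydrogens or without 3D coordinates are rebuilt the same way.  Every
#' molecule is ring-perceived, atom-typed and given Gasteiger partial
#' charges.  Unparsable entries are skipped with a warning.
#'
#' @param path Path to a `.smi`/`.smiles` or `.sdf` file.
#' @param embed_seed Integer seed for the distance-geometry embedding.
#' @return List of [ligand_mol()] objects (possibly empty).
#' @export
read_ligands <- function(path, embed_seed = 1L) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(list())
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    n_conv <- run_embed3d(path, tmp, embed_seed)
    if (n_conv < length(lines))
      warning(length(lines) - n_conv, " SMILES entr",
              if (length(lines) - n_conv == 1) "y" else "ies",
              " could not be parsed/embedded and were skipped")
    if (n_conv == 0L) return(list())
    sdf_to_mols(tmp, embed_seed)
  } else if (ext == "sdf") {
    sdf_to_mols(path, embed_seed)
  } else stop("unsupported ligand file extension: '", ext, "'")
}

# ETKDG + MMFF94 embedding via the packaged RDKit helper; returns the
# number of molecules successfully embedded
run_embed3d <- function(in_path, out_path, seed = 1L) {
  script <- system.file("scripts", "embed3d.py", package = "selectiscreen")
  if (!nzchar(script)) stop("embed3d.py helper not found in package")
  out <- suppressWarnings(system2("python",
    c(shQuote(script), shQuote(in_path), shQuote(out_path),
      as.integer(seed)), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("3D embedding failed (exit ", status, "): ",
         paste(out, collapse = "\n"))
  m <- regmatches(out, regexec("^([0-9]+) of ([0-9]+) embedded", out))
  for (x in m) if (length(x) == 3) return(as.integer(x[2]))
  0L
}

sdf_to_mols <- function(path, embed_seed = 1L) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfs) == 0L) return(list())
  ok <- ChemmineR::validSDF(sdfs)
  if (any(!ok))
    warning(sum(!ok), " invalid SDF record(s) skipped")
  sdfs <- sdfs[ok]
  mols <- lapply(seq_along(ChemmineR::cid(sdfs)), function(k) {
    sdf_record_to_mol(sdfs[[k]])
  })
  # rebuild molecules lacking explicit H or 3D coordinates
  needs_fix <- vapply(mols, function(m) {
    !any(m$atoms$element == "H") || all(abs(m$atoms$z) < 1e-8)
  }, logical(1))
  if (any(needs_fix)) {
    tmp_in <- tempfile(fileext = ".sdf"); tmp_out <- tempfile(fileext = ".sdf")
    on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
    write_ligands(mols[needs_fix], tmp_in)
    run_embed3d(tmp_in, tmp_out, embed_seed)
    fixed <- sdf_to_mols_raw(tmp_out)
    if (length(fixed) == sum(needs_fix)) mols[needs_fix] <- fixed
  }
  lapply(mols, assign_gasteiger_charges)
}

sdf_to_mols_raw <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  lapply(seq_along(ChemmineR::cid(sdfs)), function(k)
    sdf_record_to_mol(sdfs[[k]]))
}

sdf_record_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(
    serial = seq_len(nrow(ab)), element = el,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    row.names = NULL)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = pmin(as.integer(bb[, 3]), 3L))
  }
  nm <- ChemmineR::sdfid(sdf)
  if (is.null(nm) || !nzchar(nm)) nm <- "mol"
  ligand_mol(atoms, bonds, name = nm)
}

#' Write ligands to an SDF (V2000) file
#'
#' @param mols List of `ligand_mol` objects.
#' @param path Output path.
#' @param fields Optional named list (per molecule) of extra SDF data
#'   fields, e.g. score breakdowns; or a function(mol) returning one.
#' @export
write_ligands <- function(mols, path, fields = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    writeLines(mol_to_sdf_text(mol), con)
    fl <- if (is.function(fields)) fields(mol) else fields[[k]]
    for (nm in names(fl)) {
      writeLines(sprintf("> <%s>", nm), con)
      writeLines(as.character(fl[[nm]]), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

mol_to_sdf_text <- function(mol) {
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  hdr <- c(mol$name, " selectiscreen          3D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element)
  bd <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        mol$bonds$i, mol$bonds$j, mol$bonds$order)
        else character(0)
  c(hdr, at, bd, "M  END")
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, keeping residue numbers
#' verbatim.  Waters and hetero groups are excluded by default.  Since
#' PDB files carry no bond table, hydrogen typing is geometric: an H
#' within 1.25 A of an N/O/S is a donatable `HD`.  Partial charges come
#' from a per-element template, or — for synthetic receptors written by
#' this package — verbatim from the B-factor column.
#'
#' @param path PDB file path.
#' @param keep_hetero Keep HETATM records (waters always dropped).
#' @param charge_scheme `"template"` (element-based defaults) or
#'   `"bfactor"` (read partial charges from the B-factor column, the
#'   convention used by the fixture writer).
#' @param hinge_residues Residue numbers annotated as the hinge
#'   (default 791:795, mature-protein EGFR numbering).
#' @return An object of class `receptor`: list with `atoms` data.frame,
#'   `residue_index`, `hinge_residues`, `pocket_center` (NULL until set).
#' @export
read_receptor <- function(path, keep_hetero = FALSE,
                          charge_scheme = c("template", "bfactor"),
                          hinge_residues = 791:795) {
  charge_scheme <- match.arg(charge_scheme)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("malformed PDB record (too short) at line ", ln)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz)))
      stop("non-numeric coordinates in PDB record at line ", ln)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no receptor atoms found in ", path)
  el <- trimws(at$elesy)
  fix <- !nzchar(el) | is.na(el)
  el[fix] <- element_from_name(at$elety[fix])
  el <- normalize_element(el)
  atoms <- data.frame(
    serial = at$eleno, element = el, atom_name = trimws(at$elety),
    resno = at$resno, resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge = 0, row.names = NULL)
  atoms$is_backbone <- atoms$atom_name %in% c("N", "CA", "C", "O", "H", "HA")
  atoms$atom_type <- receptor_atom_types(atoms)
  atoms$charge <- if (charge_scheme == "bfactor") at$b
                  else template_charges(atoms)
  res <- split(seq_len(nrow(atoms)), atoms$resno)
  structure(list(atoms = atoms,
                 residue_index = res,
                 hinge_residues = intersect(hinge_residues,
                                            as.integer(names(res))),
                 pocket_center = NULL),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor: %d atoms, %d residues, hinge {%s}>\n",
              nrow(x$atoms), length(x$residue_index),
              paste(x$hinge_residues, collapse = ",")))
  invisible(x)
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

element_from_name <- function(name) {
  name <- trimws(name)
  two <- toupper(substr(name, 1, 2))
  ifelse(two %in% c("CL", "BR"), two, substr(gsub("[0-9]", "", name), 1, 1))
}

# geometric typing for receptor atoms (no bond table in PDB)
receptor_atom_types <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  ty <- character(nrow(atoms))
  polar_heavy <- which(el %in% c("N", "O", "S"))
  hs <- which(el == "H")
  h_polar <- rep(FALSE, nrow(atoms))
  n_has_h <- rep(FALSE, nrow(atoms))
  if (length(hs) && length(polar_heavy)) {
    d2 <- outer(rowSums(xyz[hs, , drop = FALSE]^2),
                rowSums(xyz[polar_heavy, , drop = FALSE]^2), "+") -
      2 * xyz[hs, , drop = FALSE] %*% t(xyz[polar_heavy, , drop = FALSE])
    close <- d2 < 1.25^2
    h_polar[hs] <- apply(close, 1, any)
    hit <- polar_heavy[unique(unlist(apply(close, 1, which)))]
    n_has_h[hit] <- TRUE
  }
  for (i in seq_len(nrow(atoms))) {
    ty[i] <- switch(el[i],
      H = if (h_polar[i]) "HD" else "H",
      C = "C",
      N = if (n_has_h[i]) "N" else "NA",
      O = "OA", S = "SA", P = "P",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      "C")
  }
  ty
}

# simple per-element template charges for receptors read without charges
template_charges <- function(atoms) {
  ch <- c(N = -0.35, O = -0.45, S = -0.15, C = 0.05, P = 0.4,
          F = -0.2, Cl = -0.1, Br = -0.1, I = -0.05)
  q <- unname(ch[atoms$element])
  q[is.na(q)] <- 0
  q[atoms$atom_type == "HD"] <- 0.30
  q[atoms$atom_type == "H"] <- 0.05
  q
}

#' Write a receptor to a PDB file
#'
#' Partial charges are stored in the B-factor column (the convention
#' [read_receptor()] reads back with `charge_scheme = "bfactor"`).
#'
#' @param receptor A `receptor`.
#' @param path Output path.
#' @export
write_receptor_pdb <- function(receptor, path) {
  a <- receptor$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, substr(a$atom_name, 1, 4), substr(a$resname, 1, 3),
    ifelse(nzchar(a$chain), a$chain, "A"), a$resno,
    a$x, a$y, a$z, 1.00, a$charge, toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Lipinski rule-of-five profile
#'
#' Molecular weight from standard atomic weights, logP from Open Babel's
#' atom-contribution model, donors as N/O bearing at least one hydrogen,
#' acceptors as the N + O count, and the violation count against
#' (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10).
#'
#' @param mol A `ligand_mol`.
#' @return List with `mw`, `logp`, `hbd`, `hba`, `violations`.
#' @export
ro5_profile <- function(mol) {
  mw <- molecular_weight(mol$formula)
  el <- mol$atoms$element
  adj <- adjacency(mol)
  no <- which(el %in% c("N", "O"))
  hbd <- sum(vapply(no, function(i) any(el[adj[[i]]] == "H"), logical(1)))
  hba <- length(no)
  logp <- mol_logp(mol)
  violations <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)
  list(mw = mw, logp = logp, hbd = hbd, hba = hba, violations = violations)
}

mol_logp <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_ligands(list(mol), tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  pr <- ChemmineR::propOB(sdfs)
  as.numeric(pr$logP[1])
}
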