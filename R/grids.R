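#' Define a grid box
#'
#' @param origin 3-vector, Angstrom: coordinates of the first node.
#' @param spacing Node spacing, Angstrom (> 0).
#' @param npts Integer 3-vector: nodes per axis (>= 2).
#' @return A `grid_box`.
#' @export
grid_box <- function(origin, spacing, npts) {
  stopifnot(spacing > 0, all(npts >= 2), length(origin) == 3)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 npts = as.integer(npts)), class = "grid_box")
}

#' @export
print.grid_box <- function(x, ...) {
  cat(sprintf("<grid_box: %dx%dx%d @ %.3f A, origin (%.2f, %.2f, %.2f)>\n",
              x$npts[1], x$npts[2], x$npts[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

box_max <- function(box) box$origin + (box$npts - 1L) * box$spacing

#' Whole-domain grid box around a receptor
#'
#' Axis-aligned bounding box of all receptor atoms, padded by `margin`
#' and snapped outward to whole spacing units, for peripheral-site scans
#' covering the entire domain.
#'
#' @param receptor A `receptor`.
#' @param margin Padding, Angstrom.
#' @param spacing Node spacing, Angstrom.
#' @return A `grid_box` containing every receptor atom.
#' @export
whole_domain_box <- function(receptor, margin = 5, spacing = 1.0) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  npts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_box(lo, spacing, npts)
}

grid_nodes <- function(box) {
  ax <- lapply(1:3, function(k)
    box$origin[k] + (seq_len(box$npts[k]) - 1L) * box$spacing)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' Precompute affinity and electrostatic grid maps
#'
#' For every probe atom type: a van der Waals map (weighted 12-6 sum
#' over receptor atoms within the cutoff) and, for types participating
#' in hydrogen bonds, a separate 12-10 map evaluated at the
#' geometry-independent upper bound `E(t) = 1` (exact directionality is
#' applied only in direct rescoring).  The electrostatic map stores the
#' screened potential per unit probe charge, without the term weight.
#' Values are clamped at `clamp` to keep clashed nodes finite.
#'
#' @param receptor A `receptor`.
#' @param box A `grid_box`.
#' @param params Energy parameter list.
#' @param pair_table Pair-potential table.
#' @param probe_types Atom types to map (default: all in the table).
#' @param clamp Upper clamp for stored values, kcal/mol.
#' @return A `grid_maps` object: `box`, `vdw` and `hbond` lists of
#'   arrays keyed by type, `elec` array, `provenance` string.
#' @export
build_grid_maps <- function(receptor, box,
                            params = default_energy_params(),
                            pair_table = default_pair_potentials(),
                            probe_types = pair_table$types,
                            clamp = 1e5) {
  nodes <- grid_nodes(box)
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  in_reach <- any(apply(rxyz, 1, function(a) {
    all(a >= box$origin - params$nb_cutoff) &&
      all(a <= box_max(box) + params$nb_cutoff)
  }))
  if (!in_reach)
    warning("no receptor atom within cutoff of the grid box; maps will be flat")
  d2 <- outer(rowSums(nodes^2), rowSums(rxyz^2), "+") - 2 * nodes %*% t(rxyz)
  d <- sqrt(pmax(d2, 0))
  within <- d <= params$nb_cutoff
  dcl <- pmax(d, params$r_clamp)
  rt <- receptor$atoms$atom_type
  ri <- match(rt, pair_table$types)
  dims <- box$npts
  vdw <- list(); hbond <- list()
  inv12 <- (1 / dcl^12) * within
  inv10 <- (1 / dcl^10) * within
  inv6 <- (1 / dcl^6) * within
  for (ty in probe_types) {
    ti <- match(ty, pair_table$types)
    a <- pair_table$A[ri, ti]; b <- pair_table$B[ri, ti]
    v <- params$w_vdw * (inv12 %*% a - inv6 %*% b)
    vdw[[ty]] <- array(pmin(as.numeric(v), clamp), dim = dims)
    if (any(pair_table$is_hbond[ri, ti])) {
      cc <- pair_table$C[ri, ti]; dd <- pair_table$D[ri, ti]
      h <- params$w_hbond * (inv12 %*% cc - inv10 %*% dd)
      hbond[[ty]] <- array(pmin(as.numeric(h), clamp), dim = dims)
    }
  }
  eps <- sigmoidal_dielectric(dcl, params$dielectric)
  pot <- (params$coulomb_constant * receptor$atoms$charge)
  e <- ((1 / (eps * dcl)) * within) %*% pot
  elec <- array(pmax(pmin(as.numeric(e), clamp), -clamp), dim = dims)
  structure(list(box = box, vdw = vdw, hbond = hbond, elec = elec,
                 probe_types = probe_types,
                 provenance = sprintf("natoms=%d;spacing=%.4f;cutoff=%.2f",
                                      nrow(rxyz), box$spacing,
                                      params$nb_cutoff)),
            class = "grid_maps")
}

# trilinear interpolation of one array at points (n x 3); out-of-box
# points get `oob` instead
trilinear <- function(arr, box, pts, oob = 1e4) {
  pts <- matrix(pts, ncol = 3)
  u <- sweep(pts, 2, box$origin) / box$spacing
  n <- box$npts
  out <- rep(oob, nrow(pts))
  ok <- u[, 1] >= 0 & u[, 1] <= n[1] - 1 &
        u[, 2] >= 0 & u[, 2] <= n[2] - 1 &
        u[, 3] >= 0 & u[, 3] <= n[3] - 1
  if (!any(ok)) return(out)
  uu <- u[ok, , drop = FALSE]
  i0 <- pmin(floor(uu), matrix(rep(n - 2L, each = nrow(uu)), ncol = 3))
  f <- uu - i0
  i0 <- i0 + 1L  # 1-based
  v <- numeric(nrow(uu))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    v <- v + w * arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[ok] <- v
  out
}

#' Interpolate a grid map at a point
#'
#' Trilinear interpolation of the probe-type affinity (vdW + bound
#' hydrogen-bond map where present) plus `W_elec * q` times the
#' electrostatic map.  Points outside the box return the documented
#' out-of-box penalty.
#'
#' @param maps A `grid_maps`.
#' @param point 3-vector or n x 3 matrix, Angstrom.
#' @param probe_type Atom type code of the probe.
#' @param charge Probe partial charge, e.
#' @param params Energy parameters (for `w_elec` and the penalty).
#' @return Interpolated energy (kcal/mol), vectorized over rows.
#' @export
interpolate <- function(maps, point, probe_type, charge = 0,
                        params = default_energy_params()) {
  if (!probe_type %in% names(maps$vdw))
    stop("no grid map for probe type '", probe_type, "'")
  pen <- params$oob_penalty
  v <- trilinear(maps$vdw[[probe_type]], maps$box, point, oob = pen)
  if (!is.null(maps$hbond[[probe_type]]))
    v <- v + trilinear(maps$hbond[[probe_type]], maps$box, point, oob = 0)
  if (any(charge != 0))
    v <- v + params$w_elec * charge *
      trilinear(maps$elec, maps$box, point, oob = 0)
  v
}

# total grid-interpolated interaction energy of a posed conformation
grid_interaction_energy <- function(maps, mol, conf_xyz,
                                    params = default_energy_params()) {
  tys <- mol$atoms$atom_type
  q <- mol$atoms$charge
  e <- 0
  for (ty in unique(tys)) {
    sel <- tys == ty
    e <- e + sum(interpolate(maps, conf_xyz[sel, , drop = FALSE], ty,
                             charge = q[sel], params = params))
  }
  e
}

#' Serialize grid maps in a plain-text .map dialect
#'
#' One file per map plus the electrostatic map, in an AutoDock-style
#' header (spacing, points per axis, center) followed by one value per
#' line in x-fastest order.  [read_grid_maps()] round-trips.
#'
#' @param maps A `grid_maps`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Paths written, invisibly.
#' @export
write_grid_maps <- function(maps, dir, stem = "receptor") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  box <- maps$box
  center <- box$origin + (box$npts - 1L) * box$spacing / 2
  hdr <- c(sprintf("SPACING %.6f", box$spacing),
           sprintf("NELEMENTS %d %d %d", box$npts[1] - 1L,
                   box$npts[2] - 1L, box$npts[3] - 1L),
           sprintf("CENTER %.6f %.6f %.6f", center[1], center[2], center[3]),
           sprintf("PROVENANCE %s", maps$provenance))
  paths <- character(0)
  emit <- function(arr, path) {
    writeLines(c(hdr, sprintf("%.10g", as.numeric(arr))), path)
    path
  }
  for (ty in names(maps$vdw))
    paths <- c(paths, emit(maps$vdw[[ty]],
                           file.path(dir, sprintf("%s.%s.map", stem, ty))))
  for (ty in names(maps$hbond))
    paths <- c(paths, emit(maps$hbond[[ty]],
                           file.path(dir, sprintf("%s.%s.hb.map", stem, ty))))
  paths <- c(paths, emit(maps$elec, file.path(dir, sprintf("%s.e.map", stem))))
  invisible(paths)
}

#' @rdname write_grid_maps
#' @param stem File-name stem used when writing.
#' @export
read_grid_maps <- function(dir, stem = "receptor") {
  files <- list.files(dir, pattern = paste0("^", stem, "\\..*\\.map$"),
                      full.names = TRUE)
  if (!length(files)) stop("no map files with stem '", stem, "' in ", dir)
  parse_one <- function(path) {
    lines <- readLines(path)
    sp <- as.numeric(strsplit(lines[1], " ")[[1]][2])
    ne <- as.integer(strsplit(lines[2], " ")[[1]][2:4])
    ce <- as.numeric(strsplit(lines[3], " ")[[1]][2:4])
    prov <- sub("^PROVENANCE ", "", lines[4])
    npts <- ne + 1L
    origin <- ce - ne * sp / 2
    vals <- as.numeric(lines[-(1:4)])
    list(box = grid_box(origin, sp, npts),
         arr = array(vals, dim = npts), prov = prov)
  }
  vdw <- list(); hbond <- list(); elec <- NULL; box <- NULL; prov <- NULL
  for (f in files) {
    p <- parse_one(f)
    box <- p$box; prov <- p$prov
    base <- sub("\\.map$", "", basename(f))
    parts <- strsplit(base, ".", fixed = TRUE)[[1]][-1]
    if (identical(parts, "e")) elec <- p$arr
    else if (length(parts) == 2 && parts[2] == "hb") hbond[[parts[1]]] <- p$arr
    else vdw[[parts[1]]] <- p$arr
  }
  structure(list(box = box, vdw = vdw, hbond = hbond, elec = elec,
                 probe_types = names(vdw), provenance = prov),
            class = "grid_maps")
}
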