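# Per-type Lennard-Jones parameters (Rmin/2 in A, well depth in kcal/mol)
# in the AMBER tradition, for the finite atom-type vocabulary.
.LJ_TYPES <- data.frame(
  type      = c("C", "A", "N", "NA", "OA", "SA", "H", "HD", "P",
                "F", "Cl", "Br", "I"),
  rmin_half = c(2.00, 2.00, 1.75, 1.75, 1.60, 2.00, 1.00, 1.00, 2.10,
                1.55, 2.04, 2.165, 2.36),
  eps       = c(0.15, 0.15, 0.16, 0.16, 0.20, 0.20, 0.02, 0.02, 0.20,
                0.08, 0.276, 0.389, 0.55),
  stringsAsFactors = FALSE
)

# 12-10 hydrogen-bond wells between a donatable hydrogen (HD) and an
# acceptor type: equilibrium distance (A) and depth (kcal/mol).
.HB_WELLS <- data.frame(
  acceptor = c("OA", "NA", "SA"),
  re       = c(1.90, 1.90, 2.50),
  eps      = c(5.0, 5.0, 1.0),
  stringsAsFactors = FALSE
)

#' Default weights and constants of the scoring function
#'
#' The four term weights are the classic empirical docking calibration
#' the model extends (all overridable via config): `w_vdw` 0.1485,
#' `w_hbond` 0.0656, `w_elec` 0.1146, `w_tor` 0.3113.  The Coulomb
#' constant is 332.0 kcal*A/(mol*e^2); the sigmoidal screening constants
#' (A, B, k, lambda) reproduce the bulk-water limit of 78.4.  `sigma` is
#' the Gaussian width (A) of the hydration occupancy envelope.
#'
#' @return Named list of parameters.
#' @export
default_energy_params <- function() {
  list(
    w_vdw = 0.1485, w_hbond = 0.0656, w_elec = 0.1146, w_tor = 0.3113,
    coulomb_constant = 332.0,
    dielectric = c(A = -8.5525, B = 86.9525, k = 7.7839, lambda = 0.003627),
    sigma = 3.5,
    hbond_angle_cutoff = 90,
    nb_cutoff = 12,
    r_clamp = 0.5,
    oob_penalty = 1e4
  )
}

#' Load energy parameters from a YAML config file
#'
#' Any subset of the fields of [default_energy_params()] may be given;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return Named parameter list.
#' @export
read_energy_config <- function(path = NULL) {
  p <- default_energy_params()
  if (is.null(path)) return(p)
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    if (nm == "dielectric") {
      d <- unlist(cfg$dielectric)
      p$dielectric[names(d)] <- d
    } else p[[nm]] <- cfg[[nm]]
  }
  stopifnot(p$sigma > 0, p$nb_cutoff > 0)
  p
}

#' Build the pair-potential table
#'
#' For every ordered pair of atom types: 12-6 coefficients
#' `A = eps * R^12`, `B = 2 eps R^6` with `R = Ri + Rj` and
#' `eps = sqrt(eps_i eps_j)`; pairs of a donatable hydrogen with an
#' acceptor are flagged as hydrogen-bond pairs and carry 12-10
#' coefficients `C = 5 eps Re^12`, `D = 6 eps Re^10` instead (their 12-6
#' part is zeroed, as the 12-10 well replaces it).
#'
#' @param lj data.frame of per-type (type, rmin_half, eps); defaults to
#'   the packaged table.
#' @param hb data.frame of 12-10 wells (acceptor, re, eps).
#' @return A `pair_table`: list of square matrices `A`, `B`, `C`, `D`,
#'   logical `is_hbond`, dimnames = atom types.
#' @export
default_pair_potentials <- function(lj = .LJ_TYPES, hb = .HB_WELLS) {
  ty <- lj$type
  nt <- length(ty)
  R <- outer(lj$rmin_half, lj$rmin_half, "+")
  EPS <- sqrt(outer(lj$eps, lj$eps))
  A <- EPS * R^12
  B <- 2 * EPS * R^6
  C <- matrix(0, nt, nt); D <- matrix(0, nt, nt)
  is_hb <- matrix(FALSE, nt, nt)
  dimnames(A) <- dimnames(B) <- dimnames(C) <- dimnames(D) <-
    dimnames(is_hb) <- list(ty, ty)
  hd <- which(ty == "HD")
  if (length(hd)) {
    for (r in seq_len(nrow(hb))) {
      ac <- which(ty == hb$acceptor[r])
      if (!length(ac)) next
      cij <- 5 * hb$eps[r] * hb$re[r]^12
      dij <- 6 * hb$eps[r] * hb$re[r]^10
      for (p in list(c(hd, ac), c(ac, hd))) {
        C[p[1], p[2]] <- cij; D[p[1], p[2]] <- dij
        A[p[1], p[2]] <- 0;   B[p[1], p[2]] <- 0
        is_hb[p[1], p[2]] <- TRUE
      }
    }
  }
  structure(list(types = ty, A = A, B = B, C = C, D = D, is_hbond = is_hb),
            class = "pair_table")
}

#' Write / read a pair-potential table as TSV
#'
#' Long format with columns type_i, type_j, A, B, C, D, is_hbond; the
#' file is the interchange contract for externalized parameters.
#'
#' @param table A `pair_table`.
#' @param path TSV path.
#' @export
write_pair_potentials <- function(table, path) {
  ty <- table$types
  idx <- which(upper.tri(table$A, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(type_i = ty[idx[, 1]], type_j = ty[idx[, 2]],
                   A = table$A[idx], B = table$B[idx],
                   C = table$C[idx], D = table$D[idx],
                   is_hbond = table$is_hbond[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_potentials
#' @export
read_pair_potentials <- function(path) {
  # na.strings disabled: "NA" is the nitrogen-acceptor atom type
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = character(0))
  ty <- sort(unique(c(df$type_i, df$type_j)))
  nt <- length(ty)
  mk <- function() matrix(0, nt, nt, dimnames = list(ty, ty))
  A <- mk(); B <- mk(); C <- mk(); D <- mk()
  is_hb <- matrix(FALSE, nt, nt, dimnames = list(ty, ty))
  for (r in seq_len(nrow(df))) {
    i <- df$type_i[r]; j <- df$type_j[r]
    A[i, j] <- A[j, i] <- df$A[r]; B[i, j] <- B[j, i] <- df$B[r]
    C[i, j] <- C[j, i] <- df$C[r]; D[i, j] <- D[j, i] <- df$D[r]
    is_hb[i, j] <- is_hb[j, i] <- df$is_hbond[r]
  }
  structure(list(types = ty, A = A, B = B, C = C, D = D, is_hbond = is_hb),
            class = "pair_table")
}

#' Atomic hydration parameters of the solvent-contact model
#'
#' Per atom type: `S`, the hydration energy density in kcal/(mol*A^3);
#' `V`, the atomic volume in A^3; `O_max`, the maximum occupancy in A^3.
#' The shipped values are an illustrative, internally consistent default
#' set (polar types carry positive S, i.e. a dehydration penalty;
#' apolar carbon a small negative S); the TSV file format is the
#' contract for supplying fitted values.
#'
#' @return data.frame with columns type, S, V, O_max.
#' @export
default_hydration_params <- function() {
  data.frame(
    type  = c("C", "A", "N", "NA", "OA", "SA", "H", "HD", "P",
              "F", "Cl", "Br", "I"),
    S     = c(-0.0030, -0.0025, 0.0120, 0.0130, 0.0150, 0.0020,
              -0.0005, 0.0080, 0.0050, 0.0060, 0.0025, 0.0018, 0.0012),
    V     = c(33.5, 33.5, 22.4, 22.4, 17.0, 33.5, 7.2, 7.2, 38.8,
              15.4, 35.8, 42.6, 55.1),
    O_max = 8 * c(33.5, 33.5, 22.4, 22.4, 17.0, 33.5, 7.2, 7.2, 38.8,
                  15.4, 35.8, 42.6, 55.1),
    stringsAsFactors = FALSE
  )
}

#' Write / read hydration parameters as TSV
#' @param table data.frame as from [default_hydration_params()].
#' @param path TSV path.
#' @export
write_hydration_params <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hydration_params
#' @export
read_hydration_params <- function(path) {
  # na.strings disabled: "NA" is the nitrogen-acceptor atom type
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = character(0))
  stopifnot(all(c("type", "S", "V", "O_max") %in% names(df)),
            all(df$V > 0), all(df$O_max > 0))
  df
}
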