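# Backbone torsion algebra, NeRF rebuilding, rigid superposition and
# torsion-bin secondary-structure assignment.

#' Ideal backbone bond geometry
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used whenever backbone
#' coordinates are rebuilt from torsions.
#'
#' @return Named list of geometry constants.
#' @export
bb_geom <- function() {
  list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
       ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
       ang_ca_c_o = 120.5, ang_c_ca_cb = 110.1)
}

# Dihedral angle (degrees, IUPAC sign) for rows of four coordinate matrices.
dihedral4 <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4) }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / row_norm(b2))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  rad2deg(atan2(y, x))
}

# Bond angle at p2 (degrees), vectorized over rows.
bond_angle3 <- function(p1, p2, p3) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3) }
  u <- p1 - p2; v <- p3 - p2
  cosang <- rowSums(u * v) / (row_norm(u) * row_norm(v))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

# Natural-extension (NeRF) placement: position atom d bonded to c, given
# bond |c-d|, angle b-c-d and dihedral a-b-c-d (degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), -bond * sin(tor) * sin(ang))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + bc * d2[1L] + m * d2[2L] + n * d2[3L]
}

#' Backbone torsion angles of a model
#'
#' Standard definitions: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1), omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1). The first
#' phi and the last psi/omega are undefined (NA).
#'
#' @param model A `protein_model` with an intact chain.
#' @return Data frame with columns `resi`, `phi`, `psi`, `omega` (degrees).
#' @export
compute_backbone_torsions <- function(model) {
  n <- n_res(model)
  rep_v <- validate_input(model)
  if ("CHAIN_BREAK" %in% rep_v$violations)
    stop("chain break; torsions undefined across the break")
  N <- bb_coords(model, "N"); CA <- bb_coords(model, "CA"); C <- bb_coords(model, "C")
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n >= 2L) {
    phi[-1L] <- dihedral4(C[-n, , drop = FALSE], N[-1L, , drop = FALSE],
                          CA[-1L, , drop = FALSE], C[-1L, , drop = FALSE])
    psi[-n] <- dihedral4(N[-n, , drop = FALSE], CA[-n, , drop = FALSE],
                         C[-n, , drop = FALSE], N[-1L, , drop = FALSE])
    omega[-n] <- dihedral4(CA[-n, , drop = FALSE], C[-n, , drop = FALSE],
                           N[-1L, , drop = FALSE], CA[-1L, , drop = FALSE])
  }
  data.frame(resi = seq_len(n), phi = phi, psi = psi, omega = omega)
}

# Place the carbonyl O of residue given N, CA, C and the residue's psi
# (NA -> treated as 180).
place_O <- function(N, CA, C, psi, geom = bb_geom()) {
  if (is.na(psi)) psi <- 180
  nerf_place(N, CA, C, geom$c_o, geom$ang_ca_c_o, wrap180(psi - 180))
}

# Place CB from backbone atoms (L-configuration); dihedral value fixed by
# construction against an ideal alanine fragment.
place_CB <- function(N, CA, C, geom = bb_geom()) {
  nerf_place(N, C, CA, geom$ca_cb, geom$ang_c_ca_cb, 120.0)
}

#' Rebuild backbone coordinates from torsions
#'
#' Deterministic NeRF-style chain construction with ideal bond geometry.
#' The first residue's N/CA/C are taken from `anchor`; subsequent atoms are
#' placed from phi/psi/omega. Carbonyl oxygens are placed from psi; CB atoms
#' are added for non-glycine residues when `add_cb` is TRUE.
#'
#' @param torsions Data frame as returned by [compute_backbone_torsions()]
#'   (phi of residue 1 and psi/omega of the last residue may be NA).
#' @param anchor 3x3 matrix: coordinates of N, CA, C of the first residue.
#' @param sequence One-letter sequence (default poly-alanine).
#' @param geom Bond geometry, see [bb_geom()].
#' @param add_cb Add CB atoms for non-glycine residues.
#' @return A backbone-only `protein_model`.
#' @export
rebuild_backbone_from_torsions <- function(torsions, anchor,
                                           sequence = NULL, geom = bb_geom(),
                                           add_cb = TRUE) {
  n <- nrow(torsions)
  aa <- if (is.null(sequence)) rep("A", n) else strsplit(sequence, "")[[1L]]
  stopifnot(length(aa) == n, nrow(anchor) == 3L)
  if (n > 1L && anyNA(torsions$psi[-n])) stop("undefined interior psi")
  if (n > 1L && anyNA(torsions$phi[-1L])) stop("undefined interior phi")
  omega <- torsions$omega
  omega[is.na(omega)] <- 180

  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- anchor[1L, ]; CA[1L, ] <- anchor[2L, ]; C[1L, ] <- anchor[3L, ]
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], geom$c_n,
                              geom$ang_ca_c_n, torsions$psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ], geom$n_ca,
                               geom$ang_c_n_ca, omega[i])
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], geom$ca_c,
                              geom$ang_n_ca_c, torsions$phi[i + 1L])
  }
  res_atoms <- vector("list", n)
  for (i in seq_len(n)) {
    al <- list(N = N[i, ], CA = CA[i, ], C = C[i, ],
               O = place_O(N[i, ], CA[i, ], C[i, ], torsions$psi[i], geom))
    if (add_cb && aa[i] != "G")
      al$CB <- place_CB(N[i, ], CA[i, ], C[i, ], geom)
    res_atoms[[i]] <- al
  }
  model_from_residue_atoms(aa, res_atoms, provenance = "rebuilt")
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile %*% R + t` onto `target`.
#'
#' @param mobile,target Point sets (k x 3 matrices, k >= 3, same k).
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  if (all(abs(s$d) < 1e-12)) stop("degenerate (rank-deficient) point set")
  t_vec <- ct - drop(cm %*% R)
  moved <- mobile %*% R
  moved <- sweep(moved, 2L, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param X k x 3 coordinate matrix.
#' @param tf Transform from [kabsch_superpose()].
#' @return Transformed k x 3 matrix.
#' @export
apply_transform <- function(X, tf) {
  sweep(as.matrix(X) %*% tf$rotation, 2L, tf$translation, `+`)
}

#' Torsion-bin secondary-structure assignment
#'
#' Assigns H (helix) when phi is in (-100,-30) and psi in (-80,-5); E
#' (strand) when phi is in (-180,-80) and psi in (80,180) or (-180,-170);
#' otherwise C. Singleton H/E labels (both neighbours differ) are smoothed
#' to C. Torsion-based by design: no hydrogen-bond (DSSP) dependency.
#'
#' @param model A `protein_model`.
#' @return Character vector of per-residue labels in {H,E,C}.
#' @export
assign_secondary_structure <- function(model) {
  tor <- compute_backbone_torsions(model)
  n <- nrow(tor)
  ss <- rep("C", n)
  phi <- tor$phi; psi <- tor$psi
  isH <- !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 & psi > -80 & psi < -5
  isE <- !is.na(phi) & !is.na(psi) & phi > -180 & phi < -80 &
    ((psi > 80 & psi <= 180) | (psi >= -180 & psi < -170))
  ss[isE] <- "E"; ss[isH] <- "H"
  # smooth singletons
  for (i in seq_len(n)) {
    if (ss[i] == "C") next
    left <- if (i > 1L) ss[i - 1L] else ""
    right <- if (i < n) ss[i + 1L] else ""
    if (left != ss[i] && right != ss[i]) ss[i] <- "C"
  }
  ss
}

# Contiguous runs of a given SS label with minimum length.
ss_chunks <- function(ss, labels = c("H", "E"), min_len = 4L) {
  r <- rle(ss)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values %in% labels & r$lengths >= min_len
  if (!any(keep)) return(list())
  mapply(function(s, e) c(s, e), starts[keep], ends[keep], SIMPLIFY = FALSE)
}
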