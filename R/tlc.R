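# Triaxial loop closure: solve for phi/psi at three pivot residues so that a
# backbone segment with otherwise fixed torsions joins two fixed anchors
# exactly. Classic three-pivot reduction: the middle-pivot CA lies on the
# circle of intersection of two spheres (virtual CA-CA distances to the
# outer pivots are conformation-invariant); for each point on that circle
# the outer-pivot bond-angle constraints give at most 2x2 discrete branches,
# and the remaining N-CA-C bond-angle constraint at the middle pivot is a
# one-dimensional root-finding problem scanned over the circle.

# A cos(x) + B sin(x) = C  ->  0, 1 or 2 solutions in (-pi, pi]
solve_sinusoid <- function(A, B, C) {
  R <- sqrt(A * A + B * B)
  if (R < 1e-14 || abs(C) > R) return(numeric(0))
  base <- atan2(B, A)
  d <- acos(min(1, max(-1, C / R)))
  c(base + d, base - d)
}

# Signed angle from p to q about unit axis u (all 3-vectors, p/q not
# necessarily unit or perpendicular to u; their perpendicular parts are used).
signed_angle_about <- function(u, p, q) {
  pp <- p - sum(p * u) * u
  qq <- q - sum(q * u) * u
  atan2(sum(u * vcross(pp, qq)), sum(pp * qq))
}

# Forward NeRF build of loop residues 1..L (+ predicted anchor residue L+1)
# from the N-side anchor. `phi`, `psi` are length-L vectors; `omega` length L
# (omega[i] between residue i and i+1); joins: psi0/omega0 connect anchor
# residue 0 to residue 1, phi_end is phi of anchor residue L+1.
tlc_build_forward <- function(anchor_n, phi, psi, omega, psi0, omega0,
                              phi_end, geom = bb_geom()) {
  L <- length(phi)
  N <- CA <- C <- matrix(NA_real_, L + 1L, 3L)
  a <- anchor_n[1L, ]; b <- anchor_n[2L, ]; cc <- anchor_n[3L, ]
  phis <- c(phi, phi_end); psis <- c(psi0, psi); omegas <- c(omega0, omega)
  for (i in seq_len(L + 1L)) {
    Ni <- nerf_place(a, b, cc, geom$c_n, geom$ang_ca_c_n, psis[i])
    CAi <- nerf_place(b, cc, Ni, geom$n_ca, geom$ang_c_n_ca, omegas[i])
    Ci <- nerf_place(cc, Ni, CAi, geom$ca_c, geom$ang_n_ca_c, phis[i])
    N[i, ] <- Ni; CA[i, ] <- CAi; C[i, ] <- Ci
    a <- Ni; b <- CAi; cc <- Ci
  }
  list(N = N, CA = CA, C = C)
}

# Backward build from the C-side anchor down to residue `stop_res`.
tlc_build_backward <- function(anchor_c, phi, psi, omega, phi_end, stop_res,
                               geom = bb_geom()) {
  L <- length(phi)
  N <- CA <- C <- matrix(NA_real_, L + 1L, 3L)
  N[L + 1L, ] <- anchor_c[1L, ]; CA[L + 1L, ] <- anchor_c[2L, ]
  C[L + 1L, ] <- anchor_c[3L, ]
  phis <- c(phi, phi_end)
  for (i in L:stop_res) {
    C[i, ] <- nerf_place(C[i + 1L, ], CA[i + 1L, ], N[i + 1L, ], geom$c_n,
                         geom$ang_c_n_ca, phis[i + 1L])
    CA[i, ] <- nerf_place(CA[i + 1L, ], N[i + 1L, ], C[i, ], geom$ca_c,
                          geom$ang_ca_c_n, omega[i])
    N[i, ] <- nerf_place(N[i + 1L, ], C[i, ], CA[i, ], geom$n_ca,
                         geom$ang_n_ca_c, psi[i])
  }
  list(N = N, CA = CA, C = C)
}

#' Analytic triaxial loop closure
#'
#' Given fixed N-side and C-side anchors (backbone N/CA/C of the residues
#' immediately before and after the loop), fixed torsions at all non-pivot
#' loop residues, and three pivot residues, returns every conformation of
#' the loop (phi/psi at the pivots) that joins both anchors with ideal
#' peptide geometry. Omega angles are never altered.
#'
#' @param torsions Data frame with L rows (columns `phi`, `psi`, `omega`,
#'   degrees) for the loop residues; pivot-row phi/psi act as reference
#'   values only. `omega[i]` is the torsion between loop residues i and i+1
#'   (`omega[L]` joins the loop to the C anchor).
#' @param fixed_n_anchor 3x3 matrix: N, CA, C of the residue before the loop.
#' @param fixed_c_anchor 3x3 matrix: N, CA, C of the residue after the loop.
#' @param pivot_residues Three strictly increasing loop-residue indices.
#' @param psi0,omega0 Torsions joining the N anchor to loop residue 1.
#' @param phi_end Phi of the C-anchor residue.
#' @param geom Bond geometry ([bb_geom()]).
#' @param n_scan Grid resolution of the circle scan (default 360).
#' @param gap_tol Maximum allowed anchor mismatch of a solution (Angstrom).
#' @return List of solutions; each has `torsions` (completed data frame),
#'   `bb` (list of N/CA/C coordinate matrices for the loop residues) and
#'   `gap` (achieved closure error, Angstrom). Empty list if no real
#'   solution exists.
#' @export
triaxial_loop_closure <- function(torsions, fixed_n_anchor, fixed_c_anchor,
                                  pivot_residues, psi0, omega0, phi_end,
                                  geom = bb_geom(), n_scan = 360L,
                                  gap_tol = 1e-6) {
  L <- nrow(torsions)
  if (L < 3L) stop("loop length must be >= 3")
  p <- sort(as.integer(pivot_residues))
  if (length(p) != 3L || p[1L] < 1L || p[3L] > L || any(duplicated(p)))
    stop("pivots must be 3 distinct residues inside the loop")
  phi <- torsions$phi; psi <- torsions$psi; omega <- torsions$omega
  phi[is.na(phi)] <- 0; psi[is.na(psi)] <- 0; omega[is.na(omega)] <- 180
  p1 <- p[1L]; p2 <- p[2L]; p3 <- p[3L]

  fwd <- tlc_build_forward(fixed_n_anchor, phi, psi, omega, psi0, omega0,
                           phi_end, geom)
  bwd <- tlc_build_backward(fixed_c_anchor, phi, psi, omega, phi_end, p2, geom)

  # fixed frame atoms
  A0 <- if (p1 == 1L) fixed_n_anchor[3L, ] else fwd$C[p1 - 1L, ]
  N1 <- fwd$N[p1, ]; CA1 <- fwd$CA[p1, ]
  N3b <- bwd$N[p3 + 1L, ]
  C3 <- bwd$C[p3, ]; CA3 <- bwd$CA[p3, ]

  d12 <- vnorm(fwd$CA[p2, ] - fwd$CA[p1, ])
  d23 <- vnorm(fwd$CA[p3, ] - fwd$CA[p2, ])
  u1ref <- vunit(fwd$C[p1, ] - CA1)
  h1 <- sum((fwd$CA[p2, ] - fwd$CA[p1, ]) * u1ref)
  u3ref <- vunit(bwd$N[p3, ] - CA3)
  h3 <- sum((bwd$CA[p2, ] - CA3) * u3ref)

  # circle of possible middle-pivot CA positions
  e <- CA3 - CA1; D <- vnorm(e)
  if (D < 1e-9) return(list())
  ehat <- e / D
  a_len <- (D * D + d12 * d12 - d23 * d23) / (2 * D)
  rc2 <- d12 * d12 - a_len * a_len
  if (rc2 <= 0) return(list())
  rc <- sqrt(rc2)
  Oc <- CA1 + a_len * ehat
  ref <- if (abs(ehat[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- vunit(vcross(ehat, ref)); v2 <- vcross(ehat, v1)

  theta1 <- deg2rad(geom$ang_n_ca_c)
  ct1 <- cos(theta1); st1 <- sin(theta1)
  # forward sinusoid frame (phi1 cone about N1-CA1)
  bc1 <- vunit(CA1 - N1); nn1 <- vunit(vcross(N1 - A0, bc1)); mm1 <- vcross(nn1, bc1)
  # backward sinusoid frame (psi3 cone about CA3-C3; NeRF a=N3b, b=C3, c=CA3)
  bc3 <- vunit(CA3 - C3); nn3 <- vunit(vcross(C3 - N3b, bc3)); mm3 <- vcross(nn3, bc3)

  # moving reference points
  fwd_pts <- rbind(fwd$C[p1, ], fwd$CA[p2, ], fwd$N[p2, ],
                   fwd$C[p2 - 1L, ], fwd$N[p1 + 1L, ])
  bwd_pts <- rbind(bwd$N[p3, ], bwd$CA[p2, ], bwd$C[p2, ],
                   bwd$N[p2 + 1L, ], bwd$C[p3 - 1L, ])

  half_fwd <- function(CA2t, branch) {
    w <- CA2t - CA1
    roots <- solve_sinusoid(st1 * sum(w * mm1), -st1 * sum(w * nn1),
                            h1 + ct1 * sum(w * bc1))
    if (length(roots) < branch) return(NULL)
    phi1 <- roots[branch]
    C1 <- CA1 - geom$ca_c * ct1 * bc1 +
      geom$ca_c * st1 * (cos(phi1) * mm1 - sin(phi1) * nn1)
    # rotation 1: about N1-CA1 line mapping ref C(p1) onto C1
    ax1 <- bc1
    dth1 <- signed_angle_about(ax1, fwd_pts[1L, ] - CA1, C1 - CA1)
    P <- rotate_about_axis(fwd_pts, CA1, ax1, dth1)
    # rotation 2: about CA1-C1 line mapping CA(p2) onto CA2t
    ax2 <- vunit(C1 - CA1)
    dth2 <- signed_angle_about(ax2, P[2L, ] - CA1, CA2t - CA1)
    P <- rotate_about_axis(P, CA1, ax2, dth2)
    list(C1 = C1, CA2 = P[2L, ], N2 = P[3L, ], Cprev = P[4L, ],
         Nnext1 = P[5L, ])
  }

  half_bwd <- function(CA2t, branch) {
    w <- CA2t - CA3
    roots <- solve_sinusoid(st1 * sum(w * mm3), -st1 * sum(w * nn3),
                            h3 + ct1 * sum(w * bc3))
    if (length(roots) < branch) return(NULL)
    psi3 <- roots[branch]
    N3 <- CA3 - geom$n_ca * ct1 * bc3 +
      geom$n_ca * st1 * (cos(psi3) * mm3 - sin(psi3) * nn3)
    ax1 <- bc3
    dth1 <- signed_angle_about(ax1, bwd_pts[1L, ] - CA3, N3 - CA3)
    P <- rotate_about_axis(bwd_pts, CA3, ax1, dth1)
    ax2 <- vunit(N3 - CA3)
    dth2 <- signed_angle_about(ax2, P[2L, ] - CA3, CA2t - CA3)
    P <- rotate_about_axis(P, CA3, ax2, dth2)
    list(N3 = N3, CA2 = P[2L, ], C2 = P[3L, ], Nnext = P[4L, ],
         Cprev3 = P[5L, ])
  }

  # vectorized residual over a vector of circle angles (NA where the
  # required sinusoid branch has no real root)
  rowdot <- function(A, B) rowSums(A * B)
  rep_row <- function(v, G) matrix(v, G, 3L, byrow = TRUE)
  # rotate rows of Xc (already origin-centred) about per-row unit axes U
  rot_rows <- function(Xc, U, ct, st) {
    Xc * ct + row_cross(U, Xc) * st + U * (rowdot(U, Xc) * (1 - ct))
  }
  half_new_vec <- function(CA2t, branch, CAc, bc, mm, nn, hh, bondlen,
                           ref_move, ref_align) {
    G <- nrow(CA2t)
    CAr <- rep_row(CAc, G)
    w <- CA2t - CAr
    A <- st1 * drop(w %*% mm); B <- -st1 * drop(w %*% nn)
    C <- hh + ct1 * drop(w %*% bc)
    R <- sqrt(A * A + B * B)
    ok <- R > 1e-14 & abs(C) <= R
    base <- atan2(B, A)
    d <- acos(pmin(1, pmax(-1, C / pmax(R, 1e-300))))
    ang <- if (branch == 1L) base + d else base - d
    X1 <- CAr - (bondlen * ct1) * rep_row(bc, G) +
      (bondlen * st1) * (outer(cos(ang), mm) - outer(sin(ang), nn))
    # rotation 1: fixed axis bc through CAc, angle from reference first
    # bond to the new one
    pref <- ref_move$bond - CAc
    qv <- X1 - CAr
    pp <- pref - sum(pref * bc) * bc
    qq <- qv - outer(drop(qv %*% bc), bc)
    dth1 <- atan2(drop(row_cross(rep_row(pp, G), qq) %*% bc),
                  drop(qq %*% pp))
    ct1v <- cos(dth1); st1v <- sin(dth1)
    rot1 <- function(X) {
      Xc <- X - CAc
      outer(ct1v, Xc) + outer(st1v, vcross(bc, Xc)) +
        outer((1 - ct1v) * sum(bc * Xc), bc)
    }
    alignp <- rot1(ref_align)
    movep <- rot1(ref_move$pt)
    # rotation 2: per-row axis along the new first bond
    U <- qv / bondlen
    p2 <- alignp
    q2 <- CA2t - CAr
    p2p <- p2 - U * rowdot(p2, U)
    q2p <- q2 - U * rowdot(q2, U)
    dth2 <- atan2(rowdot(U, row_cross(p2p, q2p)), rowdot(p2p, q2p))
    out <- rot_rows(movep, U, cos(dth2), sin(dth2)) + CAr
    out[!ok, ] <- NA_real_
    out
  }
  resid_vec <- function(av, b1, b3) {
    G <- length(av)
    CA2t <- rep_row(Oc, G) + rc * (outer(cos(av), v1) + outer(sin(av), v2))
    N2new <- half_new_vec(CA2t, b1, CA1, bc1, mm1, nn1, h1, geom$ca_c,
                          list(bond = fwd_pts[1L, ], pt = fwd_pts[3L, ]),
                          fwd_pts[2L, ])
    C2new <- half_new_vec(CA2t, b3, CA3, bc3, mm3, nn3, h3, geom$n_ca,
                          list(bond = bwd_pts[1L, ], pt = bwd_pts[3L, ]),
                          bwd_pts[2L, ])
    bond_angle3(N2new, CA2t, C2new) - geom$ang_n_ca_c
  }
  resid_fun <- function(alpha, b1, b3) resid_vec(alpha, b1, b3)

  assemble <- function(alpha, b1, b3) {
    CA2t <- Oc + rc * (cos(alpha) * v1 + sin(alpha) * v2)
    F <- half_fwd(CA2t, b1); B <- half_bwd(CA2t, b3)
    if (is.null(F) || is.null(B)) return(NULL)
    sol_phi <- phi; sol_psi <- psi
    sol_phi[p1] <- dihedral4(A0, N1, CA1, F$C1)
    sol_psi[p1] <- dihedral4(N1, CA1, F$C1, F$Nnext1)
    sol_phi[p2] <- dihedral4(F$Cprev, F$N2, CA2t, B$C2)
    sol_psi[p2] <- dihedral4(F$N2, CA2t, B$C2, B$Nnext)
    sol_phi[p3] <- dihedral4(B$Cprev3, B$N3, CA3, C3)
    sol_psi[p3] <- dihedral4(B$N3, CA3, C3, N3b)
    chk <- tlc_build_forward(fixed_n_anchor, sol_phi, sol_psi, omega, psi0,
                             omega0, phi_end, geom)
    gap <- max(vnorm(chk$N[L + 1L, ] - fixed_c_anchor[1L, ]),
               vnorm(chk$CA[L + 1L, ] - fixed_c_anchor[2L, ]),
               vnorm(chk$C[L + 1L, ] - fixed_c_anchor[3L, ]))
    tor <- torsions
    tor$phi <- wrap180(sol_phi); tor$psi <- wrap180(sol_psi); tor$omega <- omega
    list(torsions = tor,
         bb = list(N = chk$N[seq_len(L), , drop = FALSE],
                   CA = chk$CA[seq_len(L), , drop = FALSE],
                   C = chk$C[seq_len(L), , drop = FALSE]),
         gap = gap)
  }

  alphas <- seq(0, 2 * pi, length.out = n_scan + 1L)[-(n_scan + 1L)]
  step <- 2 * pi / n_scan
  sols <- list()
  add_root <- function(root, b1, b3) {
    s <- assemble(root, b1, b3)
    if (!is.null(s) && s$gap < gap_tol) sols[[length(sols) + 1L]] <<- s
  }
  # batched bracketing (3 rounds of 33-point vector scans) + secant polish
  refine_root <- function(lo, hi, b1, b3) {
    for (r in 1:3) {
      xs <- seq(lo, hi, length.out = 33L)
      gs <- resid_vec(xs, b1, b3)
      found <- FALSE
      for (k in 1:32) {
        if (!is.finite(gs[k]) || !is.finite(gs[k + 1L])) next
        if (gs[k] == 0) return(xs[k])
        if (gs[k] * gs[k + 1L] < 0) {
          lo <- xs[k]; hi <- xs[k + 1L]; found <- TRUE; break
        }
      }
      if (!found) return(NA_real_)
    }
    x1 <- lo; x2 <- hi
    g1 <- resid_vec(x1, b1, b3); g2 <- resid_vec(x2, b1, b3)
    for (it in 1:10) {
      if (!is.finite(g1) || !is.finite(g2) || g2 == g1) break
      x3 <- x2 - g2 * (x2 - x1) / (g2 - g1)
      if (!is.finite(x3) || x3 < lo - (hi - lo) || x3 > hi + (hi - lo))
        x3 <- (x1 + x2) / 2
      g3 <- resid_vec(x3, b1, b3)
      if (!is.finite(g3)) break
      x1 <- x2; g1 <- g2; x2 <- x3; g2 <- g3
      if (abs(g3) < 1e-12) break
    }
    x2
  }
  # locate the branch-existence edge inside (lo, hi) by nested vector scans
  edge_scan <- function(lo, hi, fin_lo, b1, b3) {
    a_edge <- NA_real_; g_edge <- NA_real_
    for (r in 1:2) {
      xs <- seq(lo, hi, length.out = 33L)
      gs <- resid_vec(xs, b1, b3)
      fin <- is.finite(gs)
      if (fin_lo) {
        k <- which(!fin)[1L]
        if (is.na(k)) { a_edge <- hi; g_edge <- gs[33L]; break }
        if (k == 1L) return(NULL)
        a_edge <- xs[k - 1L]; g_edge <- gs[k - 1L]
        lo <- xs[k - 1L]; hi <- xs[k]
      } else {
        k <- rev(which(!fin))[1L]
        if (is.na(k)) { a_edge <- lo; g_edge <- gs[1L]; break }
        if (k == 33L) return(NULL)
        a_edge <- xs[k + 1L]; g_edge <- gs[k + 1L]
        lo <- xs[k]; hi <- xs[k + 1L]
      }
    }
    if (!is.finite(g_edge)) NULL else list(a = a_edge, g = g_edge)
  }
  for (b1 in 1:2) for (b3 in 1:2) {
    g <- resid_vec(alphas, b1, b3)
    for (k in seq_len(n_scan)) {
      k2 <- if (k == n_scan) 1L else k + 1L
      a_lo <- alphas[k]; a_hi <- alphas[k] + step
      g1 <- g[k]; g2 <- g[k2]
      if (is.finite(g1) && is.finite(g2)) {
        if (g1 == 0) add_root(a_lo, b1, b3)
        else if (g1 * g2 < 0) {
          root <- refine_root(a_lo, a_hi, b1, b3)
          if (is.finite(root)) add_root(root, b1, b3)
        }
      } else if (is.finite(g1) != is.finite(g2)) {
        # a branch appears/vanishes inside this interval: locate the seam
        # and look for a sign change against the near-seam value (solution
        # curves pass continuously between sibling branches there)
        fin_lo <- is.finite(g1)
        edge <- edge_scan(a_lo, a_hi, fin_lo, b1, b3)
        g_base <- if (fin_lo) g1 else g2
        a_base <- if (fin_lo) a_lo else a_hi
        if (!is.null(edge) && g_base * edge$g < 0) {
          root <- refine_root(min(a_base, edge$a), max(a_base, edge$a),
                              b1, b3)
          if (is.finite(root)) add_root(root, b1, b3)
        }
      }
    }
  }
  # de-duplicate (branch boundaries can yield the same solution twice)
  if (length(sols) > 1L) {
    keymat <- t(vapply(sols, function(s)
      c(s$torsions$phi[p], s$torsions$psi[p]), numeric(6)))
    keep <- !duplicated(round(keymat, 3))
    sols <- sols[keep]
  }
  sols
}
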