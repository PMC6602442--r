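# Splicing rebuilt backbone spans into models: shared machinery for the
# structure operators, threading and pool initialization. Side-chain atoms
# of a respliced residue ride along on the rigid N/CA/C frame transform;
# carbonyl oxygens are rebuilt from the new psi torsions.

rebuild_O_range <- function(model, start, end, geom = bb_geom()) {
  n <- n_res(model)
  iN <- atom_index(model, "N"); iCA <- atom_index(model, "CA")
  iC <- atom_index(model, "C"); iO <- atom_index(model, "O")
  for (r in start:end) {
    if (is.na(iO[r])) next
    psi <- if (r < n)
      dihedral4(model$xyz[iN[r], ], model$xyz[iCA[r], ], model$xyz[iC[r], ],
                model$xyz[iN[r + 1L], ])
    else NA_real_
    model$xyz[iO[r], ] <- place_O(model$xyz[iN[r], ], model$xyz[iCA[r], ],
                                  model$xyz[iC[r], ], psi, geom)
  }
  model
}

# Replace backbone N/CA/C of residues start..end with new coordinates
# (matrices with one row per span residue); side chains follow rigidly,
# oxygens are rebuilt.
set_backbone_span <- function(model, start, end, N, CA, C, geom = bb_geom()) {
  iN <- atom_index(model, "N"); iCA <- atom_index(model, "CA")
  iC <- atom_index(model, "C")
  xyz <- model$xyz
  for (r in start:end) {
    k <- r - start + 1L
    old <- rbind(xyz[iN[r], ], xyz[iCA[r], ], xyz[iC[r], ])
    new <- rbind(N[k, ], CA[k, ], C[k, ])
    side <- which(model$atom_resi == r &
                    !(model$atom_name %in% c("N", "CA", "C", "O")))
    if (length(side) && max(abs(old - new)) > 1e-12) {
      tf <- kabsch_superpose(old, new)
      xyz[side, ] <- apply_transform(xyz[side, , drop = FALSE], tf)
    }
    xyz[iN[r], ] <- N[k, ]; xyz[iCA[r], ] <- CA[k, ]; xyz[iC[r], ] <- C[k, ]
  }
  model$xyz <- xyz
  rebuild_O_range(model, max(1L, start - 1L), end, geom)
}

# Torsions of residues start..end plus the join torsions needed to rebuild
# the span between anchors.
span_torsions <- function(model, start, end) {
  tt <- backbone_torsions_raw(model)
  list(loop = tt[start:end, , drop = FALSE],
       psi0 = if (start > 1L) tt$psi[start - 1L] else NA_real_,
       omega0 = if (start > 1L) tt$omega[start - 1L] else NA_real_,
       phi_end = if (end < n_res(model)) tt$phi[end + 1L] else NA_real_)
}

anchor_coords <- function(model, resi) {
  rbind(bb_coords(model, "N")[resi, ], bb_coords(model, "CA")[resi, ],
        bb_coords(model, "C")[resi, ])
}

# Re-close an interior span after its torsions were modified. Returns a list
# of candidate models (one per TLC solution); empty list if closure failed.
close_loop_span <- function(model, start, end, new_torsions, pivots = NULL,
                            n_scan = 360L, geom = bb_geom()) {
  n <- n_res(model)
  stopifnot(start >= 2L, end <= n - 1L, end - start + 1L >= 3L)
  st <- span_torsions(model, start, end)
  tor <- st$loop
  tor$phi <- new_torsions$phi; tor$psi <- new_torsions$psi
  L <- end - start + 1L
  if (is.null(pivots)) pivots <- unique(c(1L, (L + 1L) %/% 2L, L))
  if (length(pivots) < 3L) pivots <- c(1L, 2L, L)
  sols <- triaxial_loop_closure(tor, anchor_coords(model, start - 1L),
                                anchor_coords(model, end + 1L), pivots,
                                psi0 = st$psi0, omega0 = st$omega0,
                                phi_end = st$phi_end, geom = geom,
                                n_scan = n_scan)
  lapply(sols, function(s)
    set_backbone_span(model, start, end, s$bb$N, s$bb$CA, s$bb$C, geom))
}

# Rebuild a terminal span (touching residue 1 or n) from new torsions; no
# closure needed. Interior anchors must remain: 1 <= start, end <= n, and
# the span must touch a terminus.
rebuild_terminal_span <- function(model, start, end, new_torsions,
                                  geom = bb_geom()) {
  n <- n_res(model)
  L <- end - start + 1L
  tt <- backbone_torsions_raw(model)
  phi <- new_torsions$phi; psi <- new_torsions$psi
  omega <- tt$omega[start:end]; omega[is.na(omega)] <- 180
  phi[is.na(phi)] <- tt$phi[start:end][is.na(phi)]
  psi[is.na(psi)] <- tt$psi[start:end][is.na(psi)]
  phi[is.na(phi)] <- -120; psi[is.na(psi)] <- 140
  if (end == n && start >= 2L) {
    bb <- tlc_build_forward(anchor_coords(model, start - 1L), phi, psi, omega,
                            psi0 = tt$psi[start - 1L],
                            omega0 = tt$omega[start - 1L],
                            phi_end = 0, geom = geom)
    sel <- seq_len(L)
  } else if (start == 1L && end <= n - 1L) {
    bb <- tlc_build_backward(anchor_coords(model, end + 1L), phi, psi, omega,
                             phi_end = tt$phi[end + 1L], stop_res = 1L,
                             geom = geom)
    sel <- seq_len(L)
  } else stop("span must touch exactly one terminus")
  set_backbone_span(model, start, end,
                    bb$N[sel, , drop = FALSE], bb$CA[sel, , drop = FALSE],
                    bb$C[sel, , drop = FALSE], geom)
}
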