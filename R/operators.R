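# The six structure-perturbation operators applied to pool members, plus
# the elastic-network normal modes they depend on. Operators never throw on
# sampling failure: they return the input flagged as a no-op so the
# refinement loop can re-draw.

flag_noop <- function(model, noop = TRUE) {
  attr(model, "noop") <- noop
  model
}

#' Was an operator application a no-op?
#' @param model A `protein_model` returned by an operator.
#' @return TRUE if the operator could not be applied.
#' @export
is_noop <- function(model) isTRUE(attr(model, "noop"))

#' Operator context
#'
#' Bundles everything operators need: the residue error profile, fragment
#' and patch libraries, the current pool (for loop-modelling partners), the
#' RNG seed, and per-operator selection weights.
#'
#' @param error_profile A `residue_error_profile`.
#' @param fraglib A `fragment_library` (or NULL).
#' @param patch_library A `patch_library` (or NULL).
#' @param pool A `structure_pool` (or NULL).
#' @param rng_seed Integer seed; operators are deterministic given it.
#' @param weights Named non-negative operator selection weights (normalized
#'   to sum 1); names from [operator_names()].
#' @param config Configuration.
#' @return An `operator_context`.
#' @export
operator_context <- function(error_profile, fraglib = NULL,
                             patch_library = NULL, pool = NULL,
                             rng_seed = 1L, weights = NULL,
                             config = default_config()) {
  nm <- operator_names()
  weights <- weights %||% stats::setNames(rep(1, length(nm)), nm)
  stopifnot(all(weights >= 0), sum(weights) > 0)
  weights <- weights[nm] / sum(weights[nm])
  structure(list(error_profile = error_profile, fraglib = fraglib,
                 patch_library = patch_library, pool = pool,
                 rng_seed = as.integer(rng_seed), weights = weights,
                 config = config),
            class = "operator_context")
}

#' Names of the six structure operators
#' @return Character vector.
#' @export
operator_names <- function() {
  c("fragment_assembly", "loop_modelling", "sidechain_perturbation",
    "normal_mode", "hybridization", "ss_perturbation")
}

# ---------------------------------------------------------------- ENM ----

#' Elastic-network (CA) normal modes
#'
#' Isotropic elastic network on CA atoms: springs on all CA pairs within
#' `cutoff`, energy k (|rij| - |rij0|)^2. The Hessian at the input geometry
#' is assembled and diagonalized; for a connected network exactly six
#' near-zero eigenvalues (rigid-body modes) result.
#'
#' @param model A `protein_model` (>= 4 residues).
#' @param cutoff Spring cutoff in Angstrom (default 10).
#' @param spring Spring constant k.
#' @return An `enm_modes` list: `eigenvalues` (ascending), `eigenvectors`
#'   (3n x 3n, columns match eigenvalues), `cutoff`, `spring`.
#' @export
compute_enm_modes <- function(model, cutoff = 10, spring = 1) {
  CA <- bb_coords(model, "CA")
  n <- nrow(CA)
  if (n < 4L) stop("need at least 4 residues")
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  d <- row_norm(CA[ii, , drop = FALSE] - CA[jj, , drop = FALSE])
  keep <- d < cutoff
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  # connectivity check (BFS)
  adj <- split(c(jj, ii), c(ii, jj))
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[as.character(v)]] %||% integer(0))
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen))
    stop("elastic network disconnected at cutoff ", cutoff,
         " A; increase the cutoff")
  H <- matrix(0, 3L * n, 3L * n)
  for (k in seq_along(ii)) {
    u <- (CA[ii[k], ] - CA[jj[k], ]) / d[k]
    B <- 2 * spring * tcrossprod(u)
    ai <- (3L * ii[k] - 2L):(3L * ii[k]); aj <- (3L * jj[k] - 2L):(3L * jj[k])
    H[ai, ai] <- H[ai, ai] + B; H[aj, aj] <- H[aj, aj] + B
    H[ai, aj] <- H[ai, aj] - B; H[aj, ai] <- H[aj, ai] - B
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(eigenvalues = e$values[ord],
                 eigenvectors = e$vectors[, ord, drop = FALSE],
                 cutoff = cutoff, spring = spring),
            class = "enm_modes")
}

# --------------------------------------------------- side-chain repack ----

# residues with rotatable side chains (atoms beyond CB)
rotatable_residues <- function(model) {
  side <- !(model$atom_name %in% c("N", "CA", "C", "O", "CB"))
  sort(unique(model$atom_resi[side]))
}

# steric clash energy of one residue's side atoms against all other atoms
local_steric <- function(xyz, side_idx, other_idx, rad) {
  if (!length(side_idx) || !length(other_idx)) return(0)
  A <- xyz[side_idx, , drop = FALSE]; B <- xyz[other_idx, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  r0 <- outer(rad[side_idx], rad[other_idx], `+`)
  sum(pmax(1 - d / r0, 0)^2)
}

#' Greedy side-chain repack on a coarse rotamer grid
#'
#' Visits residues with rotatable side chains in seeded random order and
#' assigns the chi1 (and chi2, when a CG atom exists) rotamer from the grid
#' {-60, 60, 180} degrees that minimizes the residue's steric clash energy
#' against the rest of the structure. Backbone coordinates are untouched.
#'
#' @param model A `protein_model`.
#' @param config Configuration.
#' @param seed RNG seed (residue visit order).
#' @return The repacked `protein_model`.
#' @export
repack_sidechains <- function(model, config = default_config(), seed = 1L) {
  rot <- rotatable_residues(model)
  if (!length(rot)) return(model)
  elem <- element_of(model$atom_name)
  rad <- VDW_RADII[elem]; rad[is.na(rad)] <- 1.7
  grid <- c(-60, 60, 180)
  with_seed(seed, {
    for (r in sample(rot)) {
      at <- which(model$atom_resi == r)
      nm <- model$atom_name[at]
      iCA <- at[nm == "CA"]; iCB <- at[nm == "CB"]; iCG <- at[nm == "CG"]
      if (!length(iCB)) next
      beyond_cb <- at[!(nm %in% c("N", "CA", "C", "O", "CB"))]
      if (!length(beyond_cb)) next
      other <- setdiff(seq_len(nrow(model$xyz)), at)
      ax1_o <- model$xyz[iCA, ]; ax1 <- vunit(model$xyz[iCB, ] - ax1_o)
      cur_chi1 <- 0
      best <- NULL; best_e <- Inf
      for (c1 in grid) {
        xyz1 <- model$xyz
        xyz1[beyond_cb, ] <- rotate_about_axis(
          xyz1[beyond_cb, , drop = FALSE], ax1_o, ax1, deg2rad(c1))
        chi2s <- if (length(iCG)) grid else 0
        for (c2 in chi2s) {
          xyz2 <- xyz1
          if (length(iCG) && c2 != 0) {
            beyond_cg <- at[!(nm %in% c("N", "CA", "C", "O", "CB", "CG"))]
            if (length(beyond_cg)) {
              ax2_o <- xyz1[iCB, ]; ax2 <- vunit(xyz1[iCG, ] - ax2_o)
              xyz2[beyond_cg, ] <- rotate_about_axis(
                xyz2[beyond_cg, , drop = FALSE], ax2_o, ax2, deg2rad(c2))
            }
          }
          e <- local_steric(xyz2, beyond_cb, other, rad)
          if (e < best_e) { best_e <- e; best <- xyz2 }
        }
      }
      if (!is.null(best)) model$xyz <- best
    }
    model
  })
}

#' Side-chain perturbation operator
#'
#' Repacks side chains on the coarse rotamer grid; backbone coordinates are
#' bit-identical to the input. No-op when the model has no rotatable side
#' chains.
#'
#' @param model A `protein_model`.
#' @param context An `operator_context`.
#' @return A `protein_model` (check [is_noop()]).
#' @export
op_sidechain_perturbation <- function(model, context) {
  if (!length(rotatable_residues(model))) return(flag_noop(model))
  out <- repack_sidechains(model, context$config, seed = context$rng_seed)
  flag_noop(out, FALSE)
}

# ------------------------------------------------- torsion-space moves ----

# torsions without chain validation (operators handle transient states)
backbone_torsions_raw <- function(model) {
  n <- n_res(model)
  N <- bb_coords(model, "N"); CA <- bb_coords(model, "CA")
  C <- bb_coords(model, "C")
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

# Replace the torsions of span s..e and re-close (interior spans) or
# rebuild freely (terminal spans). Returns NULL on closure failure.
apply_span_torsions <- function(model, s, e, new_phi, new_psi, config,
                                pick_seed = 1L) {
  n <- n_res(model)
  tor <- data.frame(phi = new_phi, psi = new_psi)
  if (s >= 2L && e <= n - 1L) {
    if (e - s + 1L < 3L) {
      # widen to the TLC minimum
      while (e - s + 1L < 3L) if (s > 2L) s <- s - 1L else e <- e + 1L
      cur <- backbone_torsions_raw(model)
      tor <- data.frame(phi = cur$phi[s:e], psi = cur$psi[s:e])
      tor$phi[seq_along(new_phi)] <- new_phi
      tor$psi[seq_along(new_psi)] <- new_psi
    }
    cands <- close_loop_span(model, s, e, tor, n_scan = config$tlc_grid)
    if (!length(cands)) return(NULL)
    k <- with_seed(pick_seed, sample.int(length(cands), 1L))
    cands[[k]]
  } else {
    rebuild_terminal_span(model, max(1L, s), min(n, e), tor)
  }
}

#' Fragment-assembly operator
#'
#' Chooses a backbone window with probability proportional to the predicted
#' residue error, replaces its torsions with those of a random library
#' fragment, and re-closes the chain by triaxial loop closure (terminal
#' windows are rebuilt freely). Residues outside the window (other than the
#' closure pivots) keep their torsions; coordinates outside the span are
#' unchanged.
#'
#' @param model A `protein_model`.
#' @param context An `operator_context` with `error_profile` and `fraglib`.
#' @return A `protein_model` (check [is_noop()]).
#' @export
op_fragment_assembly <- function(model, context) {
  lib <- context$fraglib
  if (is.null(lib) || nrow(lib$phi) == 0L) return(flag_noop(model))
  w <- lib$window
  n <- n_res(model)
  if (w > n - 2L) return(flag_noop(model))
  err <- context$error_profile$predicted_error
  nwin <- n - w + 1L
  wts <- vapply(seq_len(nwin), function(j) mean(err[j:(j + w - 1L)]),
                numeric(1))
  if (all(wts <= 0)) wts <- rep(1, nwin)
  cfg <- context$config
  with_seed(context$rng_seed, {
    for (att in seq_len(cfg$tlc_attempts)) {
      j <- sample.int(nwin, 1L, prob = wts)
      f <- sample.int(nrow(lib$phi), 1L)
      out <- apply_span_torsions(model, j, j + w - 1L, lib$phi[f, ],
                                 lib$psi[f, ], cfg,
                                 pick_seed = stats::runif(1L, 1, 1e8))
      if (!is.null(out)) return(flag_noop(out, FALSE))
    }
    flag_noop(model)
  })
}

#' Loop-modelling operator
#'
#' Either mixes the backbone torsions of a selected ULR with those of
#' another pool structure (circular interpolation by `mix_coeff`) or
#' mutates them with seeded Gaussian noise, then re-closes by TLC.
#'
#' @param model A `protein_model`.
#' @param partner A same-length `protein_model` (mix mode).
#' @param ulr `c(start, end)` residue range to remodel.
#' @param mode `"mix"` or `"mutate"`.
#' @param mix_coeff Interpolation coefficient in [0, 1] (0 = parent,
#'   1 = partner).
#' @param context An `operator_context`.
#' @return A `protein_model` (check [is_noop()]).
#' @export
op_loop_modelling <- function(model, partner, ulr,
                              mode = c("mix", "mutate"), mix_coeff = 0.5,
                              context) {
  mode <- match.arg(mode)
  s <- ulr[1L]; e <- ulr[2L]
  stopifnot(s >= 1L, e <= n_res(model), s <= e)
  cur <- backbone_torsions_raw(model)
  idx <- s:e
  cfg <- context$config
  with_seed(context$rng_seed, {
    if (mode == "mix") {
      stopifnot(n_res(partner) == n_res(model))
      ptor <- backbone_torsions_raw(partner)
      new_phi <- wrap180(cur$phi[idx] + mix_coeff *
                           wrap180(ptor$phi[idx] - cur$phi[idx]))
      new_psi <- wrap180(cur$psi[idx] + mix_coeff *
                           wrap180(ptor$psi[idx] - cur$psi[idx]))
    } else {
      new_phi <- wrap180(cur$phi[idx] + stats::rnorm(length(idx), 0,
                                                     cfg$mutate_sigma))
      new_psi <- wrap180(cur$psi[idx] + stats::rnorm(length(idx), 0,
                                                     cfg$mutate_sigma))
    }
    out <- apply_span_torsions(model, s, e, new_phi, new_psi, cfg,
                               pick_seed = stats::runif(1L, 1, 1e8))
    if (is.null(out)) flag_noop(model) else flag_noop(out, FALSE)
  })
}

#' Normal-mode perturbation operator
#'
#' Displaces the CA trace along one randomly chosen low-frequency
#' elastic-network mode with the requested RMS amplitude, carries each
#' residue rigidly with its CA, and restores covalent geometry by a short
#' relaxation anchored at the displaced CA positions.
#'
#' @param model A `protein_model`.
#' @param context An `operator_context`.
#' @param amplitude RMS CA displacement in Angstrom (0 = identity).
#' @param n_low_modes Number of lowest non-rigid modes to draw from.
#' @return A `protein_model`; attribute `nm_displacement` holds the applied
#'   CA displacement matrix.
#' @export
op_normal_mode_perturbation <- function(model, context,
                                        amplitude = NULL,
                                        n_low_modes = NULL) {
  cfg <- context$config
  amplitude <- amplitude %||% cfg$nm_amplitude
  n_low_modes <- n_low_modes %||% cfg$n_low_modes
  if (amplitude == 0) return(flag_noop(model, FALSE))
  modes <- tryCatch(compute_enm_modes(model, cfg$enm_cutoff, cfg$enm_spring),
                    error = function(e) NULL)
  if (is.null(modes)) return(flag_noop(model))
  n <- n_res(model)
  nm_avail <- min(n_low_modes, 3L * n - 6L)
  with_seed(context$rng_seed, {
    k <- 6L + sample.int(nm_avail, 1L)
    v <- matrix(modes$eigenvectors[, k], n, 3L, byrow = TRUE)
    v <- v * (amplitude / sqrt(mean(rowSums(v^2))))
    out <- model
    for (r in seq_len(n)) {
      at <- which(model$atom_resi == r)
      out$xyz[at, ] <- out$xyz[at, , drop = FALSE] +
        matrix(v[r, ], length(at), 3L, byrow = TRUE)
    }
    # restore covalent geometry around the displaced CA trace
    anch <- structure(list(ca_anchor = bb_coords(out, "CA"),
                           ca_pairs = data.frame(i = integer(0), j = integer(0),
                                                 target = numeric(0)),
                           no_pairs = data.frame(i = integer(0), j = integer(0),
                                                 target = numeric(0)),
                           form = "harmonic", neglect_fraction = 0,
                           lorentz_c = cfg$lorentz_c),
                      class = "restraint_set")
    # direct geometry regularization (not an energy relaxation): minimize
    # bonded strain + smooth terms under the displaced-CA anchors
    cache <- make_energy_cache(out, cfg)
    obj <- relax_objective(out, cache, anch, cfg)
    res <- tryCatch(stats::optim(as.numeric(out$xyz), obj$fn, obj$gr,
                                 method = "L-BFGS-B",
                                 control = list(maxit = cfg$nm_relax_steps,
                                                factr = 1e7)),
                    error = function(e) NULL)
    if (is.null(res)) return(flag_noop(model))
    out2 <- out
    out2$xyz <- matrix(res$par, nrow(out$xyz), 3L)
    if (!chain_intact(out2)) return(flag_noop(model))
    out2 <- flag_noop(out2, FALSE)
    attr(out2, "nm_displacement") <- v
    attr(out2, "nm_mode_index") <- k
    out2
  })
}

# re-close the junctions around a rigidly replaced span s..e; returns NULL
# on failure. `phi_s` is the phi to impose at residue s (N-side junction),
# `psi_e`/`omega_e` the join torsions at residue e (C-side junction).
reclose_junctions <- function(model, s, e, phi_s, psi_e, config,
                              flank = 4L, pick_seed = 1L) {
  n <- n_res(model)
  cur <- backbone_torsions_raw(model)
  # N-side
  if (s > 1L) {
    lo <- s - flank
    if (lo >= 2L) {
      st <- list(loop = cur[lo:(s - 1L), ],
                 psi0 = cur$psi[lo - 1L], omega0 = cur$omega[lo - 1L])
      L <- flank
      piv <- unique(c(1L, (L + 1L) %/% 2L, L)); if (length(piv) < 3L) piv <- c(1L, 2L, L)
      tor <- st$loop; tor$omega[L] <- 180
      sols <- triaxial_loop_closure(tor, anchor_coords(model, lo - 1L),
                                    anchor_coords(model, s), piv,
                                    psi0 = st$psi0, omega0 = st$omega0,
                                    phi_end = phi_s, n_scan = config$tlc_grid)
      if (!length(sols)) return(NULL)
      k <- with_seed(pick_seed, sample.int(length(sols), 1L))
      sb <- sols[[k]]$bb
      model <- set_backbone_span(model, lo, s - 1L, sb$N, sb$CA, sb$C)
    } else {
      tor <- cur[1:(s - 1L), ]
      model <- rebuild_terminal_span(model, 1L, s - 1L,
                                     data.frame(phi = tor$phi, psi = tor$psi))
    }
  }
  # C-side
  if (e < n) {
    hi <- e + flank
    if (hi <= n - 1L) {
      L <- flank
      piv <- unique(c(1L, (L + 1L) %/% 2L, L)); if (length(piv) < 3L) piv <- c(1L, 2L, L)
      tor <- cur[(e + 1L):hi, ]; tor$omega[L] <- cur$omega[hi]
      sols <- triaxial_loop_closure(tor, anchor_coords(model, e),
                                    anchor_coords(model, hi + 1L), piv,
                                    psi0 = psi_e, omega0 = 180,
                                    phi_end = cur$phi[hi + 1L],
                                    n_scan = config$tlc_grid)
      if (!length(sols)) return(NULL)
      k <- with_seed(pick_seed + 1L, sample.int(length(sols), 1L))
      sb <- sols[[k]]$bb
      model <- set_backbone_span(model, e + 1L, hi, sb$N, sb$CA, sb$C)
    } else {
      tor <- cur[(e + 1L):n, ]
      model <- rebuild_terminal_span(model, e + 1L, n,
                                     data.frame(phi = tor$phi, psi = tor$psi))
    }
  }
  if (!chain_intact(model)) return(NULL)
  model
}

#' Structure-hybridization operator
#'
#' Copies a random backbone patch harvested from optimized threaded
#' homologs into the model: the donor patch is superposed via its flanking
#' anchor residues (two on each side), the span is replaced, and the
#' junction loops are re-closed by TLC. No-op when the patch library is
#' empty or closure fails.
#'
#' @param model A `protein_model`.
#' @param context An `operator_context` with `patch_library`.
#' @return A `protein_model` (check [is_noop()]).
#' @export
op_hybridization <- function(model, context) {
  pl <- context$patch_library
  if (is.null(pl) || !length(pl$patches)) return(flag_noop(model))
  cfg <- context$config
  n <- n_res(model)
  with_seed(context$rng_seed, {
    for (att in seq_len(5L)) {
      p <- pl$patches[[sample.int(length(pl$patches), 1L)]]
      s <- p$range[1L]; e <- p$range[2L]
      if (e > n) next
      fl <- c(max(1L, s - 2L):(s - 1L), (e + 1L):min(n, e + 2L))
      fl <- fl[fl >= 1L & fl <= n & (fl < s | fl > e)]
      if (length(fl) < 2L || is.null(p$flank)) next
      fk <- p$flank[p$flank$resi %in% fl, ]
      if (nrow(fk) < 2L) next
      donor_pts <- as.matrix(fk[, c("x", "y", "z")])
      model_pts <- do.call(rbind, lapply(seq_len(nrow(fk)), function(q) {
        bb_coords(model, fk$atom[q])[fk$resi[q], ]
      }))
      tf <- kabsch_superpose(donor_pts, model_pts)
      Nn <- apply_transform(p$bb$N, tf); CAn <- apply_transform(p$bb$CA, tf)
      Cn <- apply_transform(p$bb$C, tf)
      out <- set_backbone_span(model, s, e, Nn, CAn, Cn)
      donor_tor <- p$torsions
      out <- reclose_junctions(out, s, e, phi_s = donor_tor$phi_s,
                               psi_e = donor_tor$psi_e, config = cfg,
                               pick_seed = stats::runif(1L, 1, 1e8))
      if (!is.null(out)) return(flag_noop(out, FALSE))
    }
    flag_noop(model)
  })
}

#' Secondary-structure perturbation operator
#'
#' Rotates and translates one randomly chosen secondary-structure chunk
#' (>= 4 consecutive H or E residues) rigidly about its centroid (rotation
#' up to `max_rot` degrees, translation up to `max_trans` Angstrom), then
#' re-closes the flanking loops by TLC. Chunk-internal geometry is
#' preserved exactly. No-op when there is no chunk or closure fails.
#'
#' @param model A `protein_model`.
#' @param context An `operator_context`.
#' @param max_rot Maximum rotation (degrees).
#' @param max_trans Maximum translation (Angstrom).
#' @return A `protein_model` (check [is_noop()]).
#' @export
op_ss_perturbation <- function(model, context, max_rot = NULL,
                               max_trans = NULL) {
  cfg <- context$config
  max_rot <- max_rot %||% cfg$ss_max_rot
  max_trans <- max_trans %||% cfg$ss_max_trans
  chunks <- ss_chunks(assign_secondary_structure(model))
  if (!length(chunks)) return(flag_noop(model))
  if (max_rot == 0 && max_trans == 0) return(flag_noop(model, FALSE))
  cur <- backbone_torsions_raw(model)
  n <- n_res(model)
  with_seed(context$rng_seed, {
    for (att in seq_len(5L)) {
      ch <- chunks[[sample.int(length(chunks), 1L)]]
      s <- ch[1L]; e <- ch[2L]
      at <- which(model$atom_resi %in% s:e)
      ctr <- colMeans(model$xyz[model$atom_resi %in% s:e &
                                  model$atom_name == "CA", , drop = FALSE])
      ax <- vunit(stats::rnorm(3L))
      ang <- stats::runif(1L, -max_rot, max_rot)
      tr <- stats::runif(3L, -1, 1)
      if (vnorm(tr) > 0) tr <- tr / vnorm(tr) * stats::runif(1L, 0, max_trans)
      out <- model
      out$xyz[at, ] <- rotate_about_axis(out$xyz[at, , drop = FALSE], ctr,
                                         ax, deg2rad(ang))
      out$xyz[at, ] <- sweep(out$xyz[at, , drop = FALSE], 2L, tr, `+`)
      out <- reclose_junctions(out, s, e, phi_s = cur$phi[s],
                               psi_e = cur$psi[e], config = cfg,
                               pick_seed = stats::runif(1L, 1, 1e8))
      if (!is.null(out)) return(flag_noop(out, FALSE))
    }
    flag_noop(model)
  })
}

#' Apply a named operator
#'
#' Dispatcher used by the refinement loop; draws operator-specific inputs
#' (ULR, partner, mode) from the context where needed.
#'
#' @param name One of [operator_names()].
#' @param model A `protein_model`.
#' @param context An `operator_context`.
#' @return A `protein_model` (check [is_noop()]).
#' @export
apply_operator <- function(name, model, context) {
  switch(name,
    fragment_assembly = op_fragment_assembly(model, context),
    sidechain_perturbation = op_sidechain_perturbation(model, context),
    normal_mode = op_normal_mode_perturbation(model, context),
    hybridization = op_hybridization(model, context),
    ss_perturbation = op_ss_perturbation(model, context),
    loop_modelling = {
      ulrs <- context$error_profile$ulrs
      if (!length(ulrs)) return(flag_noop(model))
      pool <- context$pool
      with_seed(context$rng_seed, {
        u <- ulrs[[sample.int(length(ulrs), 1L)]]
        partner <- if (!is.null(pool) && length(pool$members) > 1L)
          pool$members[[sample.int(length(pool$members), 1L)]]$model
        else model
        mode <- sample(c("mix", "mutate"), 1L)
        ctx2 <- context
        ctx2$rng_seed <- split_seed(context$rng_seed, 17L)
        op_loop_modelling(model, partner, u, mode,
                          mix_coeff = context$config$mix_coeff, ctx2)
      })
    },
    stop("unknown operator: ", name))
}
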