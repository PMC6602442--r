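# Composite surrogate energy: soft-sphere sterics, backbone N-O hydrogen-bond
# reward, coarse Ramachandran statistics, compactness, and input-derived
# restraints (harmonic or Lorentzian, with worst-fraction neglect). Also the
# restrained Cartesian relaxation that stands in for short MD runs.

#' Build the restraint set from a starting structure
#'
#' Restraints encode the input model: one Cartesian CA anchor per residue,
#' all CA-CA pair distances with sequence separation >= 4 below 12 Angstrom,
#' and all backbone N-O pair distances below 3.5 Angstrom (separation >= 2,
#' the hydrogen-bond network). Targets equal the input-model values.
#'
#' @param initial A validated `protein_model`.
#' @param form `"harmonic"` or `"lorentzian"`.
#' @param config Configuration ([default_config()]); supplies cutoffs and
#'   the neglect fraction.
#' @return A `restraint_set` with fields `ca_anchor`, `ca_pairs`,
#'   `no_pairs`, `form`, `neglect_fraction`.
#' @export
build_restraints <- function(initial, form = NULL, config = default_config()) {
  form <- form %||% config$restraint_form
  stopifnot(form %in% c("harmonic", "lorentzian"))
  CA <- bb_coords(initial, "CA")
  n <- nrow(CA)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- (jj - ii) >= config$ca_pair_min_sep
  d <- row_norm(CA[ii[keep], , drop = FALSE] - CA[jj[keep], , drop = FALSE])
  near <- d < config$ca_pair_max_dist
  ca_pairs <- data.frame(i = ii[keep][near], j = jj[keep][near],
                         target = d[near])

  Nx <- bb_coords(initial, "N"); Ox <- bb_coords(initial, "O")
  gi <- rep(seq_len(n), each = n); gj <- rep(seq_len(n), times = n)
  sep_ok <- abs(gi - gj) >= 2L
  dno <- row_norm(Nx[gi[sep_ok], , drop = FALSE] - Ox[gj[sep_ok], , drop = FALSE])
  hb <- dno < config$no_pair_max_dist & is.finite(dno)
  no_pairs <- data.frame(i = gi[sep_ok][hb], j = gj[sep_ok][hb],
                         target = dno[hb])

  structure(list(ca_anchor = CA, ca_pairs = ca_pairs, no_pairs = no_pairs,
                 form = form, neglect_fraction = config$neglect_fraction,
                 lorentz_c = config$lorentz_c),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %s form, %d CA anchors, %d CA-CA pairs, %d N-O pairs, neglect %.0f%%\n",
              x$form, nrow(x$ca_anchor), nrow(x$ca_pairs), nrow(x$no_pairs),
              100 * x$neglect_fraction))
  invisible(x)
}

# penalty of a vector of deviations under the chosen functional form
restraint_form_penalty <- function(dev, form, c_soft) {
  if (form == "harmonic") dev^2 else dev^2 / (dev^2 + c_soft^2)
}

restraint_form_dpenalty <- function(dev, form, c_soft) {
  if (form == "harmonic") 2 * dev
  else 2 * dev * c_soft^2 / (dev^2 + c_soft^2)^2
}

# indices of restraints KEPT after dropping the worst ceil(f * N)
neglect_keep <- function(pen, fraction) {
  N <- length(pen)
  if (N == 0L || fraction <= 0) return(seq_len(N))
  ndrop <- ceiling(fraction * N)
  if (ndrop >= N) return(integer(0))
  order(pen)[seq_len(N - ndrop)]
}

# full restraint evaluation; optionally with gradient w.r.t. all atoms
restraint_eval <- function(restraints, model, want_grad = FALSE) {
  r <- restraints
  n <- n_res(model)
  if (nrow(r$ca_anchor) != n) stop("restraint indices do not match model")
  iCA <- atom_index(model, "CA"); iN <- atom_index(model, "N")
  iO <- atom_index(model, "O")
  G <- if (want_grad) matrix(0, nrow(model$xyz), 3L) else NULL
  total <- 0

  # CA anchors act in a superposed frame
  CA <- model$xyz[iCA, , drop = FALSE]
  tf <- kabsch_superpose(CA, r$ca_anchor)
  CAp <- apply_transform(CA, tf)
  dvec <- CAp - r$ca_anchor
  dev <- row_norm(dvec)
  pen <- restraint_form_penalty(dev, r$form, r$lorentz_c)
  keep <- neglect_keep(pen, r$neglect_fraction)
  total <- total + sum(pen[keep])
  if (want_grad && length(keep)) {
    dpen <- restraint_form_dpenalty(dev[keep], r$form, r$lorentz_c)
    safe <- pmax(dev[keep], 1e-12)
    W <- (dpen / safe) * dvec[keep, , drop = FALSE]
    # back-rotate into the model frame (rotation treated as fixed)
    G[iCA[keep], ] <- G[iCA[keep], ] + W %*% t(tf$rotation)
  }

  pair_term <- function(P, ia, ja) {
    if (nrow(P) == 0L) return(invisible(NULL))
    dx <- model$xyz[ia, , drop = FALSE] - model$xyz[ja, , drop = FALSE]
    dist <- row_norm(dx)
    dlt <- dist - P$target
    pen <- restraint_form_penalty(dlt, r$form, r$lorentz_c)
    keep <- neglect_keep(pen, r$neglect_fraction)
    total <<- total + sum(pen[keep])
    if (want_grad && length(keep)) {
      dpen <- restraint_form_dpenalty(dlt[keep], r$form, r$lorentz_c)
      W <- (dpen / pmax(dist[keep], 1e-12)) * dx[keep, , drop = FALSE]
      S <- rowsum(rbind(W, -W), c(ia[keep], ja[keep]))
      rows <- as.integer(rownames(S))
      G[rows, ] <<- G[rows, ] + S
    }
  }
  pair_term(r$ca_pairs, iCA[r$ca_pairs$i], iCA[r$ca_pairs$j])
  pair_term(r$no_pairs, iN[r$no_pairs$i], iO[r$no_pairs$j])
  list(value = total, grad = G)
}

#' Restraint penalty of a model
#'
#' Per-restraint deviation d gives penalty d^2 (harmonic) or
#' d^2/(d^2 + c^2) (Lorentzian, softness c). Within each restraint class
#' (CA anchors, CA-CA pairs, N-O pairs) the worst ceil(f*N) penalties are
#' dropped before summing, re-evaluated at every call. CA-anchor deviations
#' are measured after superposing the current CA trace onto the anchors.
#'
#' @param restraints A `restraint_set`.
#' @param model A `protein_model` with matching residue count.
#' @return Total penalty (energy units).
#' @export
restraint_penalty <- function(restraints, model) {
  restraint_eval(restraints, model, want_grad = FALSE)$value
}

# coarse Ramachandran frequency table: -log f per residue
RAMA_BASINS <- list(
  helix = list(phi = c(-160, -20), psi = c(-120, 30), f = 0.40),
  sheet = list(phi = c(-180, -20), psi = c(60, 180), f = 0.30),
  sheet2 = list(phi = c(-180, -20), psi = c(-180, -170), f = 0.30),
  lalpha = list(phi = c(20, 100), psi = c(-60, 100), f = 0.08),
  other_neg = list(phi = c(-180, 0), psi = c(-180, 180), f = 0.15)
)
RAMA_F_FLOOR <- 0.02

rama_neglog <- function(phi, psi) {
  f <- rep(RAMA_F_FLOOR, length(phi))
  for (b in rev(RAMA_BASINS)) {   # later (more specific) basins override
    hit <- !is.na(phi) & !is.na(psi) &
      phi >= b$phi[1L] & phi < b$phi[2L] & psi >= b$psi[1L] & psi < b$psi[2L]
    f[hit] <- b$f
  }
  f[is.na(phi) | is.na(psi)] <- 1
  -log(f)
}

# pair topology and bonded-surrogate cache for one model
make_energy_cache <- function(model, config) {
  natom <- nrow(model$xyz)
  elem <- element_of(model$atom_name)
  rad <- VDW_RADII[elem]; rad[is.na(rad)] <- 1.7
  resi <- model$atom_resi
  ii <- rep(seq_len(natom - 1L), times = (natom - 1L):1L)
  jj <- sequence((natom - 1L):1L) + ii
  nb <- abs(resi[ii] - resi[jj]) >= 2L
  st_i <- ii[nb]; st_j <- jj[nb]
  r0 <- rad[st_i] + rad[st_j]

  iN <- atom_index(model, "N"); iO <- atom_index(model, "O")
  n <- n_res(model)
  gi <- rep(seq_len(n), each = n); gj <- rep(seq_len(n), times = n)
  hb_ok <- abs(gi - gj) >= 2L & !is.na(iN[gi]) & !is.na(iO[gj])
  hb_i <- iN[gi[hb_ok]]; hb_j <- iO[gj[hb_ok]]

  iCA <- atom_index(model, "CA"); iC <- atom_index(model, "C")

  list(natom = natom, st_i = st_i, st_j = st_j, r0 = r0,
       hb_i = hb_i, hb_j = hb_j, ca = iCA, iN = iN, iC = iC,
       bonded = bonded_terms(model, config))
}

# ideal-geometry derived distances, computed once from a NeRF-built fragment
ideal_distances <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tor <- data.frame(resi = 1:2, phi = c(NA, -57), psi = c(-47, NA),
                      omega = c(180, NA))
    m <- rebuild_backbone_from_torsions(tor, default_anchor())
    al <- residue_atoms(m)
    d <- function(a, b) vnorm(a - b)
    cache <<- list(
      n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
      n_c = d(al[[1L]]$N, al[[1L]]$C), ca_o = d(al[[1L]]$CA, al[[1L]]$O),
      o_n1 = d(al[[1L]]$O, al[[2L]]$N), ca_n1 = d(al[[1L]]$CA, al[[2L]]$N),
      c_ca1 = d(al[[1L]]$C, al[[2L]]$CA), ca_ca1 = d(al[[1L]]$CA, al[[2L]]$CA),
      n_cb = d(al[[1L]]$N, al[[1L]]$CB), c_cb = d(al[[1L]]$C, al[[1L]]$CB))
    cache
  }
})

# distance-harmonic surrogate for bonds/angles/omega planarity
bonded_terms <- function(model, config) {
  idd <- ideal_distances()
  iN <- atom_index(model, "N"); iCA <- atom_index(model, "CA")
  iC <- atom_index(model, "C"); iO <- atom_index(model, "O")
  iCB <- atom_index(model, "CB")
  n <- n_res(model)
  ii <- integer(0); jj <- integer(0); tt <- numeric(0); kk <- numeric(0)
  add <- function(a, b, target, k) {
    ok <- !is.na(a) & !is.na(b)
    ii <<- c(ii, a[ok]); jj <<- c(jj, b[ok])
    tt <<- c(tt, rep(target, sum(ok))); kk <<- c(kk, rep(k, sum(ok)))
  }
  nx <- seq_len(n - 1L)
  add(iN, iCA, idd$n_ca, config$k_bond)
  add(iCA, iC, idd$ca_c, config$k_bond)
  add(iC, iO, idd$c_o, config$k_bond)
  add(iC[nx], iN[nx + 1L], idd$c_n, config$k_bond)
  add(iCA, iCB, idd$ca_cb, config$k_bond)
  add(iN, iC, idd$n_c, config$k_13)
  add(iCA, iO, idd$ca_o, config$k_13)
  add(iO[nx], iN[nx + 1L], idd$o_n1, config$k_13)
  add(iCA[nx], iN[nx + 1L], idd$ca_n1, config$k_13)
  add(iC[nx], iCA[nx + 1L], idd$c_ca1, config$k_13)
  add(iN, iCB, idd$n_cb, config$k_13)
  add(iC, iCB, idd$c_cb, config$k_13)
  add(iCA[nx], iCA[nx + 1L], idd$ca_ca1, config$k_14)
  # side chains beyond CB: hold current intra-residue geometry
  side <- which(!(model$atom_name %in% c("N", "CA", "C", "O", "CB")))
  if (length(side)) {
    for (r in unique(model$atom_resi[side])) {
      at <- which(model$atom_resi == r & !(model$atom_name %in% c("N", "C", "O")))
      if (length(at) < 2L) next
      cmb <- utils::combn(at, 2L)
      d <- row_norm(model$xyz[cmb[1L, ], , drop = FALSE] -
                      model$xyz[cmb[2L, ], , drop = FALSE])
      near <- d < 2.9
      ii <- c(ii, cmb[1L, near]); jj <- c(jj, cmb[2L, near])
      tt <- c(tt, d[near])
      kk <- c(kk, ifelse(d[near] < 1.9, config$k_bond, config$k_13))
    }
  }
  list(i = ii, j = jj, target = tt, k = kk)
}

# term-by-term evaluation; gradient excludes the piecewise-constant
# Ramachandran statistics term
energy_terms <- function(xyz, model, cache, restraints, config,
                         want_grad = FALSE, include_bonded = FALSE,
                         want_torsion = TRUE) {
  G <- if (want_grad) matrix(0, cache$natom, 3L) else NULL
  acc <- function(ia, ja, coef, dx) {
    S <- rowsum(rbind(coef * dx, -coef * dx), c(ia, ja))
    rows <- as.integer(rownames(S))
    G[rows, ] <<- G[rows, ] + S
  }
  m2 <- model; m2$xyz <- xyz

  # steric soft-sphere
  dx <- xyz[cache$st_i, , drop = FALSE] - xyz[cache$st_j, , drop = FALSE]
  r <- row_norm(dx)
  ov <- which(r < cache$r0)
  steric <- sum((1 - r[ov] / cache$r0[ov])^2)
  if (want_grad && length(ov)) {
    coef <- config$w_steric * (-2) * (1 - r[ov] / cache$r0[ov]) /
      (cache$r0[ov] * pmax(r[ov], 1e-9))
    acc(cache$st_i[ov], cache$st_j[ov], coef, dx[ov, , drop = FALSE])
  }

  # backbone N-O hydrogen-bond reward
  hbond <- 0
  if (length(cache$hb_i)) {
    dxh <- xyz[cache$hb_i, , drop = FALSE] - xyz[cache$hb_j, , drop = FALSE]
    rh <- row_norm(dxh)
    eh <- exp(-(rh - config$hbond_center)^2 / (2 * config$hbond_sigma^2))
    hbond <- -sum(eh)
    if (want_grad) {
      coef <- config$w_hbond * eh * (rh - config$hbond_center) /
        (config$hbond_sigma^2 * pmax(rh, 1e-9))
      acc(cache$hb_i, cache$hb_j, coef, dxh)
    }
  }

  # compactness on CA
  CA <- xyz[cache$ca, , drop = FALSE]
  nres <- nrow(CA)
  ctr <- colMeans(CA)
  dev2 <- rowSums(sweep(CA, 2L, ctr)^2)
  rg <- sqrt(mean(dev2))
  rg_t <- config$rg_coef * nres^config$rg_exp
  compact <- (rg - rg_t)^2
  if (want_grad && rg > 1e-9) {
    coef <- config$w_compact * 2 * (rg - rg_t) / (nres * rg)
    Gc <- coef * sweep(CA, 2L, ctr)
    # centroid term cancels because sum of deviations is zero
    G[cache$ca, ] <- G[cache$ca, ] + Gc
  }

  # Ramachandran statistics (value only; no chain validation so it can be
  # evaluated on transient minimizer states)
  torsion_stat <- 0
  if (want_torsion) {
    nr <- length(cache$ca)
    Nx <- xyz[cache$iN, , drop = FALSE]
    CAx <- xyz[cache$ca, , drop = FALSE]
    Cx <- xyz[cache$iC, , drop = FALSE]
    phi <- c(NA_real_, dihedral4(Cx[-nr, , drop = FALSE], Nx[-1L, , drop = FALSE],
                                 CAx[-1L, , drop = FALSE], Cx[-1L, , drop = FALSE]))
    psi <- c(dihedral4(Nx[-nr, , drop = FALSE], CAx[-nr, , drop = FALSE],
                       Cx[-nr, , drop = FALSE], Nx[-1L, , drop = FALSE]), NA_real_)
    torsion_stat <- sum(rama_neglog(phi, psi))
  }

  restr <- 0
  if (!is.null(restraints)) {
    re <- restraint_eval(restraints, m2, want_grad = want_grad)
    restr <- re$value
    if (want_grad) G <- G + config$w_restraint * re$grad
  }

  bonded <- 0
  if (include_bonded && length(cache$bonded$i)) {
    b <- cache$bonded
    dxb <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    rb <- row_norm(dxb)
    bonded <- sum(b$k * (rb - b$target)^2)
    if (want_grad) {
      coef <- 2 * b$k * (rb - b$target) / pmax(rb, 1e-9)
      acc(b$i, b$j, coef, dxb)
    }
  }

  list(steric = config$w_steric * steric,
       hbond = config$w_hbond * hbond,
       torsion_stat = config$w_torsion * torsion_stat,
       compactness = config$w_compact * compact,
       restraint = config$w_restraint * restr,
       bonded = bonded, grad = G)
}

#' Evaluate the composite energy of a model
#'
#' Terms (each reported after weighting): `steric` soft-sphere repulsion
#' sum((1 - r/r0)^2) for non-bonded pairs closer than the vdW contact r0;
#' `hbond` Gaussian reward well on backbone N-O pairs around 3.0 Angstrom;
#' `torsion_stat` per-residue negative log frequency from a coarse
#' Ramachandran bin table; `compactness` (Rg - 2.2 L^0.38)^2; `restraint`
#' from [restraint_penalty()] (0 when `restraints` is NULL).
#' `total_without_restraints` is used for final model ranking.
#'
#' @param model A `protein_model`.
#' @param restraints A `restraint_set` or NULL.
#' @param config Configuration with term weights.
#' @return An `energy_breakdown` list with the term fields plus
#'   `total_with_restraints` and `total_without_restraints`.
#' @export
evaluate_energy <- function(model, restraints = NULL,
                            config = default_config()) {
  cache <- make_energy_cache(model, config)
  et <- energy_terms(model$xyz, model, cache, restraints, config)
  out <- list(steric = et$steric, hbond = et$hbond,
              torsion_stat = et$torsion_stat, compactness = et$compactness,
              restraint = et$restraint)
  out$total_without_restraints <- et$steric + et$hbond + et$torsion_stat +
    et$compactness
  out$total_with_restraints <- out$total_without_restraints + et$restraint
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<energy_breakdown> steric %.3f  hbond %.3f  torsion %.3f",
                     "  compact %.3f  restraint %.3f  total %.3f (no-restr %.3f)\n"),
              x$steric, x$hbond, x$torsion_stat, x$compactness, x$restraint,
              x$total_with_restraints, x$total_without_restraints))
  invisible(x)
}

#' Analytic gradient of the composite energy
#'
#' Gradient of `total_with_restraints` with respect to all atom coordinates.
#' The Ramachandran term is piecewise constant and contributes zero almost
#' everywhere; CA-anchor restraints are differentiated at fixed
#' superposition (exact for full-set harmonic anchors).
#'
#' @param model A `protein_model`.
#' @param restraints A `restraint_set` or NULL.
#' @param config Configuration.
#' @return Matrix (atoms x 3) of partial derivatives.
#' @export
energy_gradient <- function(model, restraints = NULL,
                            config = default_config()) {
  cache <- make_energy_cache(model, config)
  energy_terms(model$xyz, model, cache, restraints, config,
               want_grad = TRUE)$grad
}

#' Relaxation schedule
#' @param steps Minimization step budget (0 = no-op).
#' @param mode `"minimize"` (strict descent) or `"noisy-minimize"`
#'   (seeded Gaussian kicks and side-chain repacks between segments).
#' @param sidechain_repack_every Segment length in steps.
#' @param rng_seed Seed for the noisy mode.
#' @return A `relax_schedule` list.
#' @export
relax_schedule <- function(steps, mode = c("minimize", "noisy-minimize"),
                           sidechain_repack_every = 100L, rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(steps >= 0)
  structure(list(steps = as.integer(steps), mode = mode,
                 sidechain_repack_every = as.integer(sidechain_repack_every),
                 rng_seed = as.integer(rng_seed)),
            class = "relax_schedule")
}

# smooth objective used by the minimizer: everything except the
# piecewise-constant Ramachandran term, plus the bonded surrogate
relax_objective <- function(model, cache, restraints, config) {
  shape <- dim(model$xyz)
  fn <- function(par) {
    xyz <- matrix(par, shape[1L], 3L)
    et <- energy_terms(xyz, model, cache, restraints, config,
                       include_bonded = TRUE, want_torsion = FALSE)
    v <- et$steric + et$hbond + et$compactness + et$restraint + et$bonded
    if (!is.finite(v)) stop("non-finite energy during minimization")
    v
  }
  gr <- function(par) {
    xyz <- matrix(par, shape[1L], 3L)
    et <- energy_terms(xyz, model, cache, restraints, config,
                       want_grad = TRUE, include_bonded = TRUE,
                       want_torsion = FALSE)
    as.numeric(et$grad)
  }
  list(fn = fn, gr = gr)
}

chain_intact <- function(model, tol = 2.0) {
  n <- n_res(model)
  if (n < 2L) return(TRUE)
  Cx <- bb_coords(model, "C"); Nx <- bb_coords(model, "N")
  all(row_norm(Nx[-1L, , drop = FALSE] - Cx[-n, , drop = FALSE]) < tol)
}

#' Restrained relaxation of a model
#'
#' Gradient-based Cartesian minimization of the restrained energy with
#' distance-harmonic bonded terms holding the covalent geometry (bond
#' lengths stay within 2% of ideal). In `minimize` mode the result is
#' guaranteed not to raise `total_with_restraints` (the input is returned
#' if minimization failed to descend or broke the chain). In
#' `noisy-minimize` mode, seeded Gaussian coordinate kicks and side-chain
#' repacks are interleaved between minimization segments.
#'
#' @param model A `protein_model`.
#' @param restraints A `restraint_set` or NULL.
#' @param schedule A [relax_schedule()].
#' @param config Configuration.
#' @return The relaxed `protein_model`.
#' @export
relax <- function(model, restraints, schedule, config = default_config()) {
  if (schedule$steps == 0L) return(model)
  cache <- make_energy_cache(model, config)
  obj <- relax_objective(model, cache, restraints, config)
  run_opt <- function(m, maxit) {
    res <- stats::optim(as.numeric(m$xyz), obj$fn, obj$gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    m$xyz <- matrix(res$par, nrow(m$xyz), 3L)
    m
  }
  if (schedule$mode == "minimize") {
    before <- evaluate_energy(model, restraints, config)
    out <- run_opt(model, schedule$steps)
    after <- evaluate_energy(out, restraints, config)
    if (!chain_intact(out) ||
        after$total_with_restraints > before$total_with_restraints)
      return(model)
    out
  } else {
    with_seed(schedule$rng_seed, {
      seg <- max(1L, schedule$sidechain_repack_every)
      left <- schedule$steps
      out <- model
      first <- TRUE
      while (left > 0L) {
        if (!first) {
          out$xyz <- out$xyz + matrix(stats::rnorm(length(out$xyz), 0,
                                                   config$relax_noise_amp),
                                      nrow(out$xyz), 3L)
          out <- repack_sidechains(out, config,
                                   seed = stats::runif(1L, 1, 1e8))
        }
        out <- run_opt(out, min(seg, left))
        left <- left - seg
        first <- FALSE
      }
      if (!chain_intact(out)) model else out
    })
  }
}
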