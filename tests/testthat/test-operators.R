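make_ctx <- function(model, seed = 11L, cfg = toy_config(), ...) {
  n <- n_res(model)
  pe <- rep(0.2, n); pe[13:17] <- 2
  prof <- structure(list(rmsf = rep(0.5, n), frag = rep(0, n), msa = NULL,
                         predicted_error = pe, threshold = 1,
                         ulrs = list(c(13L, 17L))),
                    class = "residue_error_profile")
  operator_context(prof, fraglib = make_fragment_library(model, 7, 10, seed = 4),
                   rng_seed = seed, config = cfg, ...)
}

test_that("elastic network has 6 rigid modes and a finite-difference Hessian", {
  b <- cached_bundle()
  em <- compute_enm_modes(b)
  expect_equal(sum(abs(em$eigenvalues) < 1e-8), 6L)
  expect_true(all(em$eigenvalues > -1e-9))
  n3 <- length(em$eigenvalues)
  expect_lt(max(abs(crossprod(em$eigenvectors) - diag(n3))), 1e-8)

  # Hessian vs central finite differences of the network energy (5 residues)
  m5 <- make_ideal_helix(5)
  CA <- bb_coords(m5, "CA")
  cutoff <- 10; k <- 1
  en <- function(x) {
    X <- matrix(x, 5, 3)
    tot <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      d0 <- sqrt(sum((CA[i, ] - CA[j, ])^2))
      if (d0 >= cutoff) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      tot <- tot + k * (d - d0)^2
    }
    tot
  }
  x0 <- as.numeric(CA)
  h <- 1e-4
  Hfd <- matrix(0, 15, 15)
  for (a in 1:15) for (b2 in 1:15) {
    xa <- x0; xa[a] <- xa[a] + h; xa[b2] <- xa[b2] + h
    xb <- x0; xb[a] <- xb[a] + h; xb[b2] <- xb[b2] - h
    xc <- x0; xc[a] <- xc[a] - h; xc[b2] <- xc[b2] + h
    xd <- x0; xd[a] <- xd[a] - h; xd[b2] <- xd[b2] - h
    Hfd[a, b2] <- (en(xa) - en(xb) - en(xc) + en(xd)) / (4 * h^2)
  }
  # assemble the analytic Hessian through the same eigen pipeline
  em5 <- compute_enm_modes(m5, cutoff, k)
  Ha <- em5$eigenvectors %*% diag(em5$eigenvalues) %*% t(em5$eigenvectors)
  # row order: analytic uses (x1,y1,z1,...); FD uses column-major (all x,
  # then y, then z) -- permute
  perm <- as.numeric(t(matrix(1:15, 5, 3)))
  expect_equal(Ha, Hfd[perm, perm], tolerance = 1e-4)

  # disconnected network errors
  two <- cached_bundle()
  two$xyz[two$atom_resi > 15, ] <- two$xyz[two$atom_resi > 15, ] + 100
  expect_error(compute_enm_modes(two), "disconnected")
})

test_that("fragment assembly is local, closed and deterministic", {
  b <- cached_bundle()
  ctx <- make_ctx(b)
  out <- op_fragment_assembly(b, ctx)
  expect_false(is_noop(out))
  expect_true(chain_intact(out))
  expect_identical(model_sequence(out), model_sequence(b))
  out2 <- op_fragment_assembly(b, ctx)
  expect_identical(out$xyz, out2$xyz)
  # window selection weights are proportional to mean window error
  err <- ctx$error_profile$predicted_error
  w <- 7
  wts <- sapply(seq_len(n_res(b) - w + 1),
                function(j) mean(err[j:(j + w - 1)]))
  # windows fully covering the planted high-error span tie for the peak
  expect_true(which.max(wts) %in% 11:13)
  expect_gt(min(wts[11:13]), max(wts[c(1:5, 20:23)]))
})

test_that("loop modelling mixes and mutates only the ULR", {
  b <- cached_bundle()
  ctx <- make_ctx(b)
  same <- op_loop_modelling(b, b, c(13, 17), "mix", 0.5, ctx)
  expect_lte(max(abs(same$xyz - b$xyz)), 1e-6)

  # mix_coeff endpoints against a genuinely different partner
  partner <- op_loop_modelling(b, b, c(13, 17), "mutate", context = ctx)
  expect_false(is_noop(partner))
  m0 <- op_loop_modelling(b, partner, c(13, 17), "mix", 0, ctx)
  tt_b <- compute_backbone_torsions(b); tt_0 <- compute_backbone_torsions(m0)
  inner <- c(14L, 16L)   # non-pivot ULR residues (pivots are 13, 15, 17)
  expect_lte(max(circ_absdiff(tt_0$phi[inner], tt_b$phi[inner])), 1e-6)
  m1 <- op_loop_modelling(b, partner, c(13, 17), "mix", 1, ctx)
  tt_p <- compute_backbone_torsions(partner)
  tt_1 <- compute_backbone_torsions(m1)
  expect_lte(max(circ_absdiff(tt_1$phi[inner], tt_p$phi[inner])), 1e-6)

  mu <- op_loop_modelling(b, b, c(13, 17), "mutate", context = ctx)
  expect_true(chain_intact(mu))
  outside <- mu$atom_resi < 12 | mu$atom_resi > 18
  expect_lte(max(abs(mu$xyz[outside, ] - b$xyz[outside, ])), 1e-6)
})

test_that("side-chain perturbation leaves the backbone bit-identical", {
  hl <- make_ideal_helix(12, strrep("L", 12))
  ctx <- make_ctx(hl)
  out <- op_sidechain_perturbation(hl, ctx)
  expect_false(is_noop(out))
  bbsel <- out$atom_name %in% c("N", "CA", "C", "O")
  expect_identical(out$xyz[bbsel, ], hl$xyz[bbsel, ])
  # coarse (no side chain) model: no-op
  expect_true(is_noop(op_sidechain_perturbation(cached_bundle(), ctx)))
  # repeated seeded repacks of a clashed fixture do not increase clashes
  set.seed(2)
  clashed <- hl
  clashed$xyz <- clashed$xyz + matrix(rnorm(length(clashed$xyz), 0, 0.3),
                                      nrow(clashed$xyz), 3)
  cl0 <- clash_score(clashed)
  cls <- sapply(1:20, function(s)
    clash_score(repack_sidechains(clashed, toy_config(), seed = s)))
  expect_lte(mean(cls), cl0)
})

test_that("normal-mode perturbation has exact amplitude and mode direction", {
  b <- cached_bundle()
  ctx <- make_ctx(b)
  same <- op_normal_mode_perturbation(b, ctx, amplitude = 0)
  expect_identical(same$xyz, b$xyz)

  out <- op_normal_mode_perturbation(b, ctx, amplitude = 1.0)
  expect_false(is_noop(out))
  v <- attr(out, "nm_displacement")
  expect_equal(sqrt(mean(rowSums(v^2))), 1.0, tolerance = 1e-6)
  # displacement lies in the span of the selected mode
  em <- compute_enm_modes(b)
  k <- attr(out, "nm_mode_index")
  vec <- as.numeric(t(v)); vec <- vec / sqrt(sum(vec^2))
  resid <- vec - em$eigenvectors[, k] %*% crossprod(em$eigenvectors[, k, drop = FALSE], vec)
  expect_lt(sqrt(sum(resid^2)), 1e-8)
  expect_true(chain_intact(out))
})

test_that("hybridization copies non-ULR patches and recloses junctions", {
  b <- cached_bundle()
  cfg <- toy_config()
  ctx0 <- make_ctx(b)
  # empty library: flagged no-op, model unchanged
  none <- op_hybridization(b, ctx0)
  expect_true(is_noop(none))
  expect_identical(none$xyz, b$xyz)

  th <- optimize_threaded(b, cfg, seed = 3)
  pl <- extract_patch_library(list(th), ctx0$error_profile$ulrs, ids = "t")
  expect_gt(length(pl$patches), 0)
  for (p in pl$patches)
    expect_true(p$range[2] < 13 || p$range[1] > 17)   # never from ULRs
  ctx <- make_ctx(b, seed = 5, patch_library = pl)
  out <- op_hybridization(b, ctx)
  expect_false(is_noop(out))
  expect_true(chain_intact(out))
  expect_identical(model_sequence(out), model_sequence(b))
})

test_that("secondary-structure perturbation moves chunks rigidly", {
  b <- cached_bundle()
  ctx <- make_ctx(b, seed = 21)
  out <- op_ss_perturbation(b, ctx)
  expect_false(is_noop(out))
  expect_true(chain_intact(out))
  # some helix chunk retained its internal CA-CA distance matrix
  chunks <- refine2lite:::ss_chunks(assign_secondary_structure(b))
  rigid <- FALSE
  for (ch in chunks) {
    CA0 <- bb_coords(b, "CA")[ch[1]:ch[2], ]
    CA1 <- bb_coords(out, "CA")[ch[1]:ch[2], ]
    if (max(abs(dist(CA0) - dist(CA1))) < 1e-6) rigid <- TRUE
  }
  expect_true(rigid)

  # all-coil chain: no chunk, flagged no-op
  set.seed(30)
  n <- 12
  tor <- data.frame(resi = 1:n,
                    phi = c(NA, runif(n - 1, -170, 170)),
                    psi = c(runif(n - 1, -170, -100), NA),
                    omega = c(rep(180, n - 1), NA))
  coil <- rebuild_backbone_from_torsions(tor, rbind(c(0, 0, 0),
                                                    c(1.458, 0, 0),
                                                    c(2.009, 1.422, 0)))
  expect_true(is_noop(op_ss_perturbation(coil, make_ctx(coil))))
})

test_that("operators preserve sequence, connectivity and finiteness", {
  b <- cached_bundle()
  for (seed in 1:8) {
    ctx <- make_ctx(b, seed = seed)
    for (op in c("fragment_assembly", "loop_modelling", "normal_mode",
                 "ss_perturbation")) {
      out <- apply_operator(op, b, ctx)
      expect_true(all(is.finite(out$xyz)))
      expect_identical(model_sequence(out), model_sequence(b))
      if (!is_noop(out)) expect_true(chain_intact(out))
    }
  }
})
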