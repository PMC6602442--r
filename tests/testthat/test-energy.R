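test_that("build_restraints matches the stated cutoffs and enumeration", {
  b <- cached_bundle()
  rs <- build_restraints(b)
  n <- n_res(b)
  expect_equal(nrow(rs$ca_anchor), n)       # one CA anchor per residue
  oc <- oracle_ca_pairs(b)
  expect_equal(nrow(rs$ca_pairs), nrow(oc))
  expect_equal(as.matrix(rs$ca_pairs), unname(oc), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_true(all(rs$ca_pairs$j - rs$ca_pairs$i >= 4))
  expect_true(all(rs$ca_pairs$target < 12))
  expect_true(all(rs$no_pairs$target < 3.5))

  # fully extended chain: no CA pairs within 12 A at separation >= 4
  ext <- make_ideal_strand(6)
  expect_equal(nrow(build_restraints(ext)$ca_pairs), 0L)
})

test_that("restraint penalties follow the closed forms and neglect rule", {
  b <- cached_bundle()
  rs <- build_restraints(b, form = "harmonic",
                         config = default_config(neglect_fraction = 0))
  expect_equal(restraint_penalty(rs, b), 0, tolerance = 1e-12)

  # single harmonic pair restraint, deviation 2 A -> penalty 4
  one <- rs
  one$ca_anchor <- bb_coords(b, "CA")
  one$ca_pairs <- one$ca_pairs[1, ]
  one$no_pairs <- one$no_pairs[0, ]
  m2 <- b
  i <- one$ca_pairs$i; j <- one$ca_pairs$j
  one$ca_pairs$target <- one$ca_pairs$target - 2   # deviation of exactly 2
  expect_equal(restraint_penalty(one, b) -
                 restraint_penalty(rs, b), 4, tolerance = 1e-9)

  # Lorentzian closed form w d^2/(d^2+c^2)
  lone <- one; lone$form <- "lorentzian"
  expect_equal(restraint_penalty(lone, b), 4 / (4 + 3^2), tolerance = 1e-9)

  # ten pair restraints, one off by 100 A, neglect 10% -> worst one dropped
  ten <- rs
  ten$ca_anchor <- bb_coords(b, "CA")
  ten$ca_pairs <- rs$ca_pairs[1:10, ]
  ten$no_pairs <- rs$no_pairs[0, ]
  ten$ca_pairs$target[7] <- ten$ca_pairs$target[7] + 100
  ten$neglect_fraction <- 0.1
  expect_equal(restraint_penalty(ten, b), 0, tolerance = 1e-9)
  # with neglect 0 the bad restraint contributes 100^2
  ten0 <- ten; ten0$neglect_fraction <- 0
  expect_equal(restraint_penalty(ten0, b), 1e4, tolerance = 1e-6)

  # Lorentzian total is bounded above by the restraint count
  far <- b; far$xyz <- far$xyz * 50
  lrs <- build_restraints(b, form = "lorentzian",
                          config = default_config(neglect_fraction = 0))
  bound <- nrow(lrs$ca_anchor) + nrow(lrs$ca_pairs) + nrow(lrs$no_pairs)
  expect_lt(restraint_penalty(lrs, far), bound)
})

test_that("Lorentzian gradients flatten at large deviation, harmonic grow", {
  dev <- c(1, 10, 100, 1000)
  gl <- abs(refine2lite:::restraint_form_dpenalty(dev, "lorentzian", 3))
  gh <- abs(refine2lite:::restraint_form_dpenalty(dev, "harmonic", 3))
  expect_true(all(diff(gl[2:4]) < 0))   # decays toward zero
  expect_lt(gl[4], 1e-3)
  expect_true(all(diff(gh) > 0))        # grows linearly
})

test_that("evaluate_energy obeys its stated structure", {
  b <- cached_bundle()
  rs <- build_restraints(b)
  zero <- evaluate_energy(b, rs, default_config(w_steric = 0, w_hbond = 0,
                                                w_torsion = 0, w_compact = 0,
                                                w_restraint = 0))
  expect_equal(zero$total_with_restraints, 0)
  expect_equal(zero$total_without_restraints, 0)

  e <- evaluate_energy(b, rs)
  expect_equal(e$total_without_restraints,
               e$steric + e$hbond + e$torsion_stat + e$compactness,
               tolerance = 1e-9)
  expect_equal(e$total_with_restraints,
               e$total_without_restraints + e$restraint, tolerance = 1e-9)

  # steric boundary: a pair exactly at the vdW contact distance (r0 =
  # 1.55 + 1.55 for two nitrogens) contributes zero; inside r0 it does not
  mk2 <- function(nn_dist) {
    res1 <- list(N = c(0, 0, 0), CA = c(-1.458, 0, 0),
                 C = c(-2.0, -1.4, 0), O = c(-3.0, -1.4, 0))
    res2 <- lapply(res1, function(p) p + c(0, 0, 100))
    res3 <- list(N = c(nn_dist, 0, 0), CA = c(nn_dist + 1.458, 0, 0),
                 C = c(nn_dist + 2.0, 1.4, 0), O = c(nn_dist + 3.0, 1.4, 0))
    model_from_residue_atoms(c("G", "G", "G"), list(res1, res2, res3))
  }
  at_contact <- evaluate_energy(mk2(3.10), NULL, default_config())
  expect_equal(at_contact$steric, 0)
  inside <- evaluate_energy(mk2(2.60), NULL, default_config())
  expect_gt(inside$steric, 0)
})

test_that("analytic gradient matches central finite differences", {
  b <- make_ideal_helix(14)
  cfg <- default_config(restraint_form = "harmonic", neglect_fraction = 0)
  rs <- build_restraints(b, config = cfg)
  set.seed(4)
  m <- b; m$xyz <- m$xyz + matrix(rnorm(length(m$xyz), 0, 0.12),
                                  nrow(m$xyz), 3)
  G <- energy_gradient(m, rs, cfg)
  h <- 1e-6
  set.seed(5)
  for (k in sample(length(m$xyz), 30)) {
    mp <- m; mp$xyz[k] <- mp$xyz[k] + h
    mm <- m; mm$xyz[k] <- mm$xyz[k] - h
    fd <- (evaluate_energy(mp, rs, cfg)$total_with_restraints -
             evaluate_energy(mm, rs, cfg)$total_with_restraints) / (2 * h)
    expect_equal(G[k], fd, tolerance = 1e-4)
  }
})

test_that("relax descends, preserves connectivity, and honors step 0", {
  b <- make_ideal_helix(16)
  cfg <- default_config()
  rs <- build_restraints(b, config = cfg)
  set.seed(8)
  m <- b; m$xyz <- m$xyz + matrix(rnorm(length(m$xyz), 0, 0.25),
                                  nrow(m$xyz), 3)
  expect_identical(relax(m, rs, relax_schedule(0), cfg), m)

  out <- relax(m, rs, relax_schedule(120), cfg)
  expect_lte(evaluate_energy(out, rs, cfg)$total_with_restraints,
             evaluate_energy(m, rs, cfg)$total_with_restraints)
  expect_true(chain_intact(out))
  # bond lengths within 2% of ideal after relaxation
  Cx <- bb_coords(out, "C"); Nx <- bb_coords(out, "N")
  pep <- sqrt(rowSums((Nx[-1, ] - Cx[-16, ])^2))
  expect_true(all(abs(pep - 1.329) / 1.329 < 0.02))

  # noisy-minimize is seeded-deterministic
  s1 <- relax(m, rs, relax_schedule(30, "noisy-minimize", 10, rng_seed = 3), cfg)
  s2 <- relax(m, rs, relax_schedule(30, "noisy-minimize", 10, rng_seed = 3), cfg)
  expect_identical(s1$xyz, s2$xyz)
})

test_that("conservative mode selects harmonic restraints with 5% neglect", {
  cfg <- default_config(mode = "conservative")
  expect_identical(cfg$restraint_form, "harmonic")
  expect_equal(cfg$neglect_fraction, 0.05)
  b <- make_ideal_helix(8)
  rs <- build_restraints(b, config = cfg)
  expect_identical(rs$form, "harmonic")
  expect_equal(rs$neglect_fraction, 0.05)
})
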