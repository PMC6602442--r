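toy_result <- function() {
  if (is.null(.fix_env$toy_result)) {
    m <- make_ideal_helix(20)
    .fix_env$toy_result <- run_refinement(m, toy_config())
  }
  .fix_env$toy_result
}

test_that("pool initialization honors capacity and rebuilds only ULRs", {
  cfg <- toy_config()
  m <- make_ideal_helix(20)
  rs <- build_restraints(m, config = cfg)
  # no ULRs: all members stay within relax tolerance of the input
  prof0 <- structure(list(rmsf = rep(0, 20), frag = rep(0, 20), msa = NULL,
                          predicted_error = rep(0, 20), threshold = 1,
                          ulrs = list()), class = "residue_error_profile")
  pool0 <- initialize_pool(m, prof0, rs, cfg)
  expect_length(pool0$members, cfg$capacity)
  for (mb in pool0$members) expect_lt(ca_rmsd(mb$model, m), 0.3)

  # with a ULR, distinct seeds give distinct members
  prof1 <- prof0
  prof1$ulrs <- list(c(8L, 13L))
  pool1 <- initialize_pool(m, prof1, rs, cfg)
  rmsds <- sapply(pool1$members, function(mb) ca_rmsd(mb$model, m))
  expect_gt(max(rmsds), 0.01)
  pair_rmsd <- ca_rmsd(pool1$members[[1]]$model, pool1$members[[2]]$model)
  expect_gt(pair_rmsd, 0.01)
  # non-ULR regions stay close to the input
  for (mb in pool1$members[1:3]) {
    keepres <- c(1:6, 15:20)
    sel <- mb$model$atom_resi %in% keepres & mb$model$atom_name == "CA"
    tf <- kabsch_superpose(mb$model$xyz[sel, ], m$xyz[sel, ])
    expect_lt(tf$rmsd, 0.5)
  }
})

test_that("update_pool applies the replacement rule and conserves size", {
  cfg <- toy_config()
  m <- make_ideal_helix(12)
  rs <- build_restraints(m, config = cfg)
  wrap <- function(mm, en) list(model = mm, energy = en, energy_norestr = en,
                                operator = "x", relax_steps = 0L)
  A <- m
  B <- perturb_structure(m, 2.0, seed = 1)
  C <- perturb_structure(m, 4.0, seed = 2)
  pool <- structure(list(members = list(wrap(A, 5), wrap(B, 8), wrap(C, 9)),
                         capacity = 3L, cycle = 1L, closeness_radius = 0.5),
                    class = "structure_pool")

  # trial above every pool energy: pool unchanged
  p2 <- update_pool(pool, list(wrap(B, 99)), cfg)
  expect_equal(sort(sapply(p2$members, `[[`, "energy")), c(5, 8, 9))
  expect_length(p2$members, 3L)

  # trial structurally close to B only: replaces B, not the global worst C
  Tn <- B
  set.seed(9)
  Tn$xyz <- Tn$xyz + matrix(rnorm(length(Tn$xyz), 0, 0.1), nrow(Tn$xyz), 3)
  expect_lt(ca_rmsd(Tn, B), 0.5)
  expect_gt(ca_rmsd(Tn, A), 0.5); expect_gt(ca_rmsd(Tn, C), 0.5)
  p3 <- update_pool(pool, list(wrap(Tn, 1)), cfg)
  expect_equal(sort(sapply(p3$members, `[[`, "energy")), c(1, 5, 9))

  # trial far from every member: replaces the global worst (C, energy 9)
  Tf <- perturb_structure(m, 5.0, seed = 3)
  expect_true(all(sapply(list(A, B, C), function(x) ca_rmsd(Tf, x)) > 0.5))
  p4 <- update_pool(pool, list(wrap(Tf, 2)), cfg)
  expect_equal(sort(sapply(p4$members, `[[`, "energy")), c(2, 5, 8))

  # min energy never increases over repeated updates; size conserved
  cur <- pool
  for (k in 1:8) {
    tr <- wrap(perturb_structure(m, runif(1, 0.5, 5), seed = 50 + k),
               runif(1, 0, 12))
    newp <- update_pool(cur, list(tr), cfg)
    expect_lte(min(sapply(newp$members, `[[`, "energy")),
               min(sapply(cur$members, `[[`, "energy")))
    expect_length(newp$members, 3L)
    cur <- newp
  }
})

test_that("the closeness radius follows its linear widening schedule", {
  cfg <- default_config(cycles = 5L, closeness_start = 0.5,
                        closeness_end = 2.0)
  r <- sapply(1:5, refine2lite:::closeness_radius_at, config = cfg)
  expect_equal(r, seq(0.5, 2.0, length.out = 5))
  expect_true(all(diff(r) > 0))
})

test_that("a toy run keeps the protocol bookkeeping", {
  res <- toy_result()
  cfg <- toy_config()
  expect_equal(res$all_scored_count,
               cfg$capacity * cfg$trials_per_member * cfg$cycles)
  expect_length(res$final_models, 10L)
  en <- sapply(res$final_models, attr, "final_energy")
  expect_true(all(diff(en) >= 0))          # ranked ascending
  expect_equal(nrow(res$log), cfg$cycles)
  expect_true(all(diff(res$log$min_energy) <= 1e-9))  # non-increasing
  expect_equal(res$log$closeness_radius[cfg$cycles], cfg$closeness_end)
  for (fm in res$final_models) {
    expect_true(chain_intact(fm))
    expect_identical(fm$provenance, "final")
  }
})

test_that("trials carry operator tags and schedule-dependent relax steps", {
  cfg <- toy_config()
  cs <- cached_case()
  rs <- build_restraints(cs$start, config = cfg)
  prof <- structure(list(rmsf = rep(0.3, 40), frag = rep(0, 40), msa = NULL,
                         predicted_error = rep(0.3, 40), threshold = 1,
                         ulrs = list(c(18L, 23L))),
                    class = "residue_error_profile")
  ctx <- operator_context(prof, fraglib = cs$fraglib, rng_seed = 3,
                          config = cfg)
  pool <- structure(list(members = list(list(model = cs$start, energy = 0,
                                             energy_norestr = 0)),
                         capacity = 1L, cycle = 1L, closeness_radius = 0.5),
                    class = "structure_pool")
  cfg2 <- cfg; cfg2$trials_per_member <- 12L
  trials <- generate_trials(pool, ctx, rs, cfg2, seed = 9)
  expect_length(trials, 12L)
  tags <- sapply(trials, `[[`, "operator")
  expect_true(all(tags %in% c(operator_names(), "none")))
  steps <- sapply(trials, `[[`, "relax_steps")
  lm <- tags == "loop_modelling"
  if (any(lm)) expect_true(all(steps[lm] == cfg$steps_short))
  if (any(!lm)) expect_true(all(steps[!lm] == cfg$steps_standard))
})

test_that("final selection ranks by restraint-free energy", {
  cfg <- toy_config()
  m <- make_ideal_helix(10)
  # fabricate trials where restrained and unrestrained orders disagree
  trials <- lapply(1:12, function(k) {
    mm <- m; mm$xyz <- mm$xyz + 0.01 * k
    list(model = mm, energy = -k, energy_norestr = k, operator = "x")
  })
  sel <- select_final_models(trials, cfg, n_final = 3L)
  # lowest energy_norestr are trials 1..3, NOT the lowest restrained ones
  expect_length(sel, 3L)
  pre <- lapply(sel, attr, "pre_optimization")
  expect_equal(sort(sapply(pre, function(p) round(p$xyz[1, 1] - m$xyz[1, 1], 4))),
               round(0.01 * (1:3), 4), tolerance = 1e-6)
  # full-atom optimization does not worsen clashes
  for (s in sel)
    expect_lte(clash_score(s), clash_score(attr(s, "pre_optimization")))
  expect_warning(select_final_models(trials[1:5], cfg, n_final = 10L),
                 "fewer")
})

test_that("identical master seeds give bit-identical refinements", {
  m <- make_ideal_helix(14)
  cfg <- default_config(capacity = 3L, trials_per_member = 3L, cycles = 2L,
                        steps_long = 20L, steps_standard = 8L,
                        steps_short = 4L, rmsf_n_runs = 2L,
                        sidechain_repack_every = 10L, tlc_grid = 120L,
                        seed = 42L)
  r1 <- run_refinement(m, cfg)
  r2 <- run_refinement(m, cfg)
  expect_identical(r1$final_models[[1]]$xyz, r2$final_models[[1]]$xyz)
  expect_identical(r1$log$min_energy, r2$log$min_energy)
})
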