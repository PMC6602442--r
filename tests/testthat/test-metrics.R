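test_that("identity and rigid-transform cases give exact metric values", {
  m <- cached_bundle()
  expect_equal(ca_rmsd(m, m), 0, tolerance = 1e-9)
  expect_equal(gdt_ha(m, m), 100)
  expect_equal(lddt(m, m), 100)
  expect_equal(tm_score(m, m), 1.0, tolerance = 1e-9)

  tfr <- random_rigid_transform(5)
  mt <- transform_model(m, tfr)
  expect_lt(ca_rmsd(mt, m), 1e-6)
  expect_equal(gdt_ha(mt, m), 100)
  expect_equal(lddt(mt, m), 100, tolerance = 1e-9)
  expect_equal(tm_score(mt, m), 1.0, tolerance = 1e-6)
  expect_equal(clash_score(mt), clash_score(m))

  # uniform 50 A translation alone
  m50 <- m; m50$xyz <- m50$xyz + 50
  expect_equal(gdt_ha(m50, m), 100)
})

test_that("GDT-HA and TM-score match exhaustive subset oracles on small toys", {
  for (seed in c(1, 2, 3, 4)) {
    tp <- random_toy_pair(8, seed, noise = 1.2)
    expect_equal(gdt_ha(tp$model, tp$reference),
                 oracle_gdt_ha(tp$model, tp$reference), tolerance = 1e-9)
    expect_warning(tm <- tm_score(tp$model, tp$reference), "d0")
    expect_equal(tm, oracle_tm_score(tp$model, tp$reference),
                 tolerance = 1e-9)
  }
  # structured case: 4 residues exactly superposable, 2 displaced 3 A
  ref <- random_toy_pair(6, 9, noise = 0)$reference
  mod <- ref
  ica <- which(mod$atom_name == "CA" & mod$atom_resi %in% c(5, 6))
  mod$xyz[mod$atom_resi %in% c(5, 6), ] <-
    mod$xyz[mod$atom_resi %in% c(5, 6), ] + c(3, 0, 0)
  expect_equal(gdt_ha(mod, ref), oracle_gdt_ha(mod, ref), tolerance = 1e-9)
})

test_that("TM-score d0 formula is exact and warns below 16 residues", {
  L <- 140
  expect_equal(1.24 * (L - 15)^(1 / 3) - 1.8, 4.4, tolerance = 1e-12)
  tp <- random_toy_pair(10, 2, noise = 0.5)
  expect_warning(tm_score(tp$model, tp$reference), "clamped")
})

test_that("LDDT matches a brute-force pair enumeration oracle", {
  for (seed in c(3, 7)) {
    tp <- random_toy_pair(8, seed, noise = 0.8)
    expect_equal(lddt(tp$model, tp$reference, mode = "ca"),
                 oracle_lddt_ca(tp$model, tp$reference), tolerance = 1e-9)
  }
  # superposition-free: invariant under rigid transform of either argument
  tp <- random_toy_pair(8, 12, noise = 0.8)
  mt <- transform_model(tp$model, random_rigid_transform(8))
  expect_equal(lddt(mt, tp$reference, mode = "ca"),
               lddt(tp$model, tp$reference, mode = "ca"), tolerance = 1e-9)
  # perfect score iff all deviations under 0.5 A
  small <- tp$reference
  small$xyz <- small$xyz + matrix(rnorm(length(small$xyz), 0, 0.01),
                                  nrow(small$xyz), 3)
  expect_equal(lddt(small, tp$reference, mode = "ca"), 100)
})

test_that("clash score matches brute force and responds to forced clashes", {
  b <- cached_bundle()
  expect_equal(clash_score(b), 0)
  tp <- random_toy_pair(8, 21, noise = 1.5)
  expect_equal(clash_score(tp$model), oracle_clash(tp$model),
               tolerance = 1e-12)
  # force two CA atoms 1.0 A apart
  m <- make_ideal_helix(8)
  i5 <- which(m$atom_name == "CA" & m$atom_resi == 5)
  i8 <- which(m$atom_name == "CA" & m$atom_resi == 8)
  m$xyz[i8, ] <- m$xyz[i5, ] + c(1, 0, 0)
  expect_gt(clash_score(m), 0)
})

test_that("accuracy_report collects all metrics consistently", {
  cs <- cached_case()
  rep <- accuracy_report(cs$start, cs$native)
  expect_true(all(c("ca_rmsd", "gdt_ha", "lddt", "tm_score",
                    "clash_per_1000", "rama_favored_pct") %in% names(rep)))
  expect_gte(rep$gdt_ha, 0); expect_lte(rep$gdt_ha, 100)
  expect_gte(rep$lddt, 0); expect_lte(rep$lddt, 100)
  expect_gt(rep$tm_score, 0); expect_lte(rep$tm_score, 1)
  expect_equal(rep$ca_rmsd, ca_rmsd(cs$start, cs$native))
})
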