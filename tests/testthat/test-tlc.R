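random_closed_chain <- function(n, seed) {
  set.seed(seed)
  tor <- data.frame(resi = 1:n, phi = c(NA, runif(n - 1, -150, -40)),
                    psi = c(runif(n - 1, -60, 160), NA),
                    omega = c(rep(180, n - 1), NA))
  rebuild_backbone_from_torsions(tor, rbind(c(0, 0, 0), c(1.458, 0, 0),
                                            c(2.009, 1.422, 0)))
}

tlc_on_model <- function(m, lo, hi, piv, loop_tor, n_scan = 360L) {
  tt <- compute_backbone_torsions(m)
  triaxial_loop_closure(
    loop_tor, anchor_coords(m, lo - 1L), anchor_coords(m, hi + 1L), piv,
    psi0 = tt$psi[lo - 1L], omega0 = tt$omega[lo - 1L],
    phi_end = tt$phi[hi + 1L], n_scan = n_scan)
}

test_that("closure recovers the original torsions after pivot perturbation", {
  for (seed in 1:6) {
    m <- random_closed_chain(14, seed)
    tt <- compute_backbone_torsions(m)
    lo <- 4L; hi <- 11L; piv <- c(1L, 4L, 8L)
    orig <- tt[lo:hi, ]
    pert <- orig
    set.seed(seed + 100)
    pert$phi[piv] <- wrap180(pert$phi[piv] + runif(3, -80, 80))
    pert$psi[piv] <- wrap180(pert$psi[piv] + runif(3, -80, 80))
    sols <- tlc_on_model(m, lo, hi, piv, pert)
    expect_gt(length(sols), 0)
    rec <- vapply(sols, function(s)
      max(circ_absdiff(s$torsions$phi[piv], orig$phi[piv]),
          circ_absdiff(s$torsions$psi[piv], orig$psi[piv])), numeric(1))
    expect_lt(min(rec), 1e-4)
    expect_true(all(vapply(sols, `[[`, numeric(1), "gap") < 1e-6))
    # non-pivot torsions unchanged in every solution
    np <- setdiff(seq_len(nrow(orig)), piv)
    for (s in sols) {
      expect_lte(max(circ_absdiff(s$torsions$phi[np], pert$phi[np])), 1e-6)
      expect_lte(max(circ_absdiff(s$torsions$psi[np], pert$psi[np])), 1e-6)
    }
  }
})

test_that("every solution closes the chain; counts stable under denser scans", {
  n_cases <- 0L; n_sols <- 0L
  for (seed in 1:10) {
    m <- random_closed_chain(13, seed + 50)
    tt <- compute_backbone_torsions(m)
    lo <- 3L; hi <- 10L; piv <- c(1L, 4L, 8L)
    tor <- tt[lo:hi, ]
    set.seed(seed)
    tor$phi <- wrap180(tor$phi + rnorm(8, 0, 25))
    tor$psi <- wrap180(tor$psi + rnorm(8, 0, 25))
    s360 <- tlc_on_model(m, lo, hi, piv, tor, n_scan = 360L)
    s1440 <- tlc_on_model(m, lo, hi, piv, tor, n_scan = 1440L)
    expect_identical(length(s360), length(s1440))
    expect_lte(length(s360), 16L)
    n_cases <- n_cases + 1L
    n_sols <- n_sols + length(s360)
    for (s in s360) expect_lt(s$gap, 1e-6)
  }
  expect_gt(n_sols, 0)
})

test_that("unreachable anchors give an empty solution list", {
  m <- random_closed_chain(12, 3)
  tt <- compute_backbone_torsions(m)
  lo <- 4L; hi <- 8L
  far <- anchor_coords(m, hi + 1L) + 40   # move the C anchor far away
  sols <- triaxial_loop_closure(tt[lo:hi, ], anchor_coords(m, lo - 1L), far,
                                c(1L, 3L, 5L), psi0 = tt$psi[lo - 1L],
                                omega0 = tt$omega[lo - 1L],
                                phi_end = tt$phi[hi + 1L])
  expect_identical(sols, list())
})

test_that("close_loop_span splices solutions without touching the rest", {
  m <- cached_bundle()
  n <- n_res(m)
  lo <- 13L; hi <- 17L
  tt <- compute_backbone_torsions(m)
  set.seed(9)
  newtor <- data.frame(phi = wrap180(tt$phi[lo:hi] + rnorm(5, 0, 30)),
                       psi = wrap180(tt$psi[lo:hi] + rnorm(5, 0, 30)))
  cands <- close_loop_span(m, lo, hi, newtor)
  expect_gt(length(cands), 0)
  for (cand in cands) {
    expect_true(chain_intact(cand))
    outside <- cand$atom_resi < lo - 1L | cand$atom_resi > hi
    expect_lte(max(abs(cand$xyz[outside, ] - m$xyz[outside, ])), 1e-6)
  }
})
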