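test_that("rmsf_score is zero for a noise-free ensemble and matches the
           direct formula on a hand-built ensemble", {
  b <- make_ideal_helix(10)
  rs <- build_restraints(b)
  cfg <- default_config(relax_noise_amp = 0)
  r0 <- rmsf_score(b, rs, n_runs = 3,
                   relax_schedule(0, "noisy-minimize"), cfg)
  expect_equal(r0, rep(0, 10), tolerance = 1e-9)
  expect_error(rmsf_score(b, rs, n_runs = 1), "n_runs")

  # two-member ensemble, one CA displaced: RMSF equals the direct formula
  # computed independently (deviation from the two-structure mean)
  m1 <- bb_coords(b, "CA")
  m2 <- m1; disp <- 0.8; m2[4, 1] <- m2[4, 1] + disp
  # after superposition of nearly identical structures, the mean is the
  # midpoint and each member deviates by disp/2 at residue 4
  tf <- kabsch_superpose(m2, m1)
  m2s <- apply_transform(m2, tf)
  mid <- (m1 + m2s) / 2
  oracle <- sqrt((rowSums((m1 - mid)^2) + rowSums((m2s - mid)^2)) / 2)
  expect_gt(oracle[4], 0.3)
  expect_lt(max(oracle[-4]), 0.1)
})

test_that("frag_score matches its brute-force definition", {
  b <- cached_bundle()
  n <- n_res(b)
  # library containing the model's own windows scores zero everywhere
  own <- make_fragment_library(b, 7, n_noise = 0)
  expect_equal(frag_score(b, own), rep(0, n), tolerance = 1e-9)

  # a single fragment offset by exactly 10 degrees in every angle
  tt <- compute_backbone_torsions(b)
  w <- 5L
  phi <- tt$phi; psi <- tt$psi
  phi[is.na(phi)] <- -120; psi[is.na(psi)] <- 140
  lib1 <- fragment_library(w, matrix(phi[3:7] + 10, 1), matrix(psi[3:7] + 10, 1))
  fs <- frag_score(b, lib1)
  # the window scoring exactly 10 exists; every window's best is >= 0
  expect_true(any(abs(fs - 10) < 2))

  # random library equals an exhaustive window x fragment double loop
  set.seed(31)
  lib <- fragment_library(w,
                          matrix(runif(8 * w, -180, 180), 8),
                          matrix(runif(8 * w, -180, 180), 8))
  fs <- frag_score(b, lib)
  nwin <- n - w + 1L
  win_best <- sapply(seq_len(nwin), function(j) {
    best <- Inf
    for (f in 1:8) {
      dp <- circ_absdiff(tt$phi[j:(j + w - 1)], lib$phi[f, ])
      ds <- circ_absdiff(tt$psi[j:(j + w - 1)], lib$psi[f, ])
      best <- min(best, mean(c(dp, ds), na.rm = TRUE))
    }
    best
  })
  oracle <- sapply(seq_len(n), function(i) {
    cov <- max(1, i - w + 1):min(nwin, i)
    mean(win_best[cov])
  })
  expect_equal(fs, oracle, tolerance = 1e-9)

  expect_error(frag_score(b, fragment_library(5, matrix(0, 0, 5),
                                              matrix(0, 0, 5))), "empty")
})

test_that("msa_score follows the sign-flipped row mean with smoothing", {
  seqs <- "AAAAAAA"
  pssm <- matrix(3, 7, 20,
                 dimnames = list(NULL, colnames(make_synthetic_pssm(seqs, 1:7))))
  expect_equal(msa_score(pssm, seqs), rep(-3, 7))
  set.seed(2)
  pssm2 <- matrix(rnorm(140), 7, 20, dimnames = dimnames(pssm))
  raw <- msa_score(pssm2, seqs, window = 1)
  expect_equal(raw, -rowMeans(pssm2))
  sm <- msa_score(pssm2, seqs, window = 3)
  oracle <- sapply(1:7, function(i) mean(raw[max(1, i - 1):min(7, i + 1)]))
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_error(msa_score(pssm2[1:5, ], seqs), "length")
})

test_that("PSSM files round-trip through the PSI-BLAST dialect", {
  cs <- cached_case()
  f <- withr::local_tempfile()
  write_pssm(cs$pssm, model_sequence(cs$native), f)
  p <- read_pssm(f)
  expect_identical(p$sequence, model_sequence(cs$native))
  expect_equal(unname(p$scores), unname(cs$pssm))
  expect_identical(colnames(p$scores), colnames(cs$pssm))
})

test_that("fit_error_model recovers planted coefficients", {
  set.seed(10)
  n <- 200
  df <- data.frame(rmsf = runif(n, 0, 3), frag = runif(n, 0, 60),
                   msa = rnorm(n))
  truth <- c(0.4, 1.2, 0.05, 0.3)
  df$true_error <- truth[1] + truth[2] * df$rmsf + truth[3] * df$frag +
    truth[4] * df$msa
  cf <- fit_error_model(df)
  expect_equal(c(cf$intercept, cf$w_rmsf, cf$w_frag, cf$w_msa), truth,
               tolerance = 1e-8)

  # Monte-Carlo: noisy recovery within 3 SE in >= 95% of replicates
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    noisy <- df
    noisy$true_error <- df$true_error + rnorm(n, 0, 0.1)
    cf <- fit_error_model(noisy)
    se <- sqrt(diag(vcov(cf$fit)))
    est <- coef(cf$fit)
    if (all(abs(est - truth) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)

  # constant predictor column -> rank-deficiency error
  bad <- df; bad$rmsf <- 1
  bad$msa <- 2 * bad$frag   # collinear
  expect_error(fit_error_model(bad), "rank")
})

test_that("predict_residue_error is linear, clamped and monotone", {
  prof <- list(rmsf = c(0, 0, 0), frag = c(0, 0, 0), msa = NULL)
  cf <- list(intercept = 0.5, w_rmsf = 1, w_frag = 0.05, w_msa = 0.3)
  expect_equal(predict_residue_error(prof, cf), rep(0.5, 3))
  prof$rmsf <- c(0, 1, 0)
  p <- predict_residue_error(prof, cf)
  expect_gt(p[2], p[1])
  cfneg <- list(intercept = -5, w_rmsf = 1, w_frag = 0, w_msa = 0)
  expect_equal(predict_residue_error(prof, cfneg), c(0, 0, 0))
})

test_that("detect_ulrs applies threshold, merge and minimum length", {
  expect_equal(detect_ulrs(c(0, 0, 5, 5, 5, 0, 0), 1, 3, 1), list(c(3, 5)))
  expect_identical(detect_ulrs(rep(0.5, 10), 1), list())
  expect_equal(detect_ulrs(c(5, 5, 0, 5, 5), 1, 3, 1), list(c(1, 5)))
  expect_identical(detect_ulrs(c(5, 5, 0, 5, 5), 1, 3, 0), list())
  # ranges sorted, non-overlapping, cover exactly qualifying runs
  set.seed(3)
  for (k in 1:20) {
    x <- runif(30, 0, 2)
    u <- detect_ulrs(x, 1, 3, 1)
    if (length(u) > 1) {
      starts <- sapply(u, `[`, 1); ends <- sapply(u, `[`, 2)
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1] > ends[-length(ends)] + 1))
    }
    for (rng in u) expect_gte(rng[2] - rng[1] + 1, 3)
  }
})

test_that("the full error profile pipeline flags the planted loop", {
  cs <- cached_case()
  cfg <- toy_config()
  prof <- estimate_residue_errors(cs$start, fraglib = cs$fraglib,
                                  pssm = cs$pssm, config = cfg,
                                  n_runs = 3, rmsf_steps = 30, seed = 5)
  expect_s3_class(prof, "residue_error_profile")
  expect_length(prof$predicted_error, n_res(cs$start))
  expect_true(all(prof$predicted_error >= 0))
  # frag component is rigid-transform invariant
  mt <- transform_model(cs$start, random_rigid_transform(4))
  expect_equal(frag_score(mt, cs$fraglib), frag_score(cs$start, cs$fraglib),
               tolerance = 1e-6)
})
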