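# Shared fixtures (memoized: bundle construction searches a placement grid)
# and independent oracles used across test files.

.fix_env <- new.env()

cached_bundle <- function(n_per_helix = 12L, loop_len = 5L) {
  key <- paste0("b", n_per_helix, "_", loop_len)
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- make_two_helix_bundle(n_per_helix, loop_len)
  .fix_env[[key]]
}

cached_case <- function(size = 40L, start_rmsd = 2.5, seed = 2L) {
  key <- paste0("c", size, "_", seed)
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- make_refinement_case(size, start_rmsd, seed)
  .fix_env[[key]]
}

toy_config <- function(...) {
  default_config(capacity = 6L, trials_per_member = 4L, cycles = 2L,
                 steps_long = 30L, steps_standard = 12L, steps_short = 6L,
                 rmsf_n_runs = 3L, sidechain_repack_every = 15L,
                 tlc_grid = 150L, seed = 7L, ...)
}

# random compact decoy pair for metric oracles
random_toy_pair <- function(n, seed, noise = 1.0) {
  set.seed(seed)
  tor <- data.frame(resi = seq_len(n),
                    phi = c(NA, runif(n - 1, -150, -50)),
                    psi = c(runif(n - 1, -70, 160), NA),
                    omega = c(rep(180, n - 1), NA))
  ref <- rebuild_backbone_from_torsions(tor, rbind(c(0, 0, 0),
                                                   c(1.458, 0, 0),
                                                   c(2.009, 1.422, 0)))
  mod <- ref
  mod$xyz <- mod$xyz + matrix(rnorm(length(mod$xyz), 0, noise),
                              nrow(mod$xyz), 3L)
  list(model = mod, reference = ref)
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(rotation = R, translation = rnorm(3, 0, 10))
}

transform_model <- function(model, tf) {
  model$xyz <- sweep(model$xyz %*% tf$rotation, 2, tf$translation, `+`)
  model
}

# --- independent oracles ----------------------------------------------

# RMSD minimized over rotations via a quaternion-parametrized numerical
# optimizer (independent of the SVD route)
oracle_min_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  }
  obj <- function(q) sqrt(mean(rowSums((A %*% t(quat_rot(q)) - B)^2)))
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    r <- optim(rnorm(4), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# all CA-index subsets of size >= 3 (n <= 10), superpose on each, count
# residues under each threshold -> exhaustive GDT oracle
oracle_gdt_ha <- function(model, reference) {
  M <- bb_coords(model, "CA"); R <- bb_coords(reference, "CA")
  n <- nrow(M)
  stopifnot(n <= 10)
  subsets <- list()
  for (k in 3:n) subsets <- c(subsets,
                              combn(n, k, simplify = FALSE))
  thr <- c(0.5, 1, 2, 4)
  best <- rep(0, length(thr))
  for (S in subsets) {
    tf <- kabsch_superpose(M[S, , drop = FALSE], R[S, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(M, tf) - R)^2))
    for (j in seq_along(thr)) best[j] <- max(best[j], sum(d < thr[j]))
  }
  mean(best / n) * 100
}

oracle_tm_score <- function(model, reference) {
  M <- bb_coords(model, "CA"); R <- bb_coords(reference, "CA")
  L <- nrow(M)
  stopifnot(L <= 10)
  d0 <- if (L < 16) 0.5 else 1.24 * (L - 15)^(1 / 3) - 1.8
  subsets <- list()
  for (k in 3:L) subsets <- c(subsets, combn(L, k, simplify = FALSE))
  best <- 0
  for (S in subsets) {
    tf <- kabsch_superpose(M[S, , drop = FALSE], R[S, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(M, tf) - R)^2))
    best <- max(best, mean(1 / (1 + (d / d0)^2)))
  }
  best
}

# brute-force pair enumeration LDDT (CA mode), written independently
oracle_lddt_ca <- function(model, reference, radius = 15) {
  M <- bb_coords(model, "CA"); R <- bb_coords(reference, "CA")
  n <- nrow(M)
  hits <- c(); tot <- 0
  devs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) < 2) next
    dr <- sqrt(sum((R[i, ] - R[j, ])^2))
    if (dr >= radius) next
    dm <- sqrt(sum((M[i, ] - M[j, ])^2))
    devs <- c(devs, abs(dm - dr))
  }
  if (!length(devs)) return(100)
  mean(sapply(c(0.5, 1, 2, 4), function(t) mean(devs < t))) * 100
}

# brute-force clash counting
oracle_clash <- function(model, overlap = 0.4) {
  rad_tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  k <- nrow(model$xyz)
  el <- substr(sub("^[0-9]", "", model$atom_name), 1, 1)
  rad <- rad_tab[el]; rad[is.na(rad)] <- 1.7
  cnt <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (abs(model$atom_resi[i] - model$atom_resi[j]) < 2) next
    d <- sqrt(sum((model$xyz[i, ] - model$xyz[j, ])^2))
    if (d < rad[i] + rad[j] - overlap) cnt <- cnt + 1
  }
  cnt / k * 1000
}

# brute-force CA-CA restraint pair enumeration
oracle_ca_pairs <- function(model, min_sep = 4, max_dist = 12) {
  CA <- bb_coords(model, "CA")
  n <- nrow(CA)
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < min_sep) next
    d <- sqrt(sum((CA[i, ] - CA[j, ])^2))
    if (d < max_dist) out <- rbind(out, c(i, j, d))
  }
  out
}
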