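# Residue-wise model-error estimation: structural fluctuation (RMSF),
# fragment-library torsion agreement (FRAG), sequence-profile conservation
# (MSA), a linear model combining them, and unreliable-local-region (ULR)
# detection.

#' Fragment library constructor
#'
#' @param window Fragment window length in residues.
#' @param phi,psi Matrices (fragments x window) of torsions in degrees.
#' @param id Optional fragment identifiers.
#' @return A `fragment_library`.
#' @export
fragment_library <- function(window, phi, psi, id = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(ncol(phi) == window, ncol(psi) == window,
            nrow(phi) == nrow(psi))
  structure(list(window = as.integer(window), phi = phi, psi = psi,
                 id = id %||% sprintf("frag%04d", seq_len(nrow(phi)))),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %d fragments, window %d\n",
              nrow(x$phi), x$window))
  invisible(x)
}

#' Read a fragment library from TSV
#'
#' Dialect: header row, then one row per fragment with columns
#' `id`, `window`, `phi_1..phi_w`, `psi_1..psi_w` (degrees).
#'
#' @param path TSV file path.
#' @return A `fragment_library`.
#' @export
read_fragment_library <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  w <- unique(df$window)
  if (length(w) != 1L) stop("mixed window lengths in fragment library")
  fragment_library(w,
                   as.matrix(df[, sprintf("phi_%d", seq_len(w)), drop = FALSE]),
                   as.matrix(df[, sprintf("psi_%d", seq_len(w)), drop = FALSE]),
                   id = as.character(df$id))
}

#' Write a fragment library to TSV
#' @param lib A `fragment_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragment_library <- function(lib, path) {
  w <- lib$window
  df <- data.frame(id = lib$id, window = w)
  colnames(lib$phi) <- sprintf("phi_%d", seq_len(w))
  colnames(lib$psi) <- sprintf("psi_%d", seq_len(w))
  utils::write.table(cbind(df, lib$phi, lib$psi), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Residue-wise RMSF score from repeated noisy relaxations
#'
#' Runs `n_runs` independently seeded noisy-minimize relaxations of the
#' model (side chains repacked every `sidechain_repack_every` steps),
#' superposes the resulting ensemble onto its iteratively refined CA mean
#' structure, and reports the per-residue root-mean-square CA deviation
#' from the mean. The protocol default is 24 runs of the long schedule.
#'
#' @param model A `protein_model`.
#' @param restraints A `restraint_set` (typically built from `model`).
#' @param n_runs Number of relaxation runs (>= 2).
#' @param schedule Base [relax_schedule()]; its seed is re-derived per run.
#' @param config Configuration.
#' @return Numeric vector of per-residue RMSF (Angstrom).
#' @export
rmsf_score <- function(model, restraints, n_runs = 24L,
                       schedule = relax_schedule(default_config()$steps_long,
                                                 "noisy-minimize"),
                       config = default_config()) {
  if (n_runs < 2L) stop("n_runs must be >= 2")
  ens <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    sk <- schedule
    sk$rng_seed <- split_seed(schedule$rng_seed, k)
    ens[[k]] <- bb_coords(relax(model, restraints, sk, config), "CA")
  }
  mean_str <- ens[[1L]]
  for (it in 1:5) {
    aligned <- lapply(ens, function(X)
      apply_transform(X, kabsch_superpose(X, mean_str)))
    mean_str <- Reduce(`+`, aligned) / n_runs
  }
  dev2 <- Reduce(`+`, lapply(aligned, function(X) rowSums((X - mean_str)^2)))
  sqrt(dev2 / n_runs)
}

#' Fragment-agreement (FRAG) score
#'
#' For every window position, the minimum over library fragments of the
#' mean circular absolute phi/psi difference (degrees) between the model
#' window and the fragment; each residue's score is the mean over the
#' windows covering it. Low values mean the local backbone looks like known
#' fragments; high values flag unusual (likely wrong) local structure.
#'
#' @param model A `protein_model`.
#' @param library A `fragment_library`.
#' @return Numeric vector of per-residue scores (degrees).
#' @export
frag_score <- function(model, library) {
  if (!inherits(library, "fragment_library") || nrow(library$phi) == 0L)
    stop("empty fragment library")
  w <- library$window
  n <- n_res(model)
  if (w > n) stop("fragment window exceeds residue count")
  tt <- compute_backbone_torsions(model)
  nwin <- n - w + 1L
  win_score <- numeric(nwin)
  for (j in seq_len(nwin)) {
    mp <- tt$phi[j:(j + w - 1L)]; ms <- tt$psi[j:(j + w - 1L)]
    best <- Inf
    for (f in seq_len(nrow(library$phi))) {
      dp <- circ_absdiff(mp, library$phi[f, ])
      ds <- circ_absdiff(ms, library$psi[f, ])
      v <- mean(c(dp, ds), na.rm = TRUE)
      if (v < best) best <- v
    }
    win_score[j] <- best
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    cov <- max(1L, i - w + 1L):min(nwin, i)
    out[i] <- mean(win_score[cov])
  }
  out
}

#' Sequence-profile (MSA) score from a PSSM
#'
#' Per-residue raw value is the mean of the 20 substitution-score components
#' of that position's PSSM row, sign-flipped so that larger values mean less
#' conserved positions and hence larger expected model error. Optionally
#' smoothed by a centered moving average.
#'
#' @param pssm Numeric matrix (positions x 20) of PSSM scores.
#' @param sequence One-letter sequence (length must match rows).
#' @param window Odd moving-average width (1 = no smoothing).
#' @param component `"mean"` (row mean) or `"native"` (the native residue's
#'   own component).
#' @return Numeric vector of per-residue scores.
#' @export
msa_score <- function(pssm, sequence, window = 1L,
                      component = c("mean", "native")) {
  component <- match.arg(component)
  pssm <- as.matrix(pssm)
  seqv <- strsplit(sequence, "")[[1L]]
  if (nrow(pssm) != length(seqv))
    stop("PSSM row count does not match sequence length")
  raw <- if (component == "mean") -rowMeans(pssm)
  else {
    cols <- match(seqv, colnames(pssm))
    if (anyNA(cols)) stop("PSSM columns must be named by one-letter code")
    -pssm[cbind(seq_len(nrow(pssm)), cols)]
  }
  if (window <= 1L) return(raw)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  half <- (window - 1L) %/% 2L
  n <- length(raw)
  vapply(seq_len(n), function(i)
    mean(raw[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Read a PSI-BLAST style ASCII PSSM
#'
#' Parses the classic `psiblast -out_ascii_pssm` dialect: rows of
#' `pos aa` followed by 20 integer substitution scores.
#'
#' @param path File path.
#' @return List with `sequence` (string) and `scores` (positions x 20
#'   matrix, columns named by one-letter code).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  aa_order <- NULL
  rows <- list(); seqv <- character(0)
  for (tk in toks) {
    if (length(tk) >= 20L && all(tk[1:20] %in% names(AA1)) && is.null(aa_order)) {
      aa_order <- tk[1:20]; next
    }
    if (length(tk) >= 22L && grepl("^[0-9]+$", tk[1L]) && tk[2L] %in% names(AA1)) {
      rows[[length(rows) + 1L]] <- as.numeric(tk[3:22])
      seqv <- c(seqv, tk[2L])
    }
  }
  if (!length(rows)) stop("no PSSM rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- aa_order %||% names(AA1)
  list(sequence = paste(seqv, collapse = ""), scores = scores)
}

#' Fit the linear residue-error model
#'
#' Ordinary least squares of true per-residue error on the RMSF, FRAG and
#' (when present) MSA scores, pooled over profiles.
#'
#' @param data Data frame with columns `rmsf`, `frag`, `true_error` and
#'   optionally `msa`.
#' @return An `error_model_coefficients` list with `intercept`, `w_rmsf`,
#'   `w_frag`, `w_msa` (NA when msa absent).
#' @export
fit_error_model <- function(data) {
  has_msa <- "msa" %in% names(data)
  if (nrow(data) < (3L + has_msa) + 4L)
    stop("need at least 4 more observations than parameters")
  fml <- if (has_msa) true_error ~ rmsf + frag + msa else true_error ~ rmsf + frag
  fit <- stats::lm(fml, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient design (constant predictor column?)")
  structure(list(intercept = unname(cf[1L]), w_rmsf = unname(cf["rmsf"]),
                 w_frag = unname(cf["frag"]),
                 w_msa = if (has_msa) unname(cf["msa"]) else NA_real_,
                 fit = fit),
            class = "error_model_coefficients")
}

#' Predict per-residue error from scores
#'
#' Linear combination `intercept + w_rmsf*rmsf + w_frag*frag + w_msa*msa`,
#' clamped at zero from below. A missing MSA score contributes nothing.
#'
#' @param profile A `residue_error_profile` or list with `rmsf`, `frag`,
#'   optionally `msa` vectors.
#' @param coeffs An `error_model_coefficients` (or list with the same
#'   fields).
#' @return Numeric vector of predicted errors (Angstrom scale).
#' @export
predict_residue_error <- function(profile, coeffs) {
  p <- coeffs$intercept + coeffs$w_rmsf * profile$rmsf +
    coeffs$w_frag * profile$frag
  if (!is.null(profile$msa) && !all(is.na(profile$msa)) &&
      !is.na(coeffs$w_msa %||% NA_real_))
    p <- p + coeffs$w_msa * profile$msa
  pmax(p, 0)
}

#' Detect unreliable local regions (ULRs)
#'
#' Maximal runs of residues whose predicted error exceeds `threshold`; runs
#' separated by at most `merge_gap` below-threshold residues are merged;
#' merged runs shorter than `min_len` are discarded. Terminal residues are
#' treated like any others.
#'
#' @param predicted_error Numeric per-residue vector.
#' @param threshold Error threshold (strictly exceeded to qualify).
#' @param min_len Minimum run length kept.
#' @param merge_gap Maximum below-threshold gap bridged when merging.
#' @return List of `c(start, end)` 1-based inclusive ranges (possibly empty).
#' @export
detect_ulrs <- function(predicted_error, threshold, min_len = 3L,
                        merge_gap = 1L) {
  stopifnot(min_len >= 1L)
  high <- predicted_error > threshold
  if (!any(high)) return(list())
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- Map(c, starts[r$values], ends[r$values])
  merged <- list(runs[[1L]])
  for (k in seq_along(runs)[-1L]) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1L] - last[2L] - 1L <= merge_gap)
      merged[[length(merged)]] <- c(last[1L], runs[[k]][2L])
    else merged[[length(merged) + 1L]] <- runs[[k]]
  }
  keep <- vapply(merged, function(x) x[2L] - x[1L] + 1L >= min_len, logical(1))
  merged[keep]
}

#' Full residue-error profile of a model
#'
#' Convenience orchestrator: computes the RMSF, FRAG and MSA scores,
#' combines them with the given (or shipped default) coefficients and
#' detects ULRs at `threshold` (default: mean + 1 SD of the predicted
#' error).
#'
#' @param model A validated `protein_model`.
#' @param fraglib Optional `fragment_library` (FRAG scores are 0 without).
#' @param pssm Optional PSSM matrix (positions x 20); MSA scores absent
#'   without.
#' @param restraints Optional `restraint_set` (built from `model` if NULL).
#' @param coeffs Optional `error_model_coefficients`; defaults to the
#'   shipped configuration coefficients.
#' @param config Configuration.
#' @param n_runs RMSF relaxation runs (default from config).
#' @param rmsf_steps Steps per RMSF run (default: the long schedule).
#' @param threshold ULR threshold (NULL = mean + 1 SD).
#' @param seed RNG seed for the RMSF ensemble.
#' @return A `residue_error_profile` with fields `rmsf`, `frag`, `msa`,
#'   `predicted_error`, `ulrs`, `threshold`.
#' @export
estimate_residue_errors <- function(model, fraglib = NULL, pssm = NULL,
                                    restraints = NULL, coeffs = NULL,
                                    config = default_config(),
                                    n_runs = config$rmsf_n_runs,
                                    rmsf_steps = config$steps_long,
                                    threshold = NULL, seed = config$seed) {
  n <- n_res(model)
  restraints <- restraints %||% build_restraints(model, config = config)
  sched <- relax_schedule(rmsf_steps, "noisy-minimize",
                          config$sidechain_repack_every,
                          rng_seed = split_seed(seed, 101L))
  rmsf <- rmsf_score(model, restraints, n_runs, sched, config)
  frag <- if (is.null(fraglib)) numeric(n) else frag_score(model, fraglib)
  msa <- if (is.null(pssm)) NULL
  else msa_score(pssm, model_sequence(model), config$msa_window)
  coeffs <- coeffs %||% list(intercept = config$coef_intercept,
                             w_rmsf = config$coef_rmsf,
                             w_frag = config$coef_frag,
                             w_msa = config$coef_msa)
  prof <- list(rmsf = rmsf, frag = frag, msa = msa)
  pred <- predict_residue_error(prof, coeffs)
  thr <- threshold %||% (mean(pred) + stats::sd(pred))
  prof$predicted_error <- pred
  prof$threshold <- thr
  prof$ulrs <- detect_ulrs(pred, thr, config$ulr_min_len, config$ulr_merge_gap)
  structure(prof, class = "residue_error_profile")
}

#' @export
print.residue_error_profile <- function(x, ...) {
  cat(sprintf("<residue_error_profile> %d residues, %d ULR(s): %s\n",
              length(x$predicted_error), length(x$ulrs),
              paste(vapply(x$ulrs, function(u)
                sprintf("%d-%d", u[1L], u[2L]), character(1)),
                collapse = " ")))
  invisible(x)
}

#' Plot a residue-error profile
#' @param x A `residue_error_profile`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.residue_error_profile <- function(x, ...) {
  n <- length(x$predicted_error)
  graphics::plot(seq_len(n), x$predicted_error, type = "l",
                 xlab = "residue", ylab = "predicted error (A)", ...)
  graphics::abline(h = x$threshold, lty = 2)
  for (u in x$ulrs)
    graphics::rect(u[1L], 0, u[2L], max(x$predicted_error),
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}
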