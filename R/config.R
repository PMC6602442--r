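# Central configuration: every tunable of the energy function, relaxation
# schedules, error model, operators and refinement loop. Defaults are the
# protocol's stated operating point; tests and toy runs override scale
# parameters (pool size, step counts), never the physics.

#' Default configuration
#'
#' Returns the full set of named defaults. Pass overrides as arguments, e.g.
#' `default_config(capacity = 8, cycles = 2)`.
#'
#' @param ... Named overrides of any listed key (unknown keys error).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    # energy term weights (applied inside evaluate_energy)
    w_steric = 1.0, w_hbond = 0.5, w_torsion = 0.5, w_compact = 0.05,
    w_restraint = 1.0,
    # restraints
    restraint_form = "lorentzian",   # "harmonic" in conservative mode
    neglect_fraction = 0.10,         # worst 10% of each class ignored
    lorentz_c = 3.0,                 # softness of the Lorentzian (Angstrom)
    ca_pair_min_sep = 4L, ca_pair_max_dist = 12, no_pair_max_dist = 3.5,
    # h-bond reward well
    hbond_center = 3.0, hbond_sigma = 0.3,
    # compactness: expected radius of gyration 2.2 * L^0.38
    rg_coef = 2.2, rg_exp = 0.38,
    # relaxation step counts; ratios mirror 14.4 : 3.0 : 1.2 ps
    steps_long = 1200L, steps_standard = 250L, steps_short = 100L,
    sidechain_repack_every = 100L, relax_noise_amp = 0.3,
    # bonded surrogate force constants
    k_bond = 300, k_13 = 60, k_14 = 20,
    # error model
    coef_intercept = 0, coef_rmsf = 1.0, coef_frag = 0.05, coef_msa = 0.3,
    rmsf_n_runs = 24L, ulr_min_len = 3L, ulr_merge_gap = 1L,
    frag_window = 7L, msa_window = 1L,
    # elastic network
    enm_cutoff = 10, enm_spring = 1.0, n_low_modes = 10L, nm_amplitude = 1.0,
    nm_relax_steps = 80L,
    # operators
    ss_max_rot = 10, ss_max_trans = 1.0, mutate_sigma = 30,
    mix_coeff = 0.5, tlc_attempts = 20L, tlc_grid = 240L,
    # threading / patches
    tm_threshold = 0.5, min_coverage = 0.4,
    patch_min = 5L, patch_max = 15L, patch_stride = 5L,
    # refinement loop
    capacity = 48L, trials_per_member = 10L, cycles = 5L,
    closeness_start = 0.5, closeness_end = 2.0,
    mode = "default", seed = 1L,
    max_residues = 300L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (identical(cfg$mode, "conservative")) {
    if (!"restraint_form" %in% names(dots)) cfg$restraint_form <- "harmonic"
    if (!"neglect_fraction" %in% names(dots)) cfg$neglect_fraction <- 0.05
  }
  cfg
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric. Unknown keys are an error.
#'
#' @param path File path.
#' @param base Configuration to override (default [default_config()]).
#' @return Merged configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(base)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    base[[key]] <- if (!is.na(num)) num else val
  }
  base
}

#' Print all configuration keys and values
#' @param cfg Configuration list.
#' @return Invisibly, `cfg`.
#' @export
show_config <- function(cfg = default_config()) {
  for (k in names(cfg)) cat(sprintf("%-24s = %s\n", k, format(cfg[[k]])))
  invisible(cfg)
}
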