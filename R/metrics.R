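# Model-accuracy and stereochemistry measures. GDT-HA and TM-score use a
# seeded iterative fit-select superposition maximizer; LDDT and the clash
# score are superposition-free.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

check_same_length <- function(model, reference) {
  if (n_res(model) != n_res(reference))
    stop("models differ in residue count (", n_res(model), " vs ",
         n_res(reference), "); provide matched models")
}

# distances of all rows of M to R after superposing M[idx] onto R[idx]
superposed_dist <- function(M, R, idx) {
  tf <- kabsch_superpose(M[idx, , drop = FALSE], R[idx, , drop = FALSE])
  sqrt(rowSums((apply_transform(M, tf) - R)^2))
}

gdt_seed_sets <- function(n, lengths = c(3L, 5L, 7L)) {
  if (n <= 12L) {
    # exhaustive seeds: the maximization is exact for short chains
    seeds <- list()
    for (k in 3:n)
      seeds <- c(seeds, utils::combn(n, k, simplify = FALSE))
    return(seeds)
  }
  seeds <- list(seq_len(n))
  for (w in lengths[lengths <= n])
    for (s in seq_len(n - w + 1L))
      seeds[[length(seeds) + 1L]] <- s:(s + w - 1L)
  seeds
}

# iterative fit-select from one seed; returns max of score_fun(d) seen
fit_select <- function(M, R, seed, select_fun, score_fun, max_iter = 20L) {
  S <- seed
  best <- -Inf
  for (it in seq_len(max_iter)) {
    d <- superposed_dist(M, R, S)
    best <- max(best, score_fun(d))
    S2 <- select_fun(d)
    if (length(S2) < 3L) S2 <- order(d)[1:3]
    if (length(S2) == length(S) && all(S2 == S)) break
    S <- S2
  }
  best
}

#' CA RMSD between two models after optimal superposition
#' @param model,reference `protein_model`s of equal length.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model, reference) {
  check_same_length(model, reference)
  kabsch_superpose(bb_coords(model, "CA"), bb_coords(reference, "CA"))$rmsd
}

#' GDT-HA score
#'
#' Mean over the 0.5/1/2/4 Angstrom thresholds of the maximal percentage of
#' CA atoms that can be superposed within the threshold. The maximization is
#' a seeded fit-select heuristic: every contiguous window of lengths 3, 5, 7
#' plus the full chain seeds an iterative superpose-reselect loop run to
#' convergence; the best count per threshold is kept. For chains of at most
#' 12 residues the seed set is exhaustive over all CA subsets, making the
#' subset-superposition maximization exact.
#'
#' @param model,reference `protein_model`s of equal length.
#' @param seeds Optional list of integer index sets to seed the search
#'   (defaults to the contiguous windows described above).
#' @return Score in [0, 100].
#' @export
gdt_ha <- function(model, reference, seeds = NULL) {
  check_same_length(model, reference)
  M <- bb_coords(model, "CA"); R <- bb_coords(reference, "CA")
  n <- nrow(M)
  if (is.null(seeds)) seeds <- gdt_seed_sets(n)
  thr <- c(0.5, 1, 2, 4)
  frac <- vapply(thr, function(t) {
    best <- 0
    for (S in seeds)
      best <- max(best, fit_select(M, R, S,
                                   select_fun = function(d) which(d < t),
                                   score_fun = function(d) sum(d < t)))
    best / n
  }, numeric(1))
  mean(frac) * 100
}

#' TM-score
#'
#' Length-normalized structural similarity max over superpositions of
#' (1/L) sum 1/(1+(d_i/d0)^2) with d0 = 1.24 (L-15)^(1/3) - 1.8 Angstrom,
#' maximized by the same seeded fit-select scheme as [gdt_ha()]. For chains
#' shorter than 16 residues d0 is clamped to 0.5 Angstrom with a warning.
#'
#' @param model,reference `protein_model`s of equal length.
#' @param seeds Optional list of seed index sets.
#' @return Score in (0, 1].
#' @export
tm_score <- function(model, reference, seeds = NULL) {
  check_same_length(model, reference)
  M <- bb_coords(model, "CA"); R <- bb_coords(reference, "CA")
  L <- nrow(R)
  if (L < 16L) {
    warning("chain shorter than 16 residues; d0 clamped to 0.5 A")
    d0 <- 0.5
  } else d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  if (is.null(seeds)) seeds <- gdt_seed_sets(L)
  best <- 0
  for (S in seeds)
    best <- max(best, fit_select(M, R, S,
                                 select_fun = function(d) which(d < max(d0, 1.0)),
                                 score_fun = function(d) mean(1 / (1 + (d / d0)^2))))
  best
}

# matched atom table for superposition-free metrics
matched_atoms <- function(model, reference, mode = c("auto", "ca", "all")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    has_side <- any(!(model$atom_name %in% c("N", "CA", "C", "O"))) &&
      any(!(reference$atom_name %in% c("N", "CA", "C", "O")))
    mode <- if (has_side) "all" else "ca"
  }
  if (mode == "ca") {
    list(resi = seq_len(n_res(model)), M = bb_coords(model, "CA"),
         R = bb_coords(reference, "CA"))
  } else {
    km <- paste(model$atom_resi, model$atom_name)
    kr <- paste(reference$atom_resi, reference$atom_name)
    common <- intersect(km, kr)
    im <- match(common, km); ir <- match(common, kr)
    list(resi = model$atom_resi[im], M = model$xyz[im, , drop = FALSE],
         R = reference$xyz[ir, , drop = FALSE])
  }
}

#' LDDT score (0-100)
#'
#' Superposition-free local distance difference test: over all atom pairs
#' within 15 Angstrom in the reference with residue separation >= 2, the
#' fraction of pairs whose model distance deviates by less than
#' 0.5/1/2/4 Angstrom, averaged over the four tolerances, times 100.
#' No stereochemistry penalty term is applied.
#'
#' @param model,reference `protein_model`s of equal length.
#' @param mode `"auto"` (all-atom when side chains exist in both, else CA),
#'   `"ca"` or `"all"`.
#' @param inclusion_radius Reference-distance cutoff (default 15 Angstrom).
#' @return Score in [0, 100].
#' @export
lddt <- function(model, reference, mode = "auto", inclusion_radius = 15) {
  check_same_length(model, reference)
  ma <- matched_atoms(model, reference, mode)
  k <- nrow(ma$M)
  ii <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  jj <- sequence((k - 1L):1L) + ii
  dr <- row_norm(ma$R[ii, , drop = FALSE] - ma$R[jj, , drop = FALSE])
  keep <- dr < inclusion_radius & abs(ma$resi[ii] - ma$resi[jj]) >= 2L
  if (!any(keep)) return(100)
  dm <- row_norm(ma$M[ii[keep], , drop = FALSE] - ma$M[jj[keep], , drop = FALSE])
  dev <- abs(dm - dr[keep])
  mean(vapply(c(0.5, 1, 2, 4), function(t) mean(dev < t), numeric(1))) * 100
}

#' Steric clash score (clashes per 1000 atoms)
#'
#' Counts non-bonded atom pairs (residue separation >= 2) closer than the
#' sum of their van der Waals radii minus 0.4 Angstrom, normalized per 1000
#' atoms. A lightweight stand-in for probe-based all-atom clash scores.
#'
#' @param model A `protein_model`.
#' @param overlap Allowed overlap before a contact counts as a clash
#'   (default 0.4 Angstrom).
#' @return Clashes per 1000 atoms (>= 0).
#' @export
clash_score <- function(model, overlap = 0.4) {
  k <- nrow(model$xyz)
  elem <- element_of(model$atom_name)
  rad <- VDW_RADII[elem]; rad[is.na(rad)] <- 1.7
  ii <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  jj <- sequence((k - 1L):1L) + ii
  sep <- abs(model$atom_resi[ii] - model$atom_resi[jj])
  keep <- sep >= 2L
  d <- row_norm(model$xyz[ii[keep], , drop = FALSE] -
                  model$xyz[jj[keep], , drop = FALSE])
  nclash <- sum(d < rad[ii[keep]] + rad[jj[keep]] - overlap)
  nclash / k * 1000
}

#' Fraction of residues in favored backbone-torsion regions
#'
#' Torsion-bin Ramachandran surrogate: a residue is favored when (phi, psi)
#' falls in the broad helical, extended or left-handed-helical basins.
#'
#' @param model A `protein_model`.
#' @return Fraction in [0, 1] over residues with defined phi and psi.
#' @export
rama_favored <- function(model) {
  tt <- compute_backbone_torsions(model)
  ok <- !is.na(tt$phi) & !is.na(tt$psi)
  if (!any(ok)) return(NA_real_)
  phi <- tt$phi[ok]; psi <- tt$psi[ok]
  fav <- (phi > -160 & phi < -20 & psi > -120 & psi < 30) |     # helical
    (phi > -180 & phi < -20 & (psi > 60 | psi < -170)) |        # extended
    (phi > 20 & phi < 100 & psi > -60 & psi < 100)              # L-alpha
  mean(fav)
}

#' Full accuracy report for a model against a reference
#' @param model,reference `protein_model`s of equal length.
#' @return One-row data frame: `ca_rmsd`, `gdt_ha`, `lddt`, `tm_score`,
#'   `clash_per_1000`, `rama_favored_pct`.
#' @export
accuracy_report <- function(model, reference) {
  data.frame(ca_rmsd = ca_rmsd(model, reference),
             gdt_ha = gdt_ha(model, reference),
             lddt = lddt(model, reference),
             tm_score = tm_score(model, reference),
             clash_per_1000 = clash_score(model),
             rama_favored_pct = 100 * rama_favored(model))
}
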