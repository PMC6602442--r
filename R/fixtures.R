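# Synthetic-data generation: every input the refinement protocol consumes
# (models, decoys, PSSMs, fragment libraries, homolog/alignment pairs) can
# be built deterministically from a seed, so the whole pipeline is testable
# without downloads. Fixtures are backbone+CB ("coarse") by default; leucine
# residues get a full coarse side chain for side-chain tests.

default_anchor <- function() {
  g <- bb_geom()
  th <- deg2rad(g$ang_n_ca_c)
  rbind(c(0, 0, 0), c(g$n_ca, 0, 0),
        c(g$n_ca + g$ca_c * -cos(th), g$ca_c * sin(th), 0))
}

# minimal side-chain builder: LEU gets CG/CD1/CD2 from chi1/chi2; everything
# else stays at CB
add_coarse_sidechain <- function(al, aa, chi1 = -60, chi2 = 175) {
  if (aa != "L" || is.null(al$CB)) return(al)
  al$CG <- nerf_place(al$N, al$CA, al$CB, 1.53, 116.3, chi1)
  al$CD1 <- nerf_place(al$CA, al$CB, al$CG, 1.52, 110.7, chi2)
  al$CD2 <- nerf_place(al$CA, al$CB, al$CG, 1.52, 110.7, wrap180(chi2 + 120))
  al
}

build_chain_from_torsions <- function(phi, psi, sequence,
                                      anchor = default_anchor(),
                                      provenance = "input") {
  n <- length(phi)
  tor <- data.frame(resi = seq_len(n), phi = phi, psi = psi,
                    omega = c(rep(180, n - 1L), NA))
  m <- rebuild_backbone_from_torsions(tor, anchor, sequence = sequence)
  aa <- strsplit(sequence, "")[[1L]]
  if (any(aa == "L")) {
    ra <- residue_atoms(m)
    for (i in which(aa == "L")) ra[[i]] <- add_coarse_sidechain(ra[[i]], "L")
    m <- model_from_residue_atoms(aa, ra, provenance = provenance)
  } else m$provenance <- provenance
  m
}

#' Ideal alpha-helix fixture
#'
#' Backbone built from phi = -57, psi = -47, omega = 180 with ideal bond
#' geometry; poly-alanine by default (leucines get coarse side chains).
#'
#' @param n Residue count (>= 4).
#' @param sequence Optional one-letter sequence of length `n`.
#' @return A `protein_model`.
#' @export
make_ideal_helix <- function(n, sequence = NULL) {
  if (n < 4L) stop("need at least 4 residues")
  sequence <- sequence %||% paste(rep("A", n), collapse = "")
  build_chain_from_torsions(c(NA, rep(-57, n - 1L)),
                            c(rep(-47, n - 1L), NA), sequence)
}

#' Ideal extended-strand fixture
#' @param n Residue count (>= 3).
#' @param sequence Optional sequence.
#' @return A `protein_model` with phi = -120, psi = 120.
#' @export
make_ideal_strand <- function(n, sequence = NULL) {
  if (n < 3L) stop("need at least 3 residues")
  sequence <- sequence %||% paste(rep("A", n), collapse = "")
  build_chain_from_torsions(c(NA, rep(-120, n - 1L)),
                            c(rep(120, n - 1L), NA), sequence)
}

#' Two-helix bundle fixture
#'
#' Two antiparallel ideal helices connected by a TLC-closed coil loop:
#' compact (inter-helix CA contacts under 12 Angstrom feed the CA-CA pair
#' restraints), clash-free, single intact chain. Used as the synthetic
#' stand-in for a small folded protein.
#'
#' @param n_per_helix Residues per helix (>= 6).
#' @param loop_len Loop length (>= 3, default 5).
#' @param sequence Optional full sequence (length 2*n_per_helix + loop_len).
#' @param separation Lateral helix-helix distance in Angstrom.
#' @return A `protein_model`.
#' @export
make_two_helix_bundle <- function(n_per_helix, loop_len = 5L,
                                  sequence = NULL, separation = 10.5) {
  stopifnot(n_per_helix >= 6L, loop_len >= 3L)
  n1 <- n_per_helix; n2 <- n_per_helix
  ntot <- n1 + loop_len + n2
  sequence <- sequence %||% paste(rep("A", ntot), collapse = "")
  aa <- strsplit(sequence, "")[[1L]]
  stopifnot(length(aa) == ntot)

  h1 <- make_ideal_helix(n1)
  CA1 <- bb_coords(h1, "CA")
  axis <- vunit(CA1[n1, ] - CA1[1L, ])
  perp <- vunit(vcross(axis, if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))

  h2base <- make_ideal_helix(n2)
  h2base$xyz <- sweep(h2base$xyz, 2L, bb_coords(h2base, "CA")[1L, ])

  pivots <- unique(c(1L, (loop_len + 1L) %/% 2L, loop_len))
  if (length(pivots) < 3L) pivots <- c(1L, 2L, loop_len)

  # deterministic search over the free join torsions (psi of the last
  # helix-1 residue, phi of the first helix-2 residue -- both undefined
  # inside the helices), loop torsions, helix-2 spin and axial offset;
  # first clash-free closed candidate wins
  grid <- expand.grid(att = 1:2, psi0 = c(-47, 60, 150, -120),
                      phi_end = c(-57, -120, 60),
                      spin = seq(0, 300, by = 60),
                      back = c(2.0, 0.5, 3.5), sep_mult = c(1, 0.93))
  for (gidx in seq_len(nrow(grid))) {
    att <- grid$att[gidx]; spin <- grid$spin[gidx]; back <- grid$back[gidx]
    sep <- separation * grid$sep_mult[gidx]
    loop_tor <- if (att == 1L)
      data.frame(resi = seq_len(loop_len), phi = rep(-80, loop_len),
                 psi = rep(80, loop_len), omega = rep(180, loop_len))
    else with_seed(split_seed(977L, gidx), data.frame(
      resi = seq_len(loop_len),
      phi = stats::runif(loop_len, -150, -50),
      psi = stats::runif(loop_len, -60, 160),
      omega = rep(180, loop_len)))
    h2t <- h2base
    h2t$xyz <- rotate_about_axis(h2t$xyz, c(0, 0, 0), axis, deg2rad(spin))
    h2t$xyz <- rotate_about_axis(h2t$xyz, c(0, 0, 0), perp, pi)
    target_ca <- CA1[n1, ] + sep * perp - back * axis
    h2t$xyz <- sweep(h2t$xyz, 2L, target_ca - bb_coords(h2t, "CA")[1L, ], `+`)
    sols <- triaxial_loop_closure(
      loop_tor, anchor_coords(h1, n1), anchor_coords(h2t, 1L), pivots,
      psi0 = grid$psi0[gidx], omega0 = 180, phi_end = grid$phi_end[gidx],
      n_scan = 240L)
    if (!length(sols)) next
    for (s in sols) {
      ra <- vector("list", ntot)
      ra[seq_len(n1)] <- residue_atoms(h1)
      ra[[n1]]$O <- place_O(ra[[n1]]$N, ra[[n1]]$CA, ra[[n1]]$C,
                            grid$psi0[gidx])
      for (k in seq_len(loop_len)) {
        al <- list(N = s$bb$N[k, ], CA = s$bb$CA[k, ], C = s$bb$C[k, ],
                   O = place_O(s$bb$N[k, ], s$bb$CA[k, ], s$bb$C[k, ],
                               s$torsions$psi[k]))
        if (aa[n1 + k] != "G")
          al$CB <- place_CB(s$bb$N[k, ], s$bb$CA[k, ], s$bb$C[k, ])
        ra[[n1 + k]] <- al
      }
      ra[(n1 + loop_len + 1L):ntot] <- residue_atoms(h2t)
      for (i in seq_len(ntot))
        ra[[i]] <- add_coarse_sidechain(ra[[i]][setdiff(names(ra[[i]]),
                                                        c("CG", "CD1", "CD2"))],
                                        aa[i])
      cand <- model_from_residue_atoms(aa, ra, provenance = "input")
      if (clash_score(cand) == 0 && validate_input(cand)$ok) return(cand)
    }
  }
  stop("could not build a clash-free bundle; adjust separation/loop_len")
}

#' Perturb a structure to a target CA-RMSD by torsion noise
#'
#' Adds seeded Gaussian noise to all defined phi/psi angles (optionally
#' weighted per residue), rebuilds the backbone, and scales the noise
#' amplitude by bisection until the CA-RMSD to the input lands within
#' [0.8, 1.2] x `target_rmsd`. Side chains ride along rigidly.
#'
#' @param model A `protein_model`.
#' @param target_rmsd Target CA-RMSD in Angstrom (0 returns the input).
#' @param seed RNG seed (same seed, same decoy).
#' @param weights Optional per-residue noise weights (default uniform).
#' @return A perturbed `protein_model`.
#' @export
perturb_structure <- function(model, target_rmsd, seed = 1L, weights = NULL) {
  if (target_rmsd <= 0) return(model)
  n <- n_res(model)
  weights <- weights %||% rep(1, n)
  tt <- compute_backbone_torsions(model)
  zphi <- with_seed(seed, stats::rnorm(n)) * weights
  zpsi <- with_seed(seed + 1L, stats::rnorm(n)) * weights
  anchor <- anchor_coords(model, 1L)

  build <- function(s) {
    tor <- tt
    tor$phi <- wrap180(tor$phi + s * zphi)
    tor$psi <- wrap180(tor$psi + s * zpsi)
    bb <- rebuild_backbone_from_torsions(tor, anchor, add_cb = FALSE)
    out <- set_backbone_span(model, 1L, n, bb_coords(bb, "N"),
                             bb_coords(bb, "CA"), bb_coords(bb, "C"))
    out$provenance <- "decoy"
    out
  }
  lo <- 0; hi <- 5 / sqrt(n)
  for (k in 1:20) {
    if (ca_rmsd(build(hi), model) >= target_rmsd) break
    hi <- hi * 2
    if (k == 20L) stop("target RMSD unreachable")
  }
  for (k in 1:50) {
    mid <- (lo + hi) / 2
    out <- build(mid)
    r <- ca_rmsd(out, model)
    if (r >= 0.8 * target_rmsd && r <= 1.2 * target_rmsd) return(out)
    if (r > target_rmsd) hi <- mid else lo <- mid
  }
  stop("bisection failed to reach target RMSD")
}

#' Synthetic PSSM with a planted conservation signal
#'
#' Positions flagged conserved get uniformly high substitution scores,
#' the rest uniformly low ones (plus seeded noise), so the sign-flipped
#' row-mean MSA score is low at conserved and high at variable positions.
#'
#' @param sequence One-letter sequence.
#' @param conserved Logical vector (per position) or integer positions.
#' @param seed RNG seed.
#' @param hi,lo Mean score at conserved / variable positions.
#' @return Positions x 20 integer-valued matrix, columns named by
#'   one-letter code.
#' @export
make_synthetic_pssm <- function(sequence, conserved, seed = 1L,
                                hi = 3, lo = -2) {
  n <- nchar(sequence)
  if (!is.logical(conserved)) conserved <- seq_len(n) %in% conserved
  base <- ifelse(conserved, hi, lo)
  scores <- with_seed(seed,
    round(matrix(stats::rnorm(n * 20L, 0, 0.5), n, 20L) + base))
  colnames(scores) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  scores
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#' @param scores Positions x 20 matrix (columns named by one-letter code).
#' @param sequence One-letter sequence.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(scores, sequence, path) {
  seqv <- strsplit(sequence, "")[[1L]]
  stopifnot(nrow(scores) == length(seqv))
  hdr <- c("", "Last position-specific scoring matrix computed",
           paste0("            ", paste(colnames(scores), collapse = "   ")))
  rows <- vapply(seq_len(nrow(scores)), function(i)
    sprintf("%5d %s %s", i, seqv[i],
            paste(sprintf("%3d", scores[i, ]), collapse = " ")),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Fragment library from a model's own torsions plus noise fragments
#'
#' Harvests every `window`-length torsion window of `model` (terminal NA
#' angles replaced by ideal coil values) and appends `n_noise` seeded
#' random-coil fragments.
#'
#' @param model Source `protein_model`.
#' @param window Window length (default 7).
#' @param n_noise Number of random fragments appended.
#' @param seed RNG seed.
#' @return A `fragment_library`.
#' @export
make_fragment_library <- function(model, window = 7L, n_noise = 30L,
                                  seed = 1L) {
  tt <- compute_backbone_torsions(model)
  phi <- tt$phi; psi <- tt$psi
  phi[is.na(phi)] <- -120; psi[is.na(psi)] <- 140
  n <- length(phi)
  nwin <- n - window + 1L
  P <- t(vapply(seq_len(nwin), function(j) phi[j:(j + window - 1L)],
                numeric(window)))
  S <- t(vapply(seq_len(nwin), function(j) psi[j:(j + window - 1L)],
                numeric(window)))
  if (n_noise > 0L) {
    noise <- with_seed(seed, list(
      phi = matrix(stats::runif(n_noise * window, -160, -40), n_noise, window),
      psi = matrix(stats::runif(n_noise * window, -60, 170), n_noise, window)))
    P <- rbind(P, noise$phi); S <- rbind(S, noise$psi)
  }
  fragment_library(window, P, S)
}

#' Complete synthetic refinement test case
#'
#' Builds a native two-helix bundle, a perturbed start model (noise
#' concentrated on the loop and termini so the planted error is localized),
#' a fragment library from the native torsions, a synthetic PSSM conserved
#' at helix positions, and two threaded-homolog decoys: one perturbed by
#' 1.5 Angstrom (above the TM-score 0.5 filter) and one by 8 Angstrom
#' (below it), each with an identity alignment.
#'
#' @param size Total residue count (helices sized to fit).
#' @param start_rmsd Target CA-RMSD of the start model from the native.
#' @param seed RNG seed; the whole case is deterministic in it.
#' @param loop_len Nominal loop length (default 5; grows by one when needed
#'   to hit `size` exactly with equal helices).
#' @return A `refinement_case` list: `native`, `start`, `pssm`, `fraglib`,
#'   `homologs` (list of `list(model, alignment)`), `target_start_rmsd`.
#' @export
make_refinement_case <- function(size, start_rmsd = 2.5, seed = 1L,
                                 loop_len = 5L) {
  stopifnot(size <= 300L, size >= 16L + loop_len)
  nph <- (size - loop_len) %/% 2L
  loop_eff <- size - 2L * nph
  native <- make_two_helix_bundle(nph, loop_eff)
  n <- n_res(native)
  stopifnot(n == size)
  loop_res <- (nph + 1L):(nph + loop_eff)
  w <- rep(1, n)
  w[loop_res] <- 4
  w[c(1:2, (n - 1L):n)] <- 3
  start <- perturb_structure(native, start_rmsd, seed = split_seed(seed, 1L),
                             weights = w)
  helix_pos <- setdiff(seq_len(n), c(loop_res, 1:2, (n - 1L):n))
  pssm <- make_synthetic_pssm(model_sequence(native),
                              seq_len(n) %in% helix_pos,
                              seed = split_seed(seed, 2L))
  fraglib <- make_fragment_library(native, seed = split_seed(seed, 3L))
  hom_near <- perturb_structure(native, 1.5, seed = split_seed(seed, 4L))
  hom_far <- perturb_structure(native, 8.0, seed = split_seed(seed, 5L))
  hom_near$provenance <- "threaded"; hom_far$provenance <- "threaded"
  seqs <- model_sequence(native)
  homologs <- list(
    list(model = hom_near,
         alignment = alignment_pair(seqs, seqs, "hom_near")),
    list(model = hom_far,
         alignment = alignment_pair(seqs, seqs, "hom_far")))
  structure(list(native = native, start = start, pssm = pssm,
                 fraglib = fraglib, homologs = homologs,
                 target_start_rmsd = start_rmsd, loop_res = loop_res),
            class = "refinement_case")
}

#' Write a refinement case to a directory as plain-text files
#' @param case A `refinement_case`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_refinement_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pdb(case$native, file.path(dir, "native.pdb"))
  write_pdb(case$start, file.path(dir, "start.pdb"))
  write_pssm(case$pssm, model_sequence(case$native),
             file.path(dir, "case.pssm"))
  write_fragment_library(case$fraglib, file.path(dir, "case.fraglib.tsv"))
  for (k in seq_along(case$homologs)) {
    write_pdb(case$homologs[[k]]$model,
              file.path(dir, sprintf("homolog_%d.pdb", k)))
    write_alignment_fasta(case$homologs[[k]]$alignment,
                          file.path(dir, sprintf("aln_%d.fasta", k)))
  }
  invisible(dir)
}
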