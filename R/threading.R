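# Threading the input sequence onto homolog structures along given
# alignments, filtering threaded models by TM-score to the input, light
# optimization, and harvesting non-ULR backbone patches for the structure
# hybridization operator.

#' Pairwise alignment container
#' @param query_seq,template_seq Aligned sequences with `-` gaps (equal
#'   length).
#' @param template_id Identifier of the template.
#' @return An `alignment_pair`.
#' @export
alignment_pair <- function(query_seq, template_seq, template_id = "template") {
  if (nchar(query_seq) != nchar(template_seq))
    stop("aligned sequences differ in length")
  structure(list(query_seq = query_seq, template_seq = template_seq,
                 template_id = template_id), class = "alignment_pair")
}

#' Read a two-sequence aligned FASTA file (query first)
#' @param path File path.
#' @return An `alignment_pair`.
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2L) stop("expected exactly 2 sequences in ", path)
  seqs <- vapply(seq_along(hdr), function(k) {
    from <- hdr[k] + 1L
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    paste(lines[from:to], collapse = "")
  }, character(1))
  alignment_pair(toupper(seqs[1L]), toupper(seqs[2L]),
                 sub("^>\\s*", "", lines[hdr[2L]]))
}

#' Write an alignment pair as aligned FASTA
#' @param aln An `alignment_pair`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(c(">query", aln$query_seq,
               paste0(">", aln$template_id), aln$template_seq), path)
  invisible(path)
}

#' Read an A3M alignment (first sequence = query master)
#'
#' Lowercase template letters are insertions relative to the query and
#' become query gaps in the returned pairwise alignments.
#'
#' @param path File path.
#' @return List of `alignment_pair` (one per non-query sequence).
#' @export
read_a3m <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) < 2L) stop("A3M needs a query and at least one sequence")
  get <- function(k) {
    from <- hdr[k] + 1L
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    paste(lines[from:to], collapse = "")
  }
  qmaster <- toupper(get(1L))
  out <- list()
  for (k in 2L:length(hdr)) {
    tmpl <- get(k)
    qc <- character(0); tc <- character(0)
    qcol <- 0L
    for (ch in strsplit(tmpl, "")[[1L]]) {
      if (ch %in% letters) {          # insertion in template
        qc <- c(qc, "-"); tc <- c(tc, toupper(ch))
      } else {
        qcol <- qcol + 1L
        qc <- c(qc, substr(qmaster, qcol, qcol)); tc <- c(tc, ch)
      }
    }
    out[[length(out) + 1L]] <- alignment_pair(
      paste(qc, collapse = ""), paste(tc, collapse = ""),
      sub("^>\\s*", "", lines[hdr[k]]))
  }
  out
}

#' Thread a sequence onto a homolog structure
#'
#' Aligned query residues inherit the homolog backbone (N/CA/C/O); side
#' chains are reduced to an ideally placed CB. Query residues aligned to
#' template gaps are rebuilt with coil torsions and closed by TLC between
#' the flanking threaded anchors (interior) or built freely (termini).
#' Interior insertions shorter than 3 residues absorb flanking aligned
#' residues into the rebuilt span to satisfy the TLC minimum.
#'
#' @param input_seq Ungapped query sequence.
#' @param homolog `protein_model` of the template structure.
#' @param alignment An `alignment_pair` (query first).
#' @param config Configuration.
#' @param seed Seed for coil-torsion draws in rebuilt segments.
#' @return A threaded `protein_model` (provenance `"threaded"`).
#' @export
thread_sequence <- function(input_seq, homolog, alignment,
                            config = default_config(), seed = 1L) {
  q <- strsplit(alignment$query_seq, "")[[1L]]
  t <- strsplit(alignment$template_seq, "")[[1L]]
  if (gsub("-", "", alignment$query_seq) != input_seq)
    stop("alignment query does not match the input sequence")
  if (gsub("-", "", alignment$template_seq) != model_sequence(homolog))
    stop("alignment template does not match the homolog sequence")
  qi <- 0L; ti <- 0L
  n <- nchar(input_seq)
  map <- rep(NA_integer_, n)     # query residue -> template residue
  for (k in seq_along(q)) {
    if (q[k] != "-") qi <- qi + 1L
    if (t[k] != "-") ti <- ti + 1L
    if (q[k] != "-" && t[k] != "-") map[qi] <- ti
  }
  if (all(is.na(map))) stop("alignment has no aligned columns")

  aa <- strsplit(input_seq, "")[[1L]]
  hom_at <- residue_atoms(homolog)
  ra <- vector("list", n)
  for (i in which(!is.na(map))) {
    h <- hom_at[[map[i]]]
    al <- list(N = h$N, CA = h$CA, C = h$C,
               O = h$O %||% place_O(h$N, h$CA, h$C, NA))
    if (aa[i] != "G") al$CB <- place_CB(h$N, h$CA, h$C)
    ra[[i]] <- al
  }
  miss <- which(is.na(map))
  if (length(miss)) {
    segs <- split(miss, cumsum(c(1L, diff(miss) != 1L)))
    for (sg in segs) {
      lo0 <- min(sg); hi0 <- max(sg)
      ok <- FALSE
      for (widen in 0:4) {
      if (ok) break
      lo <- lo0; hi <- hi0
      # absorb flanking aligned residues: insertions between rigid anchors
      # are often unreachable for a minimal span, so widen progressively
      grow <- widen + max(0L, 3L - (hi0 - lo0 + 1L))
      for (g in seq_len(grow)) {
        if (lo > 1L && !is.null(ra[[lo - 1L]])) lo <- lo - 1L
        else if (hi < n && !is.null(ra[[hi + 1L]])) hi <- hi + 1L
      }
      while (hi - lo + 1L < 3L) {
        if (lo > 1L && !is.null(ra[[lo - 1L]])) lo <- lo - 1L
        else if (hi < n && !is.null(ra[[hi + 1L]])) hi <- hi + 1L
        else break
      }
      L <- hi - lo + 1L
      for (att in seq_len(config$tlc_attempts)) {
        draws <- with_seed(split_seed(seed, att + 100L * widen), list(
          phi = stats::runif(L, -140, -50), psi = stats::runif(L, -50, 160),
          join = stats::runif(2L, -180, 180)))
        tor <- data.frame(resi = seq_len(L), phi = draws$phi,
                          psi = draws$psi, omega = rep(180, L))
        join <- if (att == 1L) c(-60, -60) else draws$join
        if (lo == 1L || hi == n || is.null(ra[[lo - 1L]]) ||
            is.null(ra[[hi + 1L]])) {
          # terminal segment: free build off the nearest anchored residue
          bb <- if (lo > 1L && !is.null(ra[[lo - 1L]])) {
            anch <- ra[[lo - 1L]]
            tlc_build_forward(rbind(anch$N, anch$CA, anch$C), tor$phi,
                              tor$psi, tor$omega, psi0 = -60, omega0 = 180,
                              phi_end = 0)
          } else if (hi < n && !is.null(ra[[hi + 1L]])) {
            anch <- ra[[hi + 1L]]
            tlc_build_backward(rbind(anch$N, anch$CA, anch$C), tor$phi,
                               tor$psi, tor$omega, phi_end = -60,
                               stop_res = 1L)
          } else stop("alignment leaves no anchored residues")
          sol <- list(bb = lapply(bb, function(M) M[seq_len(L), , drop = FALSE]),
                      torsions = tor)
          ok <- TRUE
        } else {
          anchN <- ra[[lo - 1L]]; anchC <- ra[[hi + 1L]]
          piv <- unique(c(1L, (L + 1L) %/% 2L, L))
          if (length(piv) < 3L) piv <- c(1L, 2L, L)
          sols <- triaxial_loop_closure(
            tor, rbind(anchN$N, anchN$CA, anchN$C),
            rbind(anchC$N, anchC$CA, anchC$C), piv,
            psi0 = join[1L], omega0 = 180, phi_end = join[2L],
            n_scan = config$tlc_grid)
          if (length(sols)) { sol <- sols[[1L]]; ok <- TRUE }
        }
        if (ok) break
      }
      }
      if (!ok) stop("could not rebuild unaligned segment ", lo0, "-", hi0)
      for (k in seq_len(L)) {
        i <- lo + k - 1L
        al <- list(N = sol$bb$N[k, ], CA = sol$bb$CA[k, ], C = sol$bb$C[k, ],
                   O = place_O(sol$bb$N[k, ], sol$bb$CA[k, ], sol$bb$C[k, ],
                               sol$torsions$psi[k]))
        if (aa[i] != "G")
          al$CB <- place_CB(sol$bb$N[k, ], sol$bb$CA[k, ], sol$bb$C[k, ])
        ra[[i]] <- al
      }
    }
  }
  model_from_residue_atoms(aa, ra, provenance = "threaded")
}

#' Coverage of the query by an alignment
#' @param alignment An `alignment_pair`.
#' @return Fraction of query residues aligned to template residues.
#' @export
alignment_coverage <- function(alignment) {
  q <- strsplit(alignment$query_seq, "")[[1L]]
  t <- strsplit(alignment$template_seq, "")[[1L]]
  sum(q != "-" & t != "-") / sum(q != "-")
}

#' Filter threaded models by TM-score to the input structure
#'
#' Keeps models with TM-score strictly greater than the threshold
#' (the protocol considers only homologs with TM-score > 0.5).
#'
#' @param threaded List of `protein_model`s, same length as the input.
#' @param input_model The input `protein_model`.
#' @param threshold TM-score threshold (default 0.5, strict).
#' @return Filtered list.
#' @export
filter_homologs_by_tmscore <- function(threaded, input_model,
                                       threshold = 0.5) {
  keep <- vapply(threaded, function(m)
    tm_score(m, input_model) > threshold, logical(1))
  threaded[keep]
}

#' Light optimization of a threaded model
#'
#' Stand-in for running the full single-model refinement protocol on each
#' threaded structure: one side-chain repack plus a short restrained
#' minimization against restraints built from the threaded model itself.
#'
#' @param model A threaded `protein_model`.
#' @param config Configuration.
#' @param seed RNG seed.
#' @return The optimized `protein_model`.
#' @export
optimize_threaded <- function(model, config = default_config(), seed = 1L) {
  rs <- build_restraints(model, config = config)
  m <- repack_sidechains(model, config, seed = seed)
  relax(m, rs, relax_schedule(config$steps_short, "minimize"), config)
}

#' Harvest a patch library from optimized threaded models
#'
#' Sliding backbone windows entirely inside non-ULR spans: window lengths
#' from `window_bounds[1]` to `window_bounds[2]`, starts advancing by
#' `stride` within each span. Each patch stores its source id, query
#' residue range and backbone coordinates.
#'
#' @param optimized_threaded List of optimized threaded `protein_model`s.
#' @param ulrs List of `c(start, end)` ULR ranges to exclude.
#' @param window_bounds `c(min, max)` patch lengths (default c(5, 15)).
#' @param stride Start offset between consecutive windows (default: min
#'   window).
#' @param ids Optional source identifiers.
#' @return A `patch_library`; `patches` is a list of
#'   `list(source_id, range, bb)`.
#' @export
extract_patch_library <- function(optimized_threaded, ulrs,
                                  window_bounds = c(5L, 15L), stride = NULL,
                                  ids = NULL) {
  stride <- as.integer(stride %||% window_bounds[1L])
  patches <- list()
  for (mi in seq_along(optimized_threaded)) {
    m <- optimized_threaded[[mi]]
    id <- if (!is.null(ids)) ids[mi] else m$provenance
    n <- n_res(m)
    in_ulr <- rep(FALSE, n)
    for (u in ulrs) in_ulr[u[1L]:u[2L]] <- TRUE
    free <- which(!in_ulr)
    if (!length(free)) next
    spans <- split(free, cumsum(c(1L, diff(free) != 1L)))
    Nx <- bb_coords(m, "N"); CAx <- bb_coords(m, "CA"); Cx <- bb_coords(m, "C")
    tors <- backbone_torsions_raw(m)
    for (sp in spans) {
      lo <- min(sp); hi <- max(sp)
      for (w in window_bounds[1L]:window_bounds[2L]) {
        if (hi - lo + 1L < w) next
        for (s in seq(lo, hi - w + 1L, by = stride)) {
          e <- s + w - 1L
          rng <- s:e
          fl <- c(max(1L, s - 2L):(s - 1L), (e + 1L):min(n, e + 2L))
          fl <- unique(fl[fl >= 1L & fl <= n & (fl < s | fl > e)])
          flank <- do.call(rbind, lapply(fl, function(r)
            data.frame(resi = r, atom = c("N", "CA", "C"),
                       x = c(Nx[r, 1L], CAx[r, 1L], Cx[r, 1L]),
                       y = c(Nx[r, 2L], CAx[r, 2L], Cx[r, 2L]),
                       z = c(Nx[r, 3L], CAx[r, 3L], Cx[r, 3L]))))
          patches[[length(patches) + 1L]] <- list(
            source_id = paste0(id, "_", mi), range = c(s, e),
            bb = list(N = Nx[rng, , drop = FALSE],
                      CA = CAx[rng, , drop = FALSE],
                      C = Cx[rng, , drop = FALSE]),
            flank = flank,
            torsions = list(
              phi_s = if (is.na(tors$phi[s])) -60 else tors$phi[s],
              psi_e = if (is.na(tors$psi[e])) -60 else tors$psi[e]))
        }
      }
    }
  }
  structure(list(patches = patches, window_bounds = window_bounds,
                 stride = stride), class = "patch_library")
}

#' @export
print.patch_library <- function(x, ...) {
  cat(sprintf("<patch_library> %d patches, windows %d-%d, stride %d\n",
              length(x$patches), x$window_bounds[1L], x$window_bounds[2L],
              x$stride))
  invisible(x)
}
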