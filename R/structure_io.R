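# Core structural data model and single-chain PDB I/O.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA1 <- structure(names(AA3), names = unname(AA3))

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a protein model object
#'
#' A `protein_model` holds one protein chain: per-residue identity and an
#' atom table with coordinates in Angstrom. It is the object every other
#' module operates on.
#'
#' @param aa Character vector of one-letter amino-acid codes, one per residue.
#' @param resno Integer vector of author residue numbers (strictly
#'   increasing); defaults to `seq_along(aa)`.
#' @param atom_resi Integer vector mapping each atom to its residue
#'   (1-based position in `aa`).
#' @param atom_name Character vector of PDB atom names (`"N"`, `"CA"`, ...).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param chain_id Single chain identifier character.
#' @param provenance Label describing where the model came from
#'   (`"input"`, `"trial"`, `"threaded"`, `"final"`, ...).
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(aa, resno = seq_along(aa), atom_resi, atom_name,
                          xyz, chain_id = "A", provenance = "input") {
  stopifnot(length(aa) == length(resno),
            length(atom_resi) == length(atom_name),
            nrow(xyz) == length(atom_resi))
  m <- structure(list(
    chain_id = chain_id,
    aa = as.character(aa),
    resno = as.integer(resno),
    atom_resi = as.integer(atom_resi),
    atom_name = as.character(atom_name),
    xyz = unname(as.matrix(xyz)),
    provenance = provenance
  ), class = "protein_model")
  m
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> chain %s, %d residues, %d atoms [%s]\n",
              x$chain_id, n_res(x), nrow(x$xyz), x$provenance))
  cat(strwrap(model_sequence(x), width = 60), sep = "\n")
  invisible(x)
}

#' Number of residues in a model
#' @param model A `protein_model`.
#' @return Integer residue count.
#' @export
n_res <- function(model) length(model$aa)

#' One-letter sequence of a model
#' @param model A `protein_model`.
#' @return Single string.
#' @export
model_sequence <- function(model) paste(model$aa, collapse = "")

# Atom-row index of atom `name` for every residue (NA where absent).
atom_index <- function(model, name) {
  idx <- rep(NA_integer_, n_res(model))
  sel <- which(model$atom_name == name)
  idx[model$atom_resi[sel]] <- sel
  idx
}

#' Backbone coordinates of one atom type
#' @param model A `protein_model`.
#' @param name Atom name (default `"CA"`).
#' @return `n_res x 3` matrix (rows of NA where the atom is absent).
#' @export
bb_coords <- function(model, name = "CA") {
  idx <- atom_index(model, name)
  out <- matrix(NA_real_, n_res(model), 3L)
  ok <- !is.na(idx)
  out[ok, ] <- model$xyz[idx[ok], , drop = FALSE]
  out
}

# Build a model from a per-residue list of named atom coordinate lists.
model_from_residue_atoms <- function(aa, res_atoms, resno = seq_along(aa),
                                     chain_id = "A", provenance = "input") {
  atom_resi <- integer(0); atom_name <- character(0); xyz <- NULL
  for (i in seq_along(res_atoms)) {
    nm <- names(res_atoms[[i]])
    atom_resi <- c(atom_resi, rep(i, length(nm)))
    atom_name <- c(atom_name, nm)
    xyz <- rbind(xyz, do.call(rbind, res_atoms[[i]]))
  }
  protein_model(aa, resno, atom_resi, atom_name, xyz,
                chain_id = chain_id, provenance = provenance)
}

# Per-residue list of named coordinate lists (inverse of the above).
residue_atoms <- function(model) {
  out <- vector("list", n_res(model))
  for (i in seq_len(n_res(model))) {
    sel <- which(model$atom_resi == i)
    al <- lapply(sel, function(k) model$xyz[k, ])
    names(al) <- model$atom_name[sel]
    out[[i]] <- al
  }
  out
}

element_of <- function(atom_name) substr(sub("^[0-9]", "", atom_name), 1L, 1L)

#' Read a single-chain protein model from a PDB file
#'
#' Parses ATOM records (and MSE HETATM records, mapped to MET). Hydrogens
#' are skipped, alternate locations are resolved to the highest-occupancy
#' record, and only the first MODEL of a multi-model file is read. The file
#' must contain exactly one chain unless `chain` selects one.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier to select.
#' @return A `protein_model`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)
  keep <- rec == "ATOM  " | (rec == "HETATM" & substr(lines, 18L, 20L) == "MSE")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM records in ", path)

  f <- function(a, b) trimws(substr(lines, a, b))
  name <- f(13L, 16L)
  altloc <- substr(lines, 17L, 17L)
  resname <- f(18L, 20L)
  chain_col <- substr(lines, 22L, 22L)
  resseq <- as.integer(f(23L, 26L))
  x <- as.numeric(f(31L, 38L)); y <- as.numeric(f(39L, 46L)); z <- as.numeric(f(47L, 54L))
  occ <- suppressWarnings(as.numeric(f(55L, 60L))); occ[is.na(occ)] <- 1

  chains <- unique(chain_col)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("multiple chains (", paste(chains, collapse = ","),
           ") and no chain selector given")
    chain <- chains[1L]
  }
  sel <- chain_col == chain
  if (!any(sel)) stop("chain ", chain, " not found")

  resname[resname == "MSE"] <- "MET"
  elem <- element_of(name)
  sel <- sel & elem != "H" & !grepl("^[0-9]*H", name)
  name <- name[sel]; altloc <- altloc[sel]; resname <- resname[sel]
  resseq <- resseq[sel]; occ <- occ[sel]
  xyz <- cbind(x[sel], y[sel], z[sel])

  bad <- !(resname %in% names(AA3))
  if (any(bad))
    stop("non-standard residues not supported: ",
         paste(unique(resname[bad]), collapse = ","))

  # resolve altlocs: keep the highest-occupancy record per (residue, atom)
  key <- paste(resseq, name)
  ord <- order(resseq, -occ)
  first <- !duplicated(key[ord])
  take <- ord[first]
  take <- sort(take)
  name <- name[take]; resname <- resname[take]; resseq <- resseq[take]
  xyz <- xyz[take, , drop = FALSE]

  ures <- unique(resseq)
  resi <- match(resseq, ures)
  aa <- unname(AA3[resname[!duplicated(resseq)]])

  # backbone completeness (O optional only at the C-terminus is NOT allowed:
  # every residue must carry N, CA, C, O)
  missing <- character(0)
  for (i in seq_along(ures)) {
    have <- name[resi == i]
    lack <- setdiff(BACKBONE_ATOMS, have)
    if (length(lack))
      missing <- c(missing, sprintf("residue %d misses %s", ures[i],
                                    paste(lack, collapse = "/")))
  }
  if (length(missing))
    stop("incomplete backbone: ", paste(missing, collapse = "; "))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", path)

  protein_model(aa, ures, resi, name, xyz, chain_id = chain,
                provenance = "input")
}

#' Write a protein model to a PDB file
#'
#' Emits standard ATOM records (element column populated), a TER record and
#' END. Coordinates are written at PDB precision (1e-3 Angstrom), so
#' `read_pdb(write_pdb(m))` reproduces coordinates to that precision.
#'
#' @param model A `protein_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  n <- nrow(model$xyz)
  res3 <- AA1[model$aa[model$atom_resi]]
  nm <- model$atom_name
  nm_fmt <- ifelse(nchar(nm) >= 4L, nm, sprintf(" %-3s", nm))
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(n), nm_fmt, res3, model$chain_id,
                   model$resno[model$atom_resi],
                   model$xyz[, 1L], model$xyz[, 2L], model$xyz[, 3L],
                   1, 0, element_of(nm))
  last <- n_res(model)
  ter <- sprintf("TER   %5d      %3s %1s%4d", n + 1L, AA1[model$aa[last]],
                 model$chain_id, model$resno[last])
  writeLines(c(lines, ter, "END"), path)
  invisible(path)
}

#' Validate a model against the tool's input contract
#'
#' Checks the refinement-server style input rules: at most 300 residues, no
#' internal chain breaks (consecutive C-N distance below 2.0 Angstrom and no
#' residue-numbering gaps), complete finite backbone, strictly increasing
#' numbering.
#'
#' @param model A `protein_model`.
#' @return A `validation_report` list with fields `ok`, `n_residues`,
#'   `violations` (character vector of codes like `OVER_LENGTH`,
#'   `CHAIN_BREAK`).
#' @export
validate_input <- function(model) {
  v <- character(0)
  n <- n_res(model)
  if (n > 300L) v <- c(v, "OVER_LENGTH")
  if (any(diff(model$resno) <= 0L)) v <- c(v, "NON_INCREASING_NUMBERING")
  for (nm in BACKBONE_ATOMS)
    if (anyNA(atom_index(model, nm))) { v <- c(v, "MISSING_BACKBONE"); break }
  if (any(!is.finite(model$xyz))) v <- c(v, "NONFINITE_COORD")
  if (n > 1L && !("MISSING_BACKBONE" %in% v)) {
    Cx <- bb_coords(model, "C"); Nx <- bb_coords(model, "N")
    gap <- row_norm(Nx[-1L, , drop = FALSE] - Cx[-n, , drop = FALSE])
    if (any(gap > 2.0) || any(diff(model$resno) > 1L)) v <- c(v, "CHAIN_BREAK")
  }
  structure(list(ok = length(v) == 0L, n_residues = n, violations = v),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d residues: %s\n", x$n_residues,
              if (x$ok) "ok" else paste(x$violations, collapse = ", ")))
  invisible(x)
}

#' Write ranked final models as model_01.pdb, model_02.pdb, ...
#' @param models List of `protein_model` objects in rank order.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_final_models <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("model_%02d.pdb", seq_along(models)))
  for (i in seq_along(models)) write_pdb(models[[i]], paths[i])
  paths
}
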