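#' Coarse C-alpha/C-beta protein structures
#'
#' The analysis runs on a coarse-grained model of a protein (or quaternary
#' assembly) keeping only the C-alpha and C-beta coordinates of each residue.
#' A `coarse_structure` holds one residue table (one row per residue, with
#' C-alpha and, where present, C-beta coordinates in nm) and optionally the
#' full heavy-atom table needed for solvent-accessibility calculations.
#'
#' @param residues Data frame with columns `chain`, `resno`, `icode`,
#'   `amino_acid`, `ca_x`, `ca_y`, `ca_z`, `cb_x`, `cb_y`, `cb_z` (the
#'   `cb_*` entries `NA` for residues without a C-beta).  Coordinates in nm.
#' @param model_id Identifier for the model (e.g. PDB id plus assembly tag);
#'   must be unique within a cohort.
#' @param atoms Optional full heavy-atom data frame (columns `chain`,
#'   `resno`, `icode`, `amino_acid`, `atom_name`, `element`, `x`, `y`, `z`
#'   in nm) used by [sidechain_sasa()].
#'
#' @return An object of class `coarse_structure`.
#' @export
coarse_structure <- function(residues, model_id = "model", atoms = NULL) {
  need <- c("chain", "resno", "icode", "amino_acid",
            "ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z")
  miss <- setdiff(need, names(residues))
  if (length(miss) > 0)
    stop("residue table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(residues) == 0) stop("empty structure: no residues with a C-alpha atom")
  if (anyNA(residues[, c("ca_x", "ca_y", "ca_z")]))
    stop("all residues must have C-alpha coordinates")
  residues$residue_id <- residue_id_of(residues)
  if (anyDuplicated(residues$residue_id))
    stop("duplicate residue identifiers in structure")
  rownames(residues) <- NULL
  structure(list(model_id = model_id, residues = residues, atoms = atoms),
            class = "coarse_structure")
}

residue_id_of <- function(df) {
  icode <- ifelse(is.na(df$icode) | df$icode == " ", "", df$icode)
  paste0(df$chain, ":", df$resno, icode)
}

#' @export
print.coarse_structure <- function(x, ...) {
  ncb <- sum(!is.na(x$residues$cb_x))
  cat("Coarse C-alpha/C-beta structure '", x$model_id, "'\n", sep = "")
  cat("  residues: ", nrow(x$residues), " (", ncb, " with C-beta)\n", sep = "")
  cat("  point cloud size: ", nrow(x$residues) + ncb, "\n", sep = "")
  if (!is.null(x$atoms))
    cat("  heavy atoms: ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Point cloud of a coarse structure
#'
#' All C-alpha and C-beta coordinates of a structure, with back-links to the
#' owning residues.  Every residue contributes its C-alpha and, when present,
#' its C-beta.
#'
#' @param x A [coarse_structure()].
#' @return List with `coords` (matrix, nm), `residue` (row index into the
#'   residue table) and `type` (`"CA"` or `"CB"`).
#' @export
structure_points <- function(x) {
  stopifnot(inherits(x, "coarse_structure"))
  r <- x$residues
  has_cb <- !is.na(r$cb_x)
  coords <- rbind(as.matrix(r[, c("ca_x", "ca_y", "ca_z")]),
                  as.matrix(r[has_cb, c("cb_x", "cb_y", "cb_z")]))
  dimnames(coords) <- NULL
  list(coords = coords,
       residue = c(seq_len(nrow(r)), which(has_cb)),
       type = c(rep("CA", nrow(r)), rep("CB", sum(has_cb))))
}

#' Read a protein structure into the coarse model
#'
#' Parses a PDB coordinate file (via \pkg{bio3d}) and reduces it to the
#' C-alpha/C-beta representation.  Waters, hydrogens and heteroatoms are
#' excluded; selenomethionine and a few other common non-standard residues
#' are remapped to their parent amino acid (unmappable residues are dropped
#' with a warning).  Alternate locations are reduced to the
#' highest-occupancy conformer (ties: first in file order), and NMR-style
#' multi-model files are reduced to the first model unless
#' `model_policy = "all"`.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"first"` (default) returns the first model;
#'   `"all"` returns a list of `coarse_structure`, one per model.
#' @param model_id Identifier for the result; defaults to the file name
#'   without extension.
#' @param config A [protrusion_config()]; supplies the non-standard residue
#'   map.
#' @return A [coarse_structure()] (or a list of them for
#'   `model_policy = "all"`) with full heavy-atom coordinates attached.
#' @export
read_structure <- function(path, model_policy = c("first", "all"),
                           model_id = NULL, config = protrusion_config()) {
  model_policy <- match.arg(model_policy)
  config <- as_config(config)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  build <- function(m) {
    a <- at
    if (n_models > 1) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    }
    coarse_from_atoms(a, if (n_models > 1) paste0(model_id, "_m", m) else model_id,
                      config)
  }
  if (model_policy == "first") build(1L) else lapply(seq_len(n_models), build)
}

coarse_from_atoms <- function(a, model_id, config) {
  a$elesy <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                   substr(trimws(a$elety), 1, 1), a$elesy)))
  a <- a[a$elesy != "H" & !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # remap non-standard residues; keep only standard amino acids afterwards
  remap <- a$resid %in% names(config$nonstandard_map)
  a$resid[remap] <- unname(config$nonstandard_map[a$resid[remap]])
  keep <- a$resid %in% AA3 & (a$type == "ATOM" | remap)
  dropped <- unique(a$resid[a$type == "ATOM" & !(a$resid %in% AA3)])
  if (length(dropped) > 0)
    warning("excluded unmappable residue type(s): ",
            paste(dropped, collapse = ", "))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no C-alpha atoms in '", model_id, "'")
  a$icode <- ifelse(is.na(a$insert) | a$insert == "", " ", a$insert)
  a$alt <- ifelse(is.na(a$alt), "", a$alt)
  a$o[is.na(a$o)] <- 1

  # alternate locations: highest occupancy wins, ties to file order
  key <- paste(a$chain, a$resno, a$icode, trimws(a$elety), sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -a$o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]

  rkey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  rfirst <- !duplicated(rkey)
  res <- data.frame(chain = a$chain[rfirst], resno = a$resno[rfirst],
                    icode = a$icode[rfirst], amino_acid = a$resid[rfirst],
                    stringsAsFactors = FALSE)
  rk <- rkey[rfirst]
  elety <- trimws(a$elety)
  ca_idx <- match(rk, rkey[elety == "CA"])
  ca_rows <- which(elety == "CA")[ca_idx]
  cb_idx <- match(rk, rkey[elety == "CB"])
  cb_rows <- which(elety == "CB")[cb_idx]
  res$ca_x <- a$x[ca_rows] / 10; res$ca_y <- a$y[ca_rows] / 10
  res$ca_z <- a$z[ca_rows] / 10
  res$cb_x <- a$x[cb_rows] / 10; res$cb_y <- a$y[cb_rows] / 10
  res$cb_z <- a$z[cb_rows] / 10
  no_ca <- is.na(res$ca_x)
  if (any(no_ca)) {
    warning("dropped ", sum(no_ca), " residue(s) without a C-alpha atom")
    drop_keys <- rk[no_ca]
    res <- res[!no_ca, , drop = FALSE]
    a <- a[!(rkey %in% drop_keys), , drop = FALSE]
  }
  if (nrow(res) == 0) stop("empty structure: no C-alpha atoms in '", model_id, "'")
  atoms <- data.frame(chain = a$chain, resno = a$resno, icode = a$icode,
                      amino_acid = a$resid, atom_name = trimws(a$elety),
                      element = a$elesy,
                      x = a$x / 10, y = a$y / 10, z = a$z / 10,
                      stringsAsFactors = FALSE)
  coarse_structure(res, model_id = model_id, atoms = atoms)
}

#' Write a coarse structure as a minimal PDB file
#'
#' Emits ATOM records (CA and CB only, coordinates converted back to
#' Angstrom).  Mainly used to exercise the PDB reader end-to-end with
#' synthetic structures.
#'
#' @param x A [coarse_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coarse_pdb <- function(x, path) {
  stopifnot(inherits(x, "coarse_structure"))
  r <- x$residues
  lines <- character(0)
  serial <- 0L
  fmt <- function(serial, name, aa, chain, resno, icode, xx, yy, zz) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, "", aa, chain, resno, icode, xx, yy, zz, 1.0, 0.0)
  }
  for (i in seq_len(nrow(r))) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", r$amino_acid[i], r$chain[i],
                          r$resno[i], r$icode[i],
                          r$ca_x[i] * 10, r$ca_y[i] * 10, r$ca_z[i] * 10))
    if (!is.na(r$cb_x[i])) {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, "CB", r$amino_acid[i], r$chain[i],
                            r$resno[i], r$icode[i],
                            r$cb_x[i] * 10, r$cb_y[i] * 10, r$cb_z[i] * 10))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
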