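# -- quick builders for controlled geometric structures -----------------------

# coarse structure from coordinate matrices; cb rows may be NA (glycine-like)
make_coarse <- function(ca, cb = NULL, aa = "ALA", model_id = "toy",
                        chain = "A") {
  n <- nrow(ca)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3)
  aa <- rep(aa, length.out = n)
  coarse_structure(
    data.frame(chain = chain, resno = seq_len(n), icode = " ",
               amino_acid = aa,
               ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
               cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
               stringsAsFactors = FALSE),
    model_id = model_id)
}

# a vertex-residue target with a controllable local density: a distant
# 3-D scaffold of glycines, one target residue extreme in +x, and
# `n_neighbors` glycine C-alphas planted within 1 nm of the target C-beta.
make_density_probe <- function(n_neighbors, neighbor_dist = 0.5,
                               model_id = "probe") {
  scaffold <- rbind(c(-10, -10, -10), c(-10, 10, -10), c(-10, 0, 10),
                    c(-5, 0, 0))
  target_cb <- c(3, 0, 0)
  target_ca <- c(2.85, 0, 0)
  nb <- matrix(NA_real_, 0, 3)
  if (n_neighbors == 1) {
    # axis-aligned: the planted distance is exact in floating point, so the
    # inclusive boundary at exactly c is meaningful
    nb <- matrix(target_cb - c(neighbor_dist, 0, 0), 1)
  } else if (n_neighbors > 1) {
    ang <- seq(0, 2 * pi, length.out = n_neighbors + 1)[-1]
    u <- cbind(-1, 0.02 * cos(ang), 0.02 * sin(ang))
    u <- u / sqrt(rowSums(u^2))
    nb <- sweep(u * neighbor_dist, 2, target_cb, "+")
  }
  ca <- rbind(scaffold, target_ca, nb)
  cb <- rbind(matrix(NA_real_, nrow(scaffold), 3), target_cb,
              matrix(NA_real_, nrow(nb), 3))
  aa <- c(rep("GLY", nrow(scaffold)), "LEU", rep("GLY", nrow(nb)))
  make_coarse(ca, cb, aa, model_id = model_id)
}
TARGET_ROW <- 5L  # row of the target residue in make_density_probe()

# -- tiny PDB texts to exercise the parser ------------------------------------

pdb_atom_line <- function(serial, name, aa, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, aa, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Ala-Gly-Leu tripeptide-like coordinates (CA + CB where applicable)
tripeptide_pdb <- function() {
  write_test_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CA", "LEU", "A", 3, 7.6, 0, 0),
    pdb_atom_line(5, "CB", "LEU", "A", 3, 9.1, 1.0, 0)))
}

# -- direct cohort entries for the weighted-statistics micro-examples ---------

# builds an annotated entry without geometry: `flags` is a data frame with
# any of the selection columns; pair counts given directly.
make_entry <- function(model_id, flags, n_pairs = 0, n_one = 0, n_both = 0,
                       null_info = NULL) {
  n <- nrow(flags)
  defaults <- data.frame(
    chain = "A", residue_id = paste0("A:", seq_len(n)),
    amino_acid = "ALA", d = NA_integer_,
    co_insertable_hydrophobes = 0L, co_insertable_partners = 0L,
    is_vertex = FALSE, is_protrusion = FALSE, is_hydrophobe = FALSE,
    is_exposed = NA, ss_class = NA_character_, is_lih = FALSE,
    ca_x = 0, ca_y = 0, ca_z = 0,
    stringsAsFactors = FALSE)
  for (nm in names(flags)) defaults[[nm]] <- flags[[nm]]
  structure(list(model_id = model_id, residues = defaults,
                 lih = if (any(defaults$is_lih)) which(defaults$is_lih)[1]
                       else NA_integer_,
                 pair_counts = c(n_pairs = n_pairs, n_one = n_one,
                                 n_both = n_both),
                 null_info = null_info),
            class = "cohort_entry")
}

# entry with k residues of which the first n_s satisfy a marker selection
mark_entry <- function(model_id, k, n_s, col = "is_hydrophobe", ...) {
  flags <- data.frame(x = c(rep(TRUE, n_s), rep(FALSE, k - n_s)))
  names(flags) <- col
  make_entry(model_id, flags, ...)
}

S_HYD <- selection(hydrophobe = TRUE)
S_PROT <- selection(protrusion = TRUE)
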