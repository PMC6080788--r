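#' Side-chain solvent-accessible surface area
#'
#' Computes the solvent-accessible surface area of each residue's side
#' chain from the full heavy-atom coordinates, by numerical surface
#' integration: each atom is expanded by the probe radius (0.14 nm by
#' default) and sampled with a deterministic golden-section spiral point
#' set; a sample point is accessible when it lies outside every other
#' expanded atom sphere.  Van der Waals radii are Bondi's.  Side-chain
#' atoms are all heavy atoms except the backbone N, CA, C, O (and OXT);
#' C-beta counts as side chain, so glycine has area 0.
#'
#' @param x A [coarse_structure()] carrying an `atoms` table (as returned by
#'   [read_structure()]), or such an atom data frame directly.
#' @param config A [protrusion_config()].
#' @return Named numeric vector of side-chain areas (nm^2), one per residue
#'   id.  Residues whose heavy atoms are all missing are excluded with a
#'   warning.
#' @export
sidechain_sasa <- function(x, config = protrusion_config()) {
  config <- as_config(config)
  atoms <- if (inherits(x, "coarse_structure")) x$atoms else x
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("no heavy-atom coordinates available for SASA")
  rad <- config$vdw_radius_set
  el <- toupper(atoms$element)
  r_atom <- unname(rad[el])
  if (anyNA(r_atom)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r_atom)]), collapse = ", "),
            "; using the carbon radius")
    r_atom[is.na(r_atom)] <- rad[["C"]]
  }
  probe <- config$sasa_probe_radius
  rr <- r_atom + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  sph <- golden_spiral_points(config$sasa_n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rr[i]^2
      next
    }
    p <- sweep(sph * rr[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= rr[j]^2
    }
    area[i] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  backbone <- c("N", "CA", "C", "O", "OXT")
  is_side <- !(atoms$atom_name %in% backbone)
  rid <- residue_id_of(atoms)
  ids <- unique(rid)
  out <- vapply(ids, function(id) sum(area[is_side & rid == id]), numeric(1))
  names(out) <- ids
  out
}

# deterministic quasi-uniform unit-sphere point set (golden-section spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Exposure flag
#'
#' A residue is "exposed" when its side-chain solvent-accessible area is
#' strictly greater than the exposure threshold (0.2 nm^2 by default).
#'
#' @param sasa Numeric vector of side-chain areas (nm^2), e.g. from
#'   [sidechain_sasa()].
#' @param config A [protrusion_config()].
#' @return Logical vector (`NA` preserved).
#' @export
#' @examples
#' flag_exposed(c(0.21, 0.20, 0))
flag_exposed <- function(sasa, config = protrusion_config()) {
  config <- as_config(config)
  sasa > config$sasa_exposure_threshold
}
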