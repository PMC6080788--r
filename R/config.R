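#' Analysis configuration
#'
#' Collects the tunable parameters of the protrusion model.  All lengths are
#' in nanometres and all areas in nm^2; PDB coordinates (Angstrom) are
#' converted on input.
#'
#' @param density_radius Neighbourhood radius `c` used for the local protein
#'   density: the number of C-alpha/C-beta atoms within this distance of a
#'   residue's C-beta.  Default 1 nm.
#' @param density_threshold Density cutoff `n`: a vertex residue is a
#'   protrusion when its local density `d < n`.  Default 22.
#' @param sasa_probe_radius Solvent probe radius for side-chain accessibility.
#'   Default 0.14 nm.
#' @param sasa_exposure_threshold A residue is "exposed" when its side-chain
#'   solvent-accessible area strictly exceeds this value.  Default 0.2 nm^2.
#' @param sasa_n_points Number of quasi-uniform sphere points per atom used in
#'   the numerical surface integration.  Default 960.
#' @param vdw_radius_set Named vector of van der Waals radii (nm) per element,
#'   Bondi values by default.  Unknown elements fall back to the carbon radius
#'   with a warning.
#' @param hydrophobe_set Amino acids (3-letter codes) counted as hydrophobes:
#'   residues that partition favourably into the membrane interface on the
#'   Wimley-White scale.
#' @param fragment_min_distance Minimum distance (nm) outside the hydrocarbon
#'   slab for a residue to belong to a non-binding surface fragment.
#'   Default 1.5 nm.
#' @param hull_tolerance Points within this distance (nm) of a hull facet are
#'   treated as on-hull, not outside.  Default 1e-9.
#' @param facet_merge_tolerance Adjacent hull facets whose normals agree
#'   within this angle (radians) are treated as one coplanar polygon; their
#'   shared edge is not a hull edge.  Default 1e-6.
#' @param random_seed Integer seed controlling the residual tie-break of the
#'   Likely Inserted Hydrophobe and, combined with model ids, the permutation
#'   null streams.
#' @param nonstandard_map Named character vector remapping non-standard
#'   residue codes to their parent amino acid.
#'
#' @return An object of class `protrusion_config`.
#' @export
#' @examples
#' cfg <- protrusion_config()
#' cfg$density_threshold
protrusion_config <- function(density_radius = 1.0,
                              density_threshold = 22L,
                              sasa_probe_radius = 0.14,
                              sasa_exposure_threshold = 0.2,
                              sasa_n_points = 960L,
                              vdw_radius_set = bondi_radii(),
                              hydrophobe_set = c("LEU", "ILE", "PHE", "TYR",
                                                 "TRP", "CYS", "MET"),
                              fragment_min_distance = 1.5,
                              hull_tolerance = 1e-9,
                              facet_merge_tolerance = 1e-6,
                              random_seed = 1L,
                              nonstandard_map = c(MSE = "MET", SEC = "CYS",
                                                  HYP = "PRO", PYL = "LYS",
                                                  CSO = "CYS", PTR = "TYR",
                                                  SEP = "SER", TPO = "THR")) {
  stopifnot(density_radius > 0, sasa_probe_radius > 0,
            sasa_exposure_threshold > 0, fragment_min_distance > 0,
            hull_tolerance > 0, facet_merge_tolerance > 0,
            sasa_n_points >= 32)
  density_threshold <- as.integer(density_threshold)
  if (density_threshold < 1L) stop("density_threshold must be >= 1")
  bad <- setdiff(hydrophobe_set, AA3)
  if (length(bad) > 0)
    stop("unknown amino acid code(s) in hydrophobe_set: ",
         paste(bad, collapse = ", "))
  structure(list(density_radius = density_radius,
                 density_threshold = density_threshold,
                 sasa_probe_radius = sasa_probe_radius,
                 sasa_exposure_threshold = sasa_exposure_threshold,
                 sasa_n_points = as.integer(sasa_n_points),
                 vdw_radius_set = vdw_radius_set,
                 hydrophobe_set = hydrophobe_set,
                 fragment_min_distance = fragment_min_distance,
                 hull_tolerance = hull_tolerance,
                 facet_merge_tolerance = facet_merge_tolerance,
                 random_seed = as.integer(random_seed),
                 nonstandard_map = nonstandard_map),
            class = "protrusion_config")
}

#' Bondi van der Waals radii
#'
#' Van der Waals radii (nm) for the elements commonly found in protein heavy
#' atoms, after Bondi's compilation.
#'
#' @return Named numeric vector of radii in nm.
#' @export
bondi_radii <- function() {
  c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
    H = 0.120, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198,
    SE = 0.190)
}

# the 20 standard amino acids, 3-letter codes
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

as_config <- function(config) {
  if (inherits(config, "protrusion_config")) return(config)
  stop("`config` must be created with protrusion_config()")
}

#' Classify an amino acid as hydrophobic
#'
#' Hydrophobes are the residues that contribute favourably to membrane
#' interface partitioning on the Wimley-White interfacial scale: Leu, Ile,
#' Phe, Tyr, Trp, Cys and Met under the default configuration.
#'
#' @param amino_acid Character vector of 3-letter amino-acid codes.
#' @param config A [protrusion_config()].
#' @return Logical vector.  Non-standard codes are an error, never silently
#'   `FALSE`.
#' @export
#' @examples
#' classify_hydrophobe(c("LEU", "ARG", "GLY"))
classify_hydrophobe <- function(amino_acid, config = protrusion_config()) {
  config <- as_config(config)
  amino_acid <- toupper(amino_acid)
  bad <- setdiff(unique(amino_acid), AA3)
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  amino_acid %in% config$hydrophobe_set
}
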