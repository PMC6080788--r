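#' Membrane frame
#'
#' An OPM-style planar membrane model: a center point on the bilayer
#' midplane, a unit normal, and the hydrocarbon half-thickness `h` -- the
#' distance from the midplane to either of the planes where the hydrocarbon
#' volume fraction reaches one half.  The insertion coordinate of an atom is
#' `h - |z|`, where `z` is its signed distance from the midplane along the
#' normal: positive inside the hydrocarbon slab, zero on either boundary
#' plane, negative on the solvated side.
#'
#' @param center Numeric 3-vector (nm): a point on the bilayer midplane.
#' @param normal Numeric 3-vector: membrane normal (normalized internally).
#' @param half_thickness Hydrocarbon half-thickness `h` (nm), > 0.
#' @param side Which half-space (+1 or -1 along the normal) a peripheral
#'   protein occupies; informational.
#' @return An object of class `membrane_frame`.
#' @export
#' @examples
#' fr <- membrane_frame(half_thickness = 1.5)
#' insertion_coordinate(c(0, 0, 0), fr)    # slab center: +1.5
#' insertion_coordinate(c(0, 0, 1.5), fr)  # boundary plane: 0
membrane_frame <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                           half_thickness = 1.5, side = 1L) {
  stopifnot(length(center) == 3, length(normal) == 3, half_thickness > 0,
            side %in% c(-1L, 1L))
  nn <- sqrt(sum(normal^2))
  if (nn <= 0) stop("membrane normal must be non-zero")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / nn,
                 half_thickness = half_thickness, side = as.integer(side)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("Membrane frame: center (%.2f, %.2f, %.2f) nm, normal (%.2f, %.2f, %.2f), h = %.2f nm\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3], x$half_thickness))
  invisible(x)
}

#' Read a membrane frame from OPM-style DUM pseudo-atoms
#'
#' OPM-oriented PDB files mark the two hydrocarbon boundary planes with
#' planes of DUM pseudo-atoms.  The frame is reconstructed from the two
#' distinct z-levels of those atoms (OPM orients the membrane normal along
#' z).
#'
#' @param path PDB file containing DUM records.
#' @return A [membrane_frame()].
#' @export
read_membrane_frame <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dum <- lines[grepl("^(ATOM|HETATM)", lines) &
                 trimws(substr(lines, 18, 20)) == "DUM"]
  if (length(dum) == 0) stop("no DUM pseudo-atoms found in ", path)
  z <- as.numeric(substr(dum, 47, 54)) / 10
  lv <- sort(unique(round(z, 6)))
  if (length(lv) != 2)
    stop("expected two DUM planes, found ", length(lv), " z-level(s)")
  membrane_frame(center = c(0, 0, mean(lv)), normal = c(0, 0, 1),
                 half_thickness = diff(lv) / 2)
}

#' Insertion coordinate of atoms
#'
#' Signed depth of atoms relative to the membrane's hydrocarbon boundary
#' planes: `h - |z|` with `z` the along-normal coordinate relative to the
#' bilayer midplane.  Positive inside the hydrocarbon slab, zero on either
#' boundary plane, negative outside (both leaflets fold onto one axis).
#'
#' @param coords Numeric 3-vector or matrix with 3 columns (nm).
#' @param frame A [membrane_frame()].
#' @return Numeric vector of insertion coordinates (nm).
#' @export
insertion_coordinate <- function(coords, frame) {
  stopifnot(inherits(frame, "membrane_frame"))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  z <- as.matrix(sweep(coords, 2, frame$center)) %*% frame$normal
  as.numeric(frame$half_thickness - abs(z))
}

#' Extract a non-binding surface fragment
#'
#' Selects the residues of an annotated protein whose C-alpha atoms lie at
#' least `config$fragment_min_distance` (1.5 nm by default) outside the
#' hydrocarbon slab, i.e. with insertion coordinate `<= -1.5` nm (inclusive,
#' and on either side of a transmembrane complex).  Structural annotations
#' are those of the full complex -- only the statistical selection is
#' restricted.
#'
#' @param object A fitted [protrusion_model()] of the entire complex.
#' @param frame A [membrane_frame()].
#' @param config A [protrusion_config()].
#' @return The annotated residue rows of the fragment (possibly empty, with
#'   a warning).
#' @export
nonbinding_fragment <- function(object, frame, config = protrusion_config()) {
  stopifnot(inherits(object, "protrusion_model"))
  config <- as_config(config)
  r <- object$residues
  ic <- insertion_coordinate(as.matrix(r[, c("ca_x", "ca_y", "ca_z")]), frame)
  keep <- ic <= -config$fragment_min_distance
  if (!any(keep))
    warning("non-binding fragment of '", object$structure$model_id,
            "' is empty")
  out <- r[keep, , drop = FALSE]
  out$insertion_coordinate <- ic[keep]
  out
}

#' Family medians of the LIH insertion coordinate
#'
#' For each family of a cohort, the median insertion coordinate of the
#' Likely Inserted Hydrophobe's C-alpha over the member proteins, and the
#' fraction of families whose median lies within a margin of the membrane
#' (median `>= -margin`).  Proteins without an LIH are skipped and counted;
#' families with no LIH-bearing member are excluded.
#'
#' @param cohort A [cohort()] of fitted models.
#' @param frames A single [membrane_frame()] used for every protein, or a
#'   named list of frames keyed by model id.
#' @param margin Margin (nm) around the hydrocarbon boundary, default 0.5.
#' @return List with `families` (data frame: family, median insertion
#'   coordinate, members used), `fraction_within_margin`, and
#'   `n_skipped_no_lih`.
#' @export
median_family_insertion <- function(cohort, frames, margin = 0.5) {
  stopifnot(inherits(cohort, "protrusion_cohort"))
  get_frame <- function(id) {
    if (inherits(frames, "membrane_frame")) return(frames)
    fr <- frames[[id]]
    if (is.null(fr)) stop("no membrane frame for model '", id, "'")
    fr
  }
  skipped <- 0L
  fam <- lapply(cohort$families, function(members) {
    ic <- numeric(0)
    for (m in members) {
      e <- cohort$models[[m]]
      if (is.na(e$lih) || length(e$lih) == 0) { skipped <<- skipped + 1L; next }
      ca <- as.numeric(e$residues[e$lih, c("ca_x", "ca_y", "ca_z")])
      ic <- c(ic, insertion_coordinate(ca, get_frame(e$model_id)))
    }
    ic
  })
  used <- vapply(fam, length, integer(1)) > 0
  if (!all(used))
    message(sum(!used), " family(ies) without any LIH-bearing member excluded")
  med <- vapply(fam[used], stats::median, numeric(1))
  list(families = data.frame(family = names(cohort$families)[used],
                             median_insertion = unname(med),
                             n_members = vapply(fam[used], length, integer(1)),
                             row.names = NULL),
       fraction_within_margin = mean(med >= -margin),
       n_skipped_no_lih = skipped)
}
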