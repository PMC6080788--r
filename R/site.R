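#' Center-to-site vector
#'
#' The vector from the protein center (the unweighted mean C-alpha position
#' over all residues of the assembly) to the mean C-alpha position of a set
#' of residues.  Used to compare predicted and experimentally identified
#' membrane-binding sites.
#'
#' @param object A fitted [protrusion_model()] or a [coarse_structure()].
#' @param I Residue set: character residue ids (`"chain:resno[icode]"`) or
#'   integer row indices into the residue table.  Must be non-empty.
#' @param source Label for the vector origin (`"experimental"`,
#'   `"predicted"`, `"protrusion-control"`, ...).
#' @return Object of class `site_vector`: list with `t` (numeric 3-vector,
#'   nm), `residues` and `source`.
#' @export
site_vector <- function(object, I, source = "predicted") {
  r <- if (is.list(object) && is.data.frame(object$residues)) object$residues
       else stop("`object` must be a protrusion_model or coarse_structure")
  if (length(I) == 0) stop("residue set I is empty")
  idx <- resolve_residues(r, I)
  ca <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  t_vec <- colMeans(ca[idx, , drop = FALSE]) - colMeans(ca)
  structure(list(t = unname(t_vec), residues = r$residue_id[idx],
                 source = source), class = "site_vector")
}

resolve_residues <- function(r, I) {
  if (is.numeric(I)) {
    idx <- as.integer(I)
    if (any(idx < 1 | idx > nrow(r))) stop("residue index out of range")
    return(idx)
  }
  idx <- match(I, r$residue_id)
  if (anyNA(idx))
    stop("unmatched residue id(s): ", paste(I[is.na(idx)], collapse = ", "))
  idx
}

#' Angle between two site vectors
#'
#' @param v1,v2 [site_vector()]s or numeric 3-vectors.  Both must be
#'   non-zero.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' site_angle(c(1, 0, 0), c(0, 1, 0)) # 90
site_angle <- function(v1, v2) {
  a <- if (inherits(v1, "site_vector")) v1$t else as.numeric(v1)
  b <- if (inherits(v2, "site_vector")) v2$t else as.numeric(v2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined angle: zero-length site vector")
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Compare the predicted binding site with experimental residues
#'
#' Computes the angle between the center-to-site vectors of the
#' experimentally identified binding residues and of the Likely Inserted
#' Hydrophobe, plus control angles for every protruding residue taken
#' singly.  When the protein has no protruding hydrophobe the predicted
#' angle is reported as the 180-degree sentinel with `no_lih = TRUE`
#' (the plotting convention of marking such proteins at 180 degrees).
#'
#' @param object A fitted [protrusion_model()] (or an annotation entry with
#'   `residues` and `lih` components, e.g. rebuilt from an annotation CSV).
#' @param experimental Experimental binding residues: character ids, integer
#'   indices, or a data frame with columns `chain`, `resno` and optionally
#'   `icode` and `offset` (an author-vs-PDB numbering offset added to
#'   `resno`).
#' @param config A [protrusion_config()] (unused placeholder for future
#'   options).
#' @return List with `lih_angle` (degrees), `no_lih`, `control_angles`
#'   (named vector over protrusions), `t_experimental`, `t_lih`.
#' @export
evaluate_binding_site <- function(object, experimental,
                                  config = protrusion_config()) {
  stopifnot(is.list(object), is.data.frame(object$residues),
            !is.null(object$lih))
  r <- object$residues
  if (is.data.frame(experimental)) {
    off <- if ("offset" %in% names(experimental)) experimental$offset else 0L
    icode <- if ("icode" %in% names(experimental))
      ifelse(is.na(experimental$icode) | experimental$icode == " ", "",
             experimental$icode) else ""
    experimental <- paste0(experimental$chain, ":",
                           experimental$resno + off, icode)
  }
  t_e <- site_vector(object, experimental, source = "experimental")
  no_lih <- length(object$lih) == 0 || is.na(object$lih)
  if (no_lih) {
    t_p <- NULL
    lih_angle <- 180
  } else {
    t_p <- site_vector(object, object$lih, source = "predicted")
    lih_angle <- site_angle(t_e, t_p)
  }
  prot <- which(r$is_protrusion)
  control <- vapply(prot, function(i) {
    site_angle(t_e, site_vector(object, i, source = "protrusion-control"))
  }, numeric(1))
  names(control) <- r$residue_id[prot]
  list(lih_angle = lih_angle, no_lih = no_lih, control_angles = control,
       t_experimental = t_e, t_lih = t_p)
}
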