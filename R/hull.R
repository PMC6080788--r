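#' Convex hull of the C-alpha/C-beta point cloud
#'
#' Computes the 3-D convex hull over all C-alpha and C-beta points of a
#' coarse structure (or over the rows of a plain coordinate matrix).
#' Vertex residues are residues whose C-beta point is a vertex of this hull.
#' Facets that are coplanar within `config$facet_merge_tolerance` are merged
#' before edges are extracted, so the reported edges are edges of the hull
#' polygon rather than of a particular triangulation.
#'
#' @param x A [coarse_structure()] or a numeric matrix with 3 columns.
#' @param config A [protrusion_config()] (supplies the on-hull and facet
#'   merge tolerances).
#' @return An object of class `hull_model`: list with `vertices` (point
#'   indices), `edges` (two-column matrix of point indices), `facets`
#'   (triangles), and, when `x` is a structure, `vertex_residues` (residue
#'   row indices whose C-beta is a hull vertex) and the point cloud mapping.
#'   Degenerate clouds (fewer than 4 points, or collinear/coplanar) are an
#'   error naming the rank.
#' @export
compute_hull <- function(x, config = protrusion_config()) {
  config <- as_config(config)
  if (is.matrix(x)) {
    pts <- list(coords = x, residue = rep(NA_integer_, nrow(x)),
                type = rep(NA_character_, nrow(x)))
  } else {
    pts <- structure_points(x)
  }
  h <- cpp_convex_hull(pts$coords, eps = config$hull_tolerance,
                       merge_tol = config$facet_merge_tolerance)
  vertex_residues <- integer(0)
  if (!is.matrix(x)) {
    cb_vertex <- pts$type[h$vertices] == "CB"
    vertex_residues <- sort(unique(pts$residue[h$vertices[cb_vertex]]))
  }
  structure(list(vertices = h$vertices, edges = h$edges, facets = h$facets,
                 vertex_residues = vertex_residues, points = pts),
            class = "hull_model")
}

#' @export
print.hull_model <- function(x, ...) {
  cat("Convex hull: ", length(x$vertices), " vertex points, ",
      nrow(x$edges), " edges, ", nrow(x$facets), " facets\n", sep = "")
  invisible(x)
}

#' Local protein density
#'
#' The local protein density `d` of a residue is the number of C-alpha or
#' C-beta atoms within a distance `c` (`config$density_radius`) of its
#' C-beta atom.  The count is inclusive at the boundary and includes the
#' residue's own C-alpha and C-beta.  Residues without a C-beta (glycine,
#' or disordered side chains) have no defined density and get `NA`.
#'
#' @param x A [coarse_structure()].
#' @param config A [protrusion_config()].
#' @return Integer vector of densities, one per residue.
#' @export
local_density <- function(x, config = protrusion_config()) {
  stopifnot(inherits(x, "coarse_structure"))
  config <- as_config(config)
  pts <- structure_points(x)
  r <- x$residues
  has_cb <- !is.na(r$cb_x)
  d <- rep(NA_integer_, nrow(r))
  if (!any(has_cb)) return(d)
  cb <- as.matrix(r[has_cb, c("cb_x", "cb_y", "cb_z")])
  # squared distances from every C-beta to every cloud point
  cl <- pts$coords
  c2 <- config$density_radius^2
  cnt <- integer(nrow(cb))
  for (i in seq_len(nrow(cb))) {
    dx <- cl[, 1] - cb[i, 1]; dy <- cl[, 2] - cb[i, 2]; dz <- cl[, 3] - cb[i, 3]
    cnt[i] <- sum(dx * dx + dy * dy + dz * dz <= c2)
  }
  d[has_cb] <- cnt
  d
}
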