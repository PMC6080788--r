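#' Residue selections
#'
#' A selection is a conjunction of per-residue predicates evaluated on an
#' annotated residue table: hydropathy, vertex/protrusion/exposure flags,
#' secondary-structure class, amino-acid identity, and half-open local
#' density ranges `l < d <= u`.  Selections are the `s` and `r` arguments of
#' the weighted counting statistics.
#'
#' @param hydrophobe,vertex,protrusion,exposed,lih Logical or `NULL`;
#'   when non-`NULL` the corresponding flag must equal the given value.
#' @param ss Character vector of secondary-structure classes to accept.
#' @param aa Character vector of 3-letter amino-acid codes to accept.
#' @param density Numeric `c(l, u)`: require `l < d <= u`.
#' @param label Optional display label.
#' @return An object of class `residue_selection`.
#' @export
#' @examples
#' selection(hydrophobe = TRUE, protrusion = TRUE)
#' selection(vertex = TRUE, density = c(7, 12))
selection <- function(hydrophobe = NULL, vertex = NULL, protrusion = NULL,
                      exposed = NULL, lih = NULL, ss = NULL, aa = NULL,
                      density = NULL, label = NULL) {
  if (!is.null(density)) {
    stopifnot(length(density) == 2, density[1] < density[2])
  }
  crit <- list(hydrophobe = hydrophobe, vertex = vertex,
               protrusion = protrusion, exposed = exposed, lih = lih,
               ss = ss, aa = aa, density = density)
  crit <- crit[!vapply(crit, is.null, logical(1))]
  if (is.null(label)) {
    lab <- character(0)
    for (nm in names(crit)) {
      v <- crit[[nm]]
      lab <- c(lab, switch(nm,
        density = sprintf("%g<d<=%g", v[1], v[2]),
        ss = paste0("ss:", paste(v, collapse = "|")),
        aa = paste(v, collapse = "|"),
        if (isTRUE(v)) nm else paste0("!", nm)))
    }
    label <- if (length(lab) == 0) "all" else paste(lab, collapse = " & ")
  }
  structure(list(criteria = crit, label = label), class = "residue_selection")
}

#' @export
print.residue_selection <- function(x, ...) {
  cat("Residue selection:", x$label, "\n")
  invisible(x)
}

#' Evaluate a selection on an annotated residue table
#'
#' @param sel A [selection()] (or a function taking the residue data frame
#'   and returning a logical vector).
#' @param residues Annotated residue data frame (from [residue_table()]).
#' @return Logical vector, `NA`-free (`NA` annotations never satisfy a
#'   criterion).
#' @export
evaluate_selection <- function(sel, residues) {
  if (is.function(sel)) {
    out <- sel(residues)
    out[is.na(out)] <- FALSE
    return(out)
  }
  stopifnot(inherits(sel, "residue_selection"))
  mask <- rep(TRUE, nrow(residues))
  flag_col <- c(hydrophobe = "is_hydrophobe", vertex = "is_vertex",
                protrusion = "is_protrusion", exposed = "is_exposed",
                lih = "is_lih")
  for (nm in names(sel$criteria)) {
    v <- sel$criteria[[nm]]
    m <- switch(nm,
                ss = residues$ss_class %in% v,
                aa = residues$amino_acid %in% v,
                density = !is.na(residues$d) & residues$d > v[1] &
                  residues$d <= v[2],
                {
                  col <- residues[[flag_col[[nm]]]]
                  !is.na(col) & col == v
                })
    mask <- mask & m
  }
  mask[is.na(mask)] <- FALSE
  mask
}

# conjunction of two selections (s intersect r)
sel_and <- function(a, b) {
  if (is.function(a) || is.function(b)) {
    force(a); force(b)
    return(function(res) evaluate_selection(a, res) & evaluate_selection(b, res))
  }
  crit <- a$criteria
  for (nm in names(b$criteria)) {
    if (!is.null(crit[[nm]]) && !identical(crit[[nm]], b$criteria[[nm]])) {
      if (nm %in% c("ss", "aa")) {
        crit[[nm]] <- intersect(crit[[nm]], b$criteria[[nm]])
        next
      }
      if (nm == "density") {
        crit[[nm]] <- c(max(crit[[nm]][1], b$criteria[[nm]][1]),
                        min(crit[[nm]][2], b$criteria[[nm]][2]))
        next
      }
      stop("contradictory selection criteria for '", nm, "'")
    }
    crit[[nm]] <- b$criteria[[nm]]
  }
  out <- structure(list(criteria = crit,
                        label = paste(a$label, "&", b$label)),
                   class = "residue_selection")
  out
}
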