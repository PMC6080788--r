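#' Fit the protrusion model to a structure
#'
#' The central fitting function of the package.  Starting from a coarse
#' C-alpha/C-beta structure it computes, in order: the convex hull of the
#' point cloud; vertex residues (C-beta on the hull); local protein density
#' `d`; protrusions (vertex residues with `d < n`); co-insertable protrusion
#' pairs (protrusions whose C-beta points are joined by a hull edge); the
#' hydrophobe flags; per-residue counts of co-insertable hydrophobic
#' partners; and the Likely Inserted Hydrophobe (LIH) -- the protruding
#' hydrophobe with the most co-insertable protruding hydrophobes, ties
#' resolved by smallest `d`, remaining ties by a seeded random draw.
#' Optionally attaches DSSP secondary structure and side-chain solvent
#' accessibility.
#'
#' @param x A [coarse_structure()] (from [read_structure()] or a synthetic
#'   generator).
#' @param config A [protrusion_config()].
#' @param dssp Optional DSSP file path or data frame (see [attach_dssp()]).
#' @param sasa `"auto"` computes side-chain solvent accessibility when
#'   full-atom coordinates are available, `"never"` skips it.
#' @return An object of class `protrusion_model` with components
#'   `structure`, `config`, `residues` (annotated residue table), `hull`,
#'   `pairs` (co-insertable pair table) and `lih` (residue row index, or
#'   `NA` when the protein has no protruding hydrophobe).
#' @seealso [predict.protrusion_model()], [simulate.protrusion_model()],
#'   [plot.protrusion_model()], [protrusions()]
#' @export
#' @examples
#' fx <- make_spiky_protein(fixture_spec(n_spikes = 5, seed = 7))
#' fit <- protrusion_model(fx$model)
#' summary(fit)
protrusion_model <- function(x, config = protrusion_config(), dssp = NULL,
                             sasa = c("auto", "never")) {
  stopifnot(inherits(x, "coarse_structure"))
  config <- as_config(config)
  sasa <- match.arg(sasa)
  if (!is.null(dssp)) x <- attach_dssp(x, dssp)

  r <- x$residues
  r$is_hydrophobe <- classify_hydrophobe(r$amino_acid, config)
  if (is.null(r$ss_class)) r$ss_class <- NA_character_

  hull <- compute_hull(x, config)
  r$d <- local_density(x, config)
  r$is_vertex <- seq_len(nrow(r)) %in% hull$vertex_residues
  r$is_protrusion <- r$is_vertex & !is.na(r$d) & r$d < config$density_threshold

  pairs <- co_insertable_pairs_impl(r, hull)
  r$co_insertable_partners <- tabulate2(c(pairs$a, pairs$b), nrow(r))
  # count, for each residue, its co-insertable partners that are hydrophobes
  cih <- integer(nrow(r))
  if (nrow(pairs) > 0) {
    cih <- tabulate2(c(pairs$a[r$is_hydrophobe[pairs$b]],
                       pairs$b[r$is_hydrophobe[pairs$a]]), nrow(r))
  }
  r$co_insertable_hydrophobes <- cih

  lih <- select_lih(r, config, x$model_id)
  r$is_lih <- seq_len(nrow(r)) == ifelse(is.na(lih), 0L, lih)

  if (sasa == "auto" && !is.null(x$atoms)) {
    sa <- sidechain_sasa(x, config)
    r$sidechain_sasa <- unname(sa[r$residue_id])
    r$is_exposed <- flag_exposed(r$sidechain_sasa, config)
  } else {
    r$sidechain_sasa <- NA_real_
    r$is_exposed <- NA
  }

  structure(list(structure = x, config = config, residues = r, hull = hull,
                 pairs = pairs, lih = lih),
            class = "protrusion_model")
}

tabulate2 <- function(i, n) tabulate(i, nbins = n)

co_insertable_pairs_impl <- function(r, hull) {
  prot <- which(r$is_protrusion)
  out <- data.frame(a = integer(0), b = integer(0))
  if (length(prot) >= 2 && nrow(hull$edges) > 0) {
    pts <- hull$points
    # point index of each protrusion's C-beta
    cb_pt <- vapply(prot, function(i) {
      which(pts$residue == i & pts$type == "CB")[1]
    }, integer(1))
    owner <- rep(NA_integer_, nrow(pts$coords))
    owner[cb_pt] <- prot
    ea <- owner[hull$edges[, 1]]
    eb <- owner[hull$edges[, 2]]
    keep <- !is.na(ea) & !is.na(eb)
    if (any(keep)) {
      a <- pmin(ea[keep], eb[keep]); b <- pmax(ea[keep], eb[keep])
      out <- unique(data.frame(a = a, b = b))
      out <- out[order(out$a, out$b), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out$residue_a <- r$residue_id[out$a]
  out$residue_b <- r$residue_id[out$b]
  out$both_hydrophobe <- r$is_hydrophobe[out$a] & r$is_hydrophobe[out$b]
  out$one_hydrophobe <- r$is_hydrophobe[out$a] | r$is_hydrophobe[out$b]
  out
}

# deterministic 31-bit hash of a string, for per-protein RNG streams
string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_stream_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

select_lih <- function(r, config, model_id) {
  cand <- which(r$is_protrusion & r$is_hydrophobe)
  if (length(cand) == 0) return(NA_integer_)
  cnt <- r$co_insertable_hydrophobes[cand]
  cand <- cand[cnt == max(cnt)]
  if (length(cand) > 1) {
    dd <- r$d[cand]
    cand <- cand[dd == min(dd)]
  }
  if (length(cand) > 1) {
    seed <- (config$random_seed + string_hash(model_id)) %% 2147483647
    cand <- with_stream_seed(seed, cand[sample.int(length(cand), 1)])
  }
  cand
}

#' Annotated residues and derived selections
#'
#' Accessors for a fitted [protrusion_model()]: the full annotated residue
#' table, the protruding residues, the co-insertable pair table, and the
#' Likely Inserted Hydrophobe.
#'
#' @param object A `protrusion_model`.
#' @return `residue_table()`: the annotated residue data frame.
#'   `protrusions()`: its protruding rows.  `co_insertable_pairs()`: one row
#'   per unordered pair of protrusions joined by a hull edge, with
#'   `both_hydrophobe`/`one_hydrophobe` flags.
#'   `likely_inserted_hydrophobe()`: the LIH row, or `NULL` when the protein
#'   has no protruding hydrophobe.
#' @export
residue_table <- function(object) {
  stopifnot(inherits(object, "protrusion_model"))
  object$residues
}

#' @rdname residue_table
#' @export
protrusions <- function(object) {
  stopifnot(inherits(object, "protrusion_model"))
  object$residues[object$residues$is_protrusion, , drop = FALSE]
}

#' @rdname residue_table
#' @export
co_insertable_pairs <- function(object) {
  stopifnot(inherits(object, "protrusion_model"))
  object$pairs
}

#' @rdname residue_table
#' @export
likely_inserted_hydrophobe <- function(object) {
  stopifnot(inherits(object, "protrusion_model"))
  if (is.na(object$lih)) return(NULL)
  object$residues[object$lih, , drop = FALSE]
}

#' @export
print.protrusion_model <- function(x, ...) {
  r <- x$residues
  cat("Protrusion model of '", x$structure$model_id, "'\n", sep = "")
  cat(sprintf("  %d residues, %d vertex residues, %d protrusions, %d co-insertable pairs\n",
              nrow(r), sum(r$is_vertex), sum(r$is_protrusion), nrow(x$pairs)))
  if (is.na(x$lih)) {
    cat("  Likely Inserted Hydrophobe: none (no protruding hydrophobe)\n")
  } else {
    cat(sprintf("  Likely Inserted Hydrophobe: %s (%s), %d co-insertable hydrophobes, d = %d\n",
                r$residue_id[x$lih], r$amino_acid[x$lih],
                r$co_insertable_hydrophobes[x$lih], r$d[x$lih]))
  }
  invisible(x)
}

#' @export
summary.protrusion_model <- function(object, ...) {
  r <- object$residues
  out <- list(
    model_id = object$structure$model_id,
    n_residues = nrow(r),
    n_vertex = sum(r$is_vertex),
    n_protrusions = sum(r$is_protrusion),
    n_protruding_hydrophobes = sum(r$is_protrusion & r$is_hydrophobe),
    n_pairs = nrow(object$pairs),
    n_pairs_both = sum(object$pairs$both_hydrophobe),
    n_pairs_one = sum(object$pairs$one_hydrophobe),
    n_exposed = if (all(is.na(r$is_exposed))) NA_integer_
                else sum(r$is_exposed, na.rm = TRUE),
    lih = if (is.na(object$lih)) NA_character_ else r$residue_id[object$lih],
    density = summary(r$d[!is.na(r$d)]))
  class(out) <- "summary.protrusion_model"
  out
}

#' @export
print.summary.protrusion_model <- function(x, ...) {
  cat("Protrusion model summary --", x$model_id, "\n")
  cat(sprintf("  residues: %d   vertex residues: %d   protrusions: %d\n",
              x$n_residues, x$n_vertex, x$n_protrusions))
  cat(sprintf("  protruding hydrophobes: %d\n", x$n_protruding_hydrophobes))
  cat(sprintf("  co-insertable pairs: %d (>=1 hydrophobe: %d, both: %d)\n",
              x$n_pairs, x$n_pairs_one, x$n_pairs_both))
  if (!is.na(x$n_exposed))
    cat(sprintf("  exposed residues (side-chain SASA > threshold): %d\n",
                x$n_exposed))
  cat("  Likely Inserted Hydrophobe:",
      if (is.na(x$lih)) "none" else x$lih, "\n")
  cat("  local density d:\n")
  print(x$density)
  invisible(x)
}

#' Plot a fitted protrusion model
#'
#' Projects the C-alpha/C-beta point cloud onto its two principal axes and
#' marks vertex residues, protrusions and the Likely Inserted Hydrophobe.
#' Hull edges are drawn in the projection.
#'
#' @param x A `protrusion_model`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.protrusion_model <- function(x, ...) {
  pts <- x$hull$points
  ctr <- colMeans(pts$coords)
  pc <- stats::prcomp(pts$coords, center = TRUE, scale. = FALSE)
  xy <- pc$x[, 1:2]
  graphics::plot(xy, pch = 16, cex = 0.5, col = "grey60",
                 xlab = "PC1 (nm)", ylab = "PC2 (nm)",
                 main = paste("Protrusions:", x$structure$model_id), ...)
  e <- x$hull$edges
  graphics::segments(xy[e[, 1], 1], xy[e[, 1], 2],
                     xy[e[, 2], 1], xy[e[, 2], 2], col = "lightblue")
  r <- x$residues
  cbpts <- which(pts$type == "CB")
  prot_pts <- cbpts[r$is_protrusion[pts$residue[cbpts]]]
  graphics::points(xy[prot_pts, , drop = FALSE], pch = 1, cex = 1.4,
                   col = "grey20")
  hyd_pts <- cbpts[(r$is_protrusion & r$is_hydrophobe)[pts$residue[cbpts]]]
  graphics::points(xy[hyd_pts, , drop = FALSE], pch = 16, col = "darkorange")
  if (!is.na(x$lih)) {
    lp <- cbpts[pts$residue[cbpts] == x$lih]
    graphics::points(xy[lp, , drop = FALSE], pch = 8, cex = 2, col = "red")
  }
  invisible(x)
}

#' Predict the membrane-binding site of a fitted model
#'
#' Returns the Likely Inserted Hydrophobe together with its center-to-site
#' vector; given a membrane frame, also its C-alpha insertion coordinate;
#' given a set of experimentally identified binding residues, also the angle
#' between the predicted and experimental site vectors.
#'
#' @param object A `protrusion_model`.
#' @param membrane Optional [membrane_frame()].
#' @param experimental Optional character vector of residue ids (format
#'   `"chain:resno[icode]"`) of experimentally identified binding residues.
#' @param ... Unused.
#' @return List with `lih` (residue id or `NA`), `no_lih` flag, `t_predicted`
#'   (site vector), and optionally `insertion_coordinate` and `angle`
#'   (degrees; the 180-degree sentinel with `no_lih = TRUE` when the protein
#'   has no protruding hydrophobe).
#' @export
predict.protrusion_model <- function(object, membrane = NULL,
                                     experimental = NULL, ...) {
  r <- object$residues
  no_lih <- is.na(object$lih)
  out <- list(lih = if (no_lih) NA_character_ else r$residue_id[object$lih],
              no_lih = no_lih,
              t_predicted = if (no_lih) NULL
                            else site_vector(object, r$residue_id[object$lih]))
  if (!is.null(membrane) && !no_lih) {
    ca <- as.numeric(r[object$lih, c("ca_x", "ca_y", "ca_z")])
    out$insertion_coordinate <- insertion_coordinate(ca, membrane)
  }
  if (!is.null(experimental)) {
    ev <- evaluate_binding_site(object, experimental)
    out$angle <- ev$lih_angle
  }
  out
}

#' Permutation null for co-insertion
#'
#' Simulates the co-insertion null model of a fitted protein: hydrophobe
#' labels are randomly reassigned among the protein's protruding positions
#' (preserving the number of hydrophobic protrusions) and the co-insertable
#' pair counts are recomputed against the fixed hull adjacency.
#'
#' @param object A `protrusion_model`.
#' @param nsim Number of permutation samples.
#' @param seed Base seed; the draw stream is keyed by (seed, model id) so
#'   cohort-level simulation is order-independent.  Defaults to the seed in
#'   the model's configuration.
#' @param ... Unused.
#' @return Data frame with one row per sample: `n_pairs_both` and
#'   `n_pairs_one` under the permuted labels.
#' @export
simulate.protrusion_model <- function(object, nsim = 1, seed = NULL, ...) {
  r <- object$residues
  if (is.null(seed)) seed <- object$config$random_seed
  prot <- which(r$is_protrusion)
  m <- sum(r$is_hydrophobe[prot])
  k <- length(prot)
  pairs <- object$pairs
  if (k == 0)
    return(data.frame(n_pairs_both = rep(NA_integer_, nsim),
                      n_pairs_one = rep(NA_integer_, nsim)))
  ia <- match(pairs$a, prot)
  ib <- match(pairs$b, prot)
  stream <- (seed + string_hash(object$structure$model_id)) %% 2147483647
  with_stream_seed(stream, {
    both <- integer(nsim); one <- integer(nsim)
    for (s in seq_len(nsim)) {
      lab <- logical(k)
      if (m > 0) lab[sample.int(k, m)] <- TRUE
      if (nrow(pairs) > 0) {
        both[s] <- sum(lab[ia] & lab[ib])
        one[s] <- sum(lab[ia] | lab[ib])
      }
    }
    data.frame(n_pairs_both = both, n_pairs_one = one)
  })
}
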