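#' Annotate structures and serialize per-residue tables
#'
#' Runs the full protrusion analysis on one or more structures and returns
#' (optionally writes) a flat per-residue table.  Column names follow the
#' published per-residue output schema where they overlap (`"local
#' density"`, `"co insertables"`, `"sidechain sasa"`, `"LIH"`); additional
#' self-explanatory columns (total co-insertable partners, C-alpha
#' coordinates) make the table sufficient to rebuild every cohort statistic
#' without the structures.
#'
#' @param x Character vector of PDB paths, or a list of
#'   [coarse_structure()]/[protrusion_model()] objects.
#' @param out Optional CSV output path.
#' @param config A [protrusion_config()].
#' @param dssp Optional named list/vector of DSSP file paths keyed by model
#'   id (or a single path when annotating a single structure).
#' @param frames Optional [membrane_frame()] or named list of frames; adds
#'   an `insertion_coordinate` column (of the C-alpha).
#' @param keep_going With multiple input files, continue past files that
#'   fail to parse (collecting warnings) instead of stopping.
#' @return Data frame of annotation records, ordered by (pdb_id, chain,
#'   residue number); failed files, if any, in `attr(, "failures")`.
#' @export
annotate_structures <- function(x, out = NULL, config = protrusion_config(),
                                dssp = NULL, frames = NULL,
                                keep_going = FALSE) {
  config <- as_config(config)
  if (length(x) == 0) stop("no input structures given")
  if (is.character(x)) {
    paths <- x
    x <- list()
    failures <- character(0)
    for (p in paths) {
      s <- tryCatch(read_structure(p, config = config), error = function(e) e)
      if (inherits(s, "error")) {
        if (!keep_going) stop(s)
        warning("skipping '", p, "': ", conditionMessage(s))
        failures <- c(failures, p)
        next
      }
      x[[s$model_id]] <- s
    }
  } else {
    failures <- character(0)
    if (inherits(x, c("coarse_structure", "protrusion_model"))) x <- list(x)
  }
  if (length(x) == 0) stop("no structure could be parsed")
  recs <- lapply(x, function(s) {
    if (inherits(s, "protrusion_model")) {
      fit <- s
    } else {
      id <- s$model_id
      d <- if (!is.null(dssp)) {
        if (length(dssp) == 1 && is.null(names(dssp))) dssp else dssp[[id]]
      }
      fit <- protrusion_model(s, config, dssp = d)
    }
    r <- fit$residues
    message(sprintf("%s: %d residues, %d vertices, %d protrusions, %d pairs",
                    fit$structure$model_id, nrow(r), sum(r$is_vertex),
                    sum(r$is_protrusion), nrow(fit$pairs)))
    rec <- data.frame(pdb_id = fit$structure$model_id, chain_id = r$chain,
                      residue_id = trimws(paste0(r$resno,
                                                 ifelse(r$icode == " ", "",
                                                        r$icode))),
                      amino_acid = r$amino_acid,
                      check.names = FALSE, stringsAsFactors = FALSE)
    rec[["sidechain sasa"]] <- r$sidechain_sasa
    rec[["local density"]] <- r$d
    rec[["co insertables"]] <- r$co_insertable_hydrophobes
    rec[["co insertable partners"]] <- r$co_insertable_partners
    rec$is_vertex <- r$is_vertex
    rec$is_protrusion <- r$is_protrusion
    rec$is_hydrophobe <- r$is_hydrophobe
    rec$is_exposed <- r$is_exposed
    rec$ss_class <- r$ss_class
    rec$LIH <- r$is_lih
    rec$ca_x <- r$ca_x; rec$ca_y <- r$ca_y; rec$ca_z <- r$ca_z
    if (!is.null(frames)) {
      fr <- if (inherits(frames, "membrane_frame")) frames
            else frames[[fit$structure$model_id]]
      if (!is.null(fr))
        rec$insertion_coordinate <-
          insertion_coordinate(as.matrix(r[, c("ca_x", "ca_y", "ca_z")]), fr)
    }
    rec[order(rec$chain_id, r$resno, r$icode), , drop = FALSE]
  })
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$pdb_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "failures") <- failures
  if (!is.null(out))
    utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Rebuild a cohort from an annotation table
#'
#' Reconstructs the per-protein summaries needed by the weighted statistics
#' from a per-residue annotation table (as written by
#' [annotate_structures()]) plus a family label table.  Counts rebuilt this
#' way are bit-identical to those computed from the fitted models.  (The
#' permutation null model additionally needs hull adjacency and therefore
#' requires fitted models.)
#'
#' @param annotations Data frame or CSV path from [annotate_structures()].
#' @param labels Data frame with columns `pdb_id` and `family`.
#' @param name Cohort name.
#' @return A [cohort()].
#' @export
cohort_from_annotations <- function(annotations, labels, name = "cohort") {
  if (is.character(annotations))
    annotations <- utils::read.csv(annotations, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  if (!all(c("pdb_id", "family") %in% names(labels)))
    stop("label table must have columns 'pdb_id' and 'family'")
  ids <- unique(annotations$pdb_id)
  miss <- setdiff(ids, labels$pdb_id)
  if (length(miss) > 0)
    stop("no family label for: ", paste(miss, collapse = ", "))
  entries <- lapply(ids, function(id) {
    a <- annotations[annotations$pdb_id == id, , drop = FALSE]
    r <- data.frame(chain = a$chain_id, residue_id = paste0(a$chain_id, ":", a$residue_id),
                    amino_acid = a$amino_acid,
                    d = a[["local density"]],
                    co_insertable_hydrophobes = a[["co insertables"]],
                    co_insertable_partners = a[["co insertable partners"]],
                    is_vertex = a$is_vertex, is_protrusion = a$is_protrusion,
                    is_hydrophobe = a$is_hydrophobe, is_exposed = a$is_exposed,
                    ss_class = a$ss_class, is_lih = a$LIH,
                    sidechain_sasa = a[["sidechain sasa"]],
                    ca_x = a$ca_x, ca_y = a$ca_y, ca_z = a$ca_z,
                    check.names = FALSE, stringsAsFactors = FALSE)
    hp <- r$is_protrusion & r$is_hydrophobe
    n_both <- sum(r$co_insertable_hydrophobes[hp]) / 2
    n_one <- sum(r$co_insertable_partners[hp]) - n_both
    n_pairs <- sum(r$co_insertable_partners[r$is_protrusion]) / 2
    lih <- which(r$is_lih)
    structure(list(model_id = id, residues = r,
                   lih = if (length(lih) == 1) lih else NA_integer_,
                   pair_counts = c(n_pairs = n_pairs, n_one = n_one,
                                   n_both = n_both),
                   null_info = NULL),
              class = "cohort_entry")
  })
  fam <- labels$family[match(ids, labels$pdb_id)]
  cohort(entries, fam, name = name)
}

#' Compare two cohorts over a set of selections
#'
#' For each comparison (a property selection `s` against a reference
#' selection `r`), computes the weighted fraction in both cohorts and their
#' log odds ratio; also reports the co-insertable pair statistics of both
#' cohorts and their contrast.
#'
#' @param cohort_a,cohort_b [cohort()]s; positive log odds ratios mean the
#'   property is more frequent in `cohort_a`.
#' @param comparisons Named list of `list(s = , r = )` selection pairs.
#' @param out Optional CSV output path.
#' @return Data frame with one row per comparison and cohort contrast:
#'   estimates, 95\% CI bounds and the weighted counts used.
#' @export
compare_cohorts <- function(cohort_a, cohort_b,
                            comparisons = list(
                              `hydrophobe|protrusion` = list(
                                s = selection(hydrophobe = TRUE),
                                r = selection(protrusion = TRUE))),
                            out = NULL) {
  row_of <- function(label, fa, fb) {
    lr <- odds_ratio(fa, fb)
    data.frame(comparison = label,
               f_a = fa$estimate, f_a_lower = fa$lower, f_a_upper = fa$upper,
               f_b = fb$estimate, f_b_lower = fb$lower, f_b_upper = fb$upper,
               successes_a = fa$successes, failures_a = fa$failures,
               successes_b = fb$successes, failures_b = fb$failures,
               ln_odds = lr$estimate, ln_odds_lower = lr$lower,
               ln_odds_upper = lr$upper, undefined = lr$infinite,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    fa <- weighted_fraction(cohort_a, cmp$s, cmp$r)
    fb <- weighted_fraction(cohort_b, cmp$s, cmp$r)
    rows[[nm]] <- row_of(nm, fa, fb)
  }
  pa <- pair_counts(cohort_a)
  pb <- pair_counts(cohort_b)
  if (!pa$undefined && !pb$undefined)
    rows[["pair both|one"]] <- row_of("pair both|one", pa$f_pair_both_one,
                                      pb$f_pair_both_one)
  rows[["proteins with co-insertable hydrophobes"]] <-
    row_of("proteins with co-insertable hydrophobes", pa$e_pair_both,
           pb$e_pair_both)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Evaluate predicted binding sites against experimental residues
#'
#' For each protein with experimentally identified binding residues,
#' computes the angle between the experimental and predicted (LIH) site
#' vectors, plus summary statistics of the per-protrusion control angles.
#' Proteins without a protruding hydrophobe are reported at the 180-degree
#' sentinel with the `no_lih` flag set.
#'
#' @param x List of fitted [protrusion_model()]s (named by model id), or an
#'   annotation table / CSV path from [annotate_structures()].
#' @param sites Data frame with columns `pdb_id`, `chain`, `resno`, and
#'   optionally `icode` and `offset`.
#' @param out Optional CSV output path.
#' @return Data frame with one row per protein: `pdb_id`, `lih`,
#'   `lih_angle`, `no_lih`, `n_controls`, `median_control_angle`.
#' @export
evaluate_sites <- function(x, sites, out = NULL) {
  need <- c("pdb_id", "chain", "resno")
  if (!all(need %in% names(sites)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (is.character(x) || is.data.frame(x)) {
    if (is.character(x))
      x <- utils::read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- data.frame(pdb_id = unique(x$pdb_id),
                         family = unique(x$pdb_id))
    ch <- cohort_from_annotations(x, labels)
    x <- ch$models
  }
  ids <- unique(sites$pdb_id)
  rows <- lapply(ids, function(id) {
    fit <- x[[id]]
    if (is.null(fit)) stop("no annotated structure for '", id, "'")
    st <- sites[sites$pdb_id == id, , drop = FALSE]
    ev <- evaluate_binding_site(fit, st)
    r <- fit$residues
    lih_id <- if (ev$no_lih) NA_character_ else r$residue_id[fit$lih]
    data.frame(pdb_id = id, lih = lih_id, lih_angle = ev$lih_angle,
               no_lih = ev$no_lih, n_controls = length(ev$control_angles),
               median_control_angle =
                 if (length(ev$control_angles) > 0)
                   stats::median(ev$control_angles) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
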