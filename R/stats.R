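#' Cohorts of fitted proteins grouped into families
#'
#' A cohort is a set of fitted proteins partitioned into families; all
#' weighted statistics give each family equal weight regardless of its
#' number of member structures.
#'
#' @param models List of fitted [protrusion_model()] objects (or annotation
#'   entries built by [cohort_from_annotations()]).
#' @param families Character vector of family labels, one per model.
#' @param name Optional cohort name.
#' @return An object of class `protrusion_cohort`.
#' @export
cohort <- function(models, families, name = "cohort") {
  stopifnot(length(models) == length(families))
  entries <- lapply(models, as_cohort_entry)
  ids <- vapply(entries, function(e) e$model_id, character(1))
  if (anyDuplicated(ids)) stop("model ids must be unique within a cohort")
  names(entries) <- ids
  structure(list(name = name, models = entries,
                 families = split(ids, factor(families, levels = unique(families)))),
            class = "protrusion_cohort")
}

as_cohort_entry <- function(m) {
  if (inherits(m, "cohort_entry")) return(m)
  stopifnot(inherits(m, "protrusion_model"))
  prot <- which(m$residues$is_protrusion)
  structure(list(model_id = m$structure$model_id,
                 residues = m$residues,
                 lih = m$lih,
                 pair_counts = c(n_pairs = nrow(m$pairs),
                                 n_one = sum(m$pairs$one_hydrophobe),
                                 n_both = sum(m$pairs$both_hydrophobe)),
                 null_info = list(k = length(prot),
                                  m = sum(m$residues$is_hydrophobe[prot]),
                                  ia = match(m$pairs$a, prot),
                                  ib = match(m$pairs$b, prot))),
            class = "cohort_entry")
}

#' @export
print.protrusion_cohort <- function(x, ...) {
  cat("Cohort '", x$name, "': ", length(x$models), " proteins in ",
      length(x$families), " families\n", sep = "")
  invisible(x)
}

#' Weighted statistic results
#'
#' Container for the family-weighted estimates: a point estimate with a
#' 95\% Wald confidence interval and the real-valued success/failure counts
#' that back it.
#'
#' @param estimate Point estimate.
#' @param successes,failures Real-valued analogs of binomial successes and
#'   failures.
#' @param trials Real-valued trial count used for the normal approximation.
#' @param estimator Name of the estimator.
#' @param infinite Flag set when the estimate is not finite (a fraction of
#'   exactly 0 or 1 entering a log odds ratio).
#' @return Object of class `stat_result` with elements `estimate`, `lower`,
#'   `upper`, `successes`, `failures`, `estimator`, `infinite`.
#' @export
stat_result <- function(estimate, successes, failures, trials = successes + failures,
                        estimator = "fraction", infinite = FALSE) {
  z <- stats::qnorm(0.975)
  if (estimator %in% c("fraction", "protein_fraction") && is.finite(estimate)) {
    se <- sqrt(estimate * (1 - estimate) / trials)
    lower <- estimate - z * se
    upper <- estimate + z * se
  } else {
    lower <- NA_real_
    upper <- NA_real_
  }
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 successes = successes, failures = failures, trials = trials,
                 estimator = estimator, infinite = infinite),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  ci <- if (is.na(x$lower)) "" else sprintf(" [%.4f, %.4f]", x$lower, x$upper)
  cat(sprintf("%s: %.4f%s  (successes %.3f, failures %.3f)\n",
              x$estimator, x$estimate, ci, x$successes, x$failures))
  invisible(x)
}

cohort_entries <- function(x) {
  stopifnot(inherits(x, "protrusion_cohort"))
  x$models
}

# |G_s| per protein of a family
count_in <- function(entry, sel) sum(evaluate_selection(sel, entry$residues))

#' Mean fraction of residues with a property within a family
#'
#' The per-family mean, over member proteins, of the fraction of residues
#' satisfying `s` among those satisfying the reference selection `r`.
#' Proteins with no `r`-residues are skipped and the mean renormalized over
#' the remaining members (with a message); it is an error if every member
#' is empty.
#'
#' @param x A list of fitted models (one family) or a [cohort()].
#' @param s,r [selection()]s (or predicate functions).
#' @param family When `x` is a cohort, the family name to evaluate.
#' @return The mean fraction (scalar).
#' @export
mean_fraction <- function(x, s, r, family = NULL) {
  if (inherits(x, "protrusion_cohort")) {
    if (is.null(family)) stop("give `family` when passing a cohort")
    entries <- x$models[x$families[[family]]]
  } else {
    entries <- lapply(x, as_cohort_entry)
  }
  sr <- sel_and(s, r)
  ratios <- vapply(entries, function(e) {
    nr <- count_in(e, r)
    if (nr == 0) return(NA_real_)
    count_in(e, sr) / nr
  }, numeric(1))
  if (all(is.na(ratios)))
    stop("undefined mean fraction: no member protein has any reference residue")
  if (anyNA(ratios))
    message(sum(is.na(ratios)),
            " protein(s) with empty reference selection skipped")
  mean(ratios, na.rm = TRUE)
}

#' Family-weighted counts and fractions
#'
#' The family-weighted count of residues with property `s`
#' (`weighted_count`), the weighted count of proteins having at least one
#' such residue (`weighted_protein_count`), the weighted fraction of
#' `s`-residues among `r`-residues (`weighted_fraction`), and the weighted
#' fraction of families whose proteins carry at least one `s`-residue
#' (`protein_fraction`).  Each family contributes the mean over its member
#' proteins, so duplicating structures within a family does not change any
#' estimate.  Fractions carry 95\% Wald confidence intervals with the
#' real-valued weighted counts serving as the binomial trial counts.
#'
#' @param cohort A [cohort()].
#' @param s,r [selection()]s.
#' @return `weighted_count`/`weighted_protein_count` return a scalar;
#'   `weighted_fraction`/`protein_fraction` a [stat_result()].
#' @export
weighted_count <- function(cohort, s) {
  sum(vapply(cohort$families, function(members) {
    mean(vapply(cohort$models[members], count_in, numeric(1), sel = s))
  }, numeric(1)))
}

#' @rdname weighted_count
#' @export
weighted_protein_count <- function(cohort, s) {
  sum(vapply(cohort$families, function(members) {
    mean(vapply(cohort$models[members], function(e) count_in(e, s) > 0,
                logical(1)))
  }, numeric(1)))
}

#' @rdname weighted_count
#' @export
weighted_fraction <- function(cohort, s, r) {
  n_sr <- weighted_count(cohort, sel_and(s, r))
  n_r <- weighted_count(cohort, r)
  if (n_r <= 0) stop("undefined weighted fraction: reference count is zero")
  stat_result(n_sr / n_r, successes = n_sr, failures = n_r - n_sr,
              trials = n_r, estimator = "fraction")
}

#' @rdname weighted_count
#' @export
protein_fraction <- function(cohort, s) {
  m_s <- weighted_protein_count(cohort, s)
  nd <- length(cohort$families)
  if (nd == 0) stop("empty cohort")
  stat_result(m_s / nd, successes = m_s, failures = nd - m_s, trials = nd,
              estimator = "protein_fraction")
}

#' Family-weighted co-insertable pair statistics
#'
#' Weighted counts over co-insertable protrusion pairs: pairs with at least
#' one protruding hydrophobe, pairs where both members are protruding
#' hydrophobes, the weighted count and fraction of proteins with at least
#' one both-hydrophobe pair, and the weighted co-insertion frequency -- the
#' conditional probability that both residues of a co-insertable pair are
#' protruding hydrophobes given that one is.
#'
#' @param cohort A [cohort()].
#' @return List with `n_pair_one`, `n_pair_both`, `m_pair_both` (scalars),
#'   `e_pair_both` and `f_pair_both_one` ([stat_result()]s;
#'   `f_pair_both_one` is `NULL` with `undefined = TRUE` when no pair has a
#'   hydrophobe).
#' @export
pair_counts <- function(cohort) {
  fam_mean <- function(f) {
    vapply(cohort$families, function(members) {
      mean(vapply(cohort$models[members], f, numeric(1)))
    }, numeric(1))
  }
  n_one <- sum(fam_mean(function(e) e$pair_counts[["n_one"]]))
  n_both <- sum(fam_mean(function(e) e$pair_counts[["n_both"]]))
  m_both <- sum(fam_mean(function(e) e$pair_counts[["n_both"]] > 0))
  nd <- length(cohort$families)
  e_both <- stat_result(m_both / nd, successes = m_both,
                        failures = nd - m_both, trials = nd,
                        estimator = "protein_fraction")
  if (n_one > 0) {
    f_both <- stat_result(n_both / n_one, successes = n_both,
                          failures = n_one - n_both, trials = n_one,
                          estimator = "fraction")
    undefined <- FALSE
  } else {
    f_both <- NULL
    undefined <- TRUE
  }
  list(n_pair_one = n_one, n_pair_both = n_both, m_pair_both = m_both,
       e_pair_both = e_both, f_pair_both_one = f_both, undefined = undefined)
}

#' Log odds ratio between two weighted fractions
#'
#' Compares a weighted fraction between two data sets A and B as
#' `ln R = ln[F_A (1 - F_B)] - ln[F_B (1 - F_A)]`, positive when the
#' property is more frequent in A.  The 95\% Wald interval uses the
#' real-valued success and failure counts carried by the two estimates.
#' Swapping A and B negates the estimate exactly.  A fraction of exactly 0
#' or 1 gives an infinite estimate, flagged rather than clipped.
#'
#' @param stat_a,stat_b [stat_result()] fractions for the two data sets.
#' @return A [stat_result()] with estimator `"ln_odds_ratio"`.
#' @export
odds_ratio <- function(stat_a, stat_b) {
  stopifnot(inherits(stat_a, "stat_result"), inherits(stat_b, "stat_result"))
  pa <- stat_a$estimate; pb <- stat_b$estimate
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    est <- log(pa / (1 - pa)) - log(pb / (1 - pb)) # +-Inf (or NaN for 0/0)
    out <- stat_result(est, successes = NA_real_, failures = NA_real_,
                       trials = NA_real_, estimator = "ln_odds_ratio",
                       infinite = TRUE)
    return(out)
  }
  est <- log(pa * (1 - pb)) - log(pb * (1 - pa))
  se <- sqrt(1 / stat_a$successes + 1 / stat_a$failures +
               1 / stat_b$successes + 1 / stat_b$failures)
  z <- stats::qnorm(0.975)
  out <- stat_result(est, successes = stat_a$successes,
                     failures = stat_a$failures, trials = stat_a$trials,
                     estimator = "ln_odds_ratio")
  out$lower <- est - z * se
  out$upper <- est + z * se
  out$se <- se
  out
}

#' Co-insertion permutation null for a cohort
#'
#' Estimates the null distribution of the weighted co-insertion frequency by
#' randomly reassigning each protein's hydrophobes among its protruding
#' positions (preserving their number) and recomputing the pair counts
#' against the fixed hull adjacency.  The observed frequency is compared to
#' the null via the log odds ratio, with the mean null counts serving as the
#' null data set's real-valued successes and failures.
#'
#' @param cohort A [cohort()] built from fully fitted models.
#' @param n_samples Number of permutation samples per protein.
#' @param seed Base seed; per-protein streams are keyed by
#'   `(seed, model_id)` so results do not depend on evaluation order.
#' @return List with `observed` (pair statistics, see [pair_counts()]),
#'   `null_n_both`, `null_n_one` (mean weighted null counts), `f_null`
#'   ([stat_result()]), `f_null_samples` (per-sample weighted null
#'   frequency), `ln_odds` ([stat_result()]), and `n_skipped` (proteins
#'   without protrusions, skipped).
#' @export
co_insertion_null <- function(cohort, n_samples = 1000, seed = NULL) {
  stopifnot(inherits(cohort, "protrusion_cohort"))
  if (is.null(seed)) seed <- 1L
  skipped <- 0L
  # per-protein null pair counts: n_samples x 2
  draws <- lapply(cohort$models, function(e) {
    ni <- e$null_info
    if (is.null(ni))
      stop("cohort entry '", e$model_id,
           "' has no hull adjacency; the null model needs fully fitted models")
    if (ni$k == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    stream <- (seed + string_hash(e$model_id)) %% 2147483647
    with_stream_seed(stream, {
      both <- integer(n_samples); one <- integer(n_samples)
      npair <- length(ni$ia)
      for (s in seq_len(n_samples)) {
        lab <- logical(ni$k)
        if (ni$m > 0) lab[sample.int(ni$k, ni$m)] <- TRUE
        if (npair > 0) {
          both[s] <- sum(lab[ni$ia] & lab[ni$ib])
          one[s] <- sum(lab[ni$ia] | lab[ni$ib])
        }
      }
      cbind(both, one)
    })
  })
  if (skipped > 0)
    message(skipped, " protein(s) without protrusions skipped in the null model")
  # family-weighted null counts per sample
  nb <- matrix(0, nrow = n_samples, ncol = length(cohort$families))
  no <- matrix(0, nrow = n_samples, ncol = length(cohort$families))
  for (fi in seq_along(cohort$families)) {
    members <- cohort$families[[fi]]
    used <- 0L
    for (m in members) {
      d <- draws[[m]]
      if (is.null(d)) next
      nb[, fi] <- nb[, fi] + d[, 1]
      no[, fi] <- no[, fi] + d[, 2]
      used <- used + 1L
    }
    w <- if (length(members) > 0) length(members) else 1L
    nb[, fi] <- nb[, fi] / w
    no[, fi] <- no[, fi] / w
  }
  null_both <- rowSums(nb)
  null_one <- rowSums(no)
  f_samples <- ifelse(null_one > 0, null_both / null_one, NA_real_)
  nb_mean <- mean(null_both)
  no_mean <- mean(null_one)
  observed <- pair_counts(cohort)
  f_null <- if (no_mean > 0)
    stat_result(nb_mean / no_mean, successes = nb_mean,
                failures = no_mean - nb_mean, trials = no_mean,
                estimator = "fraction") else NULL
  ln_odds <- if (!observed$undefined && !is.null(f_null))
    odds_ratio(observed$f_pair_both_one, f_null) else NULL
  list(observed = observed, null_n_both = nb_mean, null_n_one = no_mean,
       f_null = f_null, f_null_samples = f_samples, ln_odds = ln_odds,
       n_skipped = skipped)
}

#' Hydrophobe enrichment on vertex residues by density range
#'
#' For each half-open density range `(l, u]`, compares the weighted
#' fraction of hydrophobes among vertex residues with `l < d <= u` between
#' two cohorts via the log odds ratio.
#'
#' @param cohort_a,cohort_b [cohort()]s (A is the numerator set: positive
#'   values mean hydrophobes are more frequent in A).
#' @param ranges List of `c(l, u)` pairs, or a numeric vector of breaks.
#' @return Data frame with one row per range: bounds, the two fractions,
#'   `ln_odds`, CI bounds and an `undefined` flag for degenerate ranges.
#' @export
density_range_comparison <- function(cohort_a, cohort_b,
                                     ranges = c(0, 6, 11, 16, 21, 26, 31)) {
  if (is.numeric(ranges))
    ranges <- Map(c, ranges[-length(ranges)], ranges[-1])
  s <- selection(hydrophobe = TRUE)
  rows <- lapply(ranges, function(lu) {
    r <- selection(vertex = TRUE, density = lu)
    fa <- tryCatch(weighted_fraction(cohort_a, s, r), error = function(e) NULL)
    fb <- tryCatch(weighted_fraction(cohort_b, s, r), error = function(e) NULL)
    if (is.null(fa) || is.null(fb)) {
      return(data.frame(lower_d = lu[1], upper_d = lu[2], f_a = NA_real_,
                        f_b = NA_real_, ln_odds = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, undefined = TRUE))
    }
    lr <- odds_ratio(fa, fb)
    data.frame(lower_d = lu[1], upper_d = lu[2], f_a = fa$estimate,
               f_b = fb$estimate, ln_odds = lr$estimate, ci_lower = lr$lower,
               ci_upper = lr$upper, undefined = lr$infinite)
  })
  do.call(rbind, rows)
}
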