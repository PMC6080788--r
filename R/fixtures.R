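#' Specification for synthetic test structures
#'
#' Parameters of the synthetic coarse "proteins" used throughout the test
#' suite and the calibration simulations: a dense spherical core (whose
#' vertex residues all have high local density) decorated with well
#' separated radial spikes whose tip residues are guaranteed hull vertices
#' with low density -- i.e. planted protrusions with known ground truth.
#'
#' @param n_core_residues Residues in the dense core (uniform in a ball).
#' @param core_radius Core ball radius (nm).
#' @param n_spikes Number of planted protrusions.
#' @param spike_length Radial spike length beyond the core surface (nm).
#' @param hydrophobe_placement Either a probability (each spike tip is
#'   hydrophobic independently with this probability) or a logical vector of
#'   length `n_spikes` planting hydrophobes deterministically.
#' @param n_families,proteins_per_family Cohort layout for [make_cohort()].
#' @param membrane Optional list with `half_thickness` and `lih_depth` (nm)
#'   for [make_membrane_scene()].
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   fixtures.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_core_residues = 100, core_radius = 1.0,
                         n_spikes = 8, spike_length = 1.2,
                         hydrophobe_placement = 1.0,
                         n_families = 10, proteins_per_family = 1,
                         membrane = list(half_thickness = 1.5, lih_depth = 0),
                         seed = 1L) {
  stopifnot(n_core_residues >= 4, core_radius > 0, n_spikes >= 0,
            spike_length > 0, n_families >= 1, proteins_per_family >= 1)
  if (is.logical(hydrophobe_placement)) {
    stopifnot(length(hydrophobe_placement) == n_spikes)
  } else {
    stopifnot(length(hydrophobe_placement) == 1,
              hydrophobe_placement >= 0, hydrophobe_placement <= 1)
  }
  structure(list(n_core_residues = n_core_residues, core_radius = core_radius,
                 n_spikes = n_spikes, spike_length = spike_length,
                 hydrophobe_placement = hydrophobe_placement,
                 n_families = n_families,
                 proteins_per_family = proteins_per_family,
                 membrane = membrane, seed = as.integer(seed)),
            class = "fixture_spec")
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_directions <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

HYDROPHOBE7 <- c("LEU", "ILE", "PHE", "TYR", "TRP", "CYS", "MET")

#' Generate a spiky synthetic protein with known protrusions
#'
#' Builds a coarse structure from a dense core of residues sampled in a ball
#' plus `n_spikes` radial spikes (tip C-beta on a sphere outside the core,
#' C-alpha 0.15 nm inward).  Spike tips are guaranteed hull vertices with
#' low local density; the generated ground truth is verified at generation
#' time by fitting the protrusion model and requiring that the planted
#' spikes are exactly the protrusion set (generation fails loudly
#' otherwise).
#'
#' @param spec A [fixture_spec()].
#' @param model_id Identifier for the generated structure.
#' @param config A [protrusion_config()] used for the verification fit.
#' @return List with `model` (the [coarse_structure()]), `fit` (the
#'   verification [protrusion_model()]), and `truth` (planted protrusion
#'   residue ids, spike hydrophobe flags, co-insertable adjacency and the
#'   realized LIH id).
#' @export
make_spiky_protein <- function(spec, model_id = "fixture",
                               config = protrusion_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  config <- as_config(config)
  k <- spec$n_spikes
  n <- spec$n_core_residues
  model <- with_stream_seed(spec$seed, {
    # core: C-alpha uniform in the ball, C-beta 0.15 nm in a random direction
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ca <- u * spec$core_radius * stats::runif(n)^(1 / 3)
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    cb <- ca + 0.15 * v
    aa <- rep(c("ALA", "SER"), length.out = n)
    if (k > 0) {
      dirs <- fibonacci_directions(k)
      tip_cb <- dirs * (spec$core_radius + spec$spike_length)
      tip_ca <- dirs * (spec$core_radius + spec$spike_length - 0.15)
      ca <- rbind(ca, tip_ca)
      cb <- rbind(cb, tip_cb)
      hyd <- if (is.logical(spec$hydrophobe_placement)) spec$hydrophobe_placement
             else stats::runif(k) < spec$hydrophobe_placement
      spike_aa <- ifelse(hyd, sample(HYDROPHOBE7, k, replace = TRUE), "ALA")
      aa <- c(aa, spike_aa)
      min_sep <- if (k > 1) min(stats::dist(tip_cb)) else Inf
      if (min_sep <= 2 * config$hull_tolerance)
        stop("spike separation too small to guarantee vertexhood")
    } else {
      hyd <- logical(0)
    }
    res <- data.frame(chain = "A", resno = seq_len(nrow(ca)), icode = " ",
                      amino_acid = aa,
                      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                      cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
                      stringsAsFactors = FALSE)
    m <- coarse_structure(res, model_id = model_id)
    attr(m, "spike_hydrophobes") <- hyd
    m
  })
  fit <- protrusion_model(model, config, sasa = "never")
  planted <- if (k > 0) seq.int(n + 1L, n + k) else integer(0)
  found <- which(fit$residues$is_protrusion)
  if (!identical(sort(found), sort(planted)))
    stop("fixture generation failed: planted spikes are not exactly the ",
         "protrusion set (", length(found), " protrusions found, ",
         k, " planted); increase core density or spike separation")
  truth <- list(protrusion_ids = fit$residues$residue_id[planted],
                spike_hydrophobes = attr(model, "spike_hydrophobes"),
                pairs = fit$pairs,
                lih = if (is.na(fit$lih)) NA_character_
                      else fit$residues$residue_id[fit$lih])
  list(model = model, fit = fit, truth = truth)
}

#' Generate a synthetic cohort of spiky proteins
#'
#' Families of spiky proteins with per-spike hydrophobe probability as given
#' in the spec; used for enrichment-recovery and null-calibration studies.
#' Per-protein seeds are derived deterministically from the spec seed and
#' the family/protein indices.
#'
#' @param spec A [fixture_spec()].
#' @param name Cohort name (also prefixes model ids).
#' @param config A [protrusion_config()].
#' @return A [cohort()] of fitted models, with the generated fixtures in
#'   `attr(, "fixtures")`.
#' @export
make_cohort <- function(spec, name = "synthetic", config = protrusion_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  fits <- list()
  fams <- character(0)
  fixtures <- list()
  for (f in seq_len(spec$n_families)) {
    for (j in seq_len(spec$proteins_per_family)) {
      sub <- spec
      sub$seed <- as.integer((spec$seed + 104729 * f + 7919 * j) %% 2147483647)
      id <- sprintf("%s_f%03d_p%02d", name, f, j)
      fx <- make_spiky_protein(sub, model_id = id, config = config)
      fits[[id]] <- fx$fit
      fixtures[[id]] <- fx
      fams <- c(fams, sprintf("fam%03d", f))
    }
  }
  out <- cohort(fits, fams, name = name)
  attr(out, "fixtures") <- fixtures
  out
}

#' Generate a membrane scene with known geometry
#'
#' Places a synthetic protein against a planar hydrocarbon slab.  For
#' `kind = "spiky"` the realized Likely Inserted Hydrophobe's C-alpha is
#' placed at the requested insertion coordinate (`spec$membrane$lih_depth`)
#' by orienting the membrane along the LIH direction.  For `kind = "rod"` a
#' helical rod threading the slab along its normal is built, so the
#' non-binding fragment is exactly the two end caps.
#'
#' @param spec A [fixture_spec()].
#' @param kind `"spiky"` or `"rod"`.
#' @param model_id Identifier for the structure.
#' @param config A [protrusion_config()].
#' @return List with `model`, `fit`, `frame` ([membrane_frame()]) and
#'   `truth` (for rods: the residue ids of the expected non-binding
#'   fragment; for spiky scenes: the planted LIH depth).
#' @export
make_membrane_scene <- function(spec, kind = c("spiky", "rod"),
                                model_id = "scene",
                                config = protrusion_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$membrane$half_thickness
  if (kind == "spiky") {
    fx <- make_spiky_protein(spec, model_id = model_id, config = config)
    if (is.na(fx$fit$lih))
      stop("membrane scene needs a protein with a Likely Inserted Hydrophobe")
    depth <- spec$membrane$lih_depth
    ca <- as.numeric(fx$fit$residues[fx$fit$lih, c("ca_x", "ca_y", "ca_z")])
    ctr <- colMeans(as.matrix(fx$fit$residues[, c("ca_x", "ca_y", "ca_z")]))
    normal <- ca - ctr
    normal <- normal / sqrt(sum(normal^2))
    frame <- membrane_frame(center = ca - (h - depth) * normal,
                            normal = normal, half_thickness = h, side = -1L)
    list(model = fx$model, fit = fx$fit, frame = frame,
         truth = list(lih = fx$truth$lih, lih_depth = depth))
  } else {
    n <- spec$n_core_residues
    z <- seq(-2.5 * h, 2.5 * h, length.out = n)
    theta <- seq(0, 6 * pi, length.out = n)
    ca <- cbind(0.3 * cos(theta), 0.3 * sin(theta), z)
    cb <- cbind(0.45 * cos(theta), 0.45 * sin(theta), z)
    res <- data.frame(chain = "A", resno = seq_len(n), icode = " ",
                      amino_acid = rep(c("ALA", "LEU"), length.out = n),
                      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                      cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
                      stringsAsFactors = FALSE)
    model <- coarse_structure(res, model_id = model_id)
    frame <- membrane_frame(center = c(0, 0, 0), normal = c(0, 0, 1),
                            half_thickness = h)
    fit <- protrusion_model(model, config, sasa = "never")
    expected <- res$resno[h - abs(z) <= -config$fragment_min_distance]
    list(model = model, fit = fit, frame = frame,
         truth = list(fragment_resno = expected))
  }
}
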