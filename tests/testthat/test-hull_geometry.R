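test_that("simplex and interior points behave as expected", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- compute_hull(tet)
  expect_setequal(h$vertices, 1:4)
  expect_equal(nrow(h$edges), 6)
  h2 <- compute_hull(rbind(tet, c(0.2, 0.2, 0.2)))
  expect_setequal(h2$vertices, 1:4)
})

test_that("degenerate clouds raise errors naming the rank", {
  expect_error(compute_hull(matrix(rnorm(9), 3, 3)), "at least 4 points")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(compute_hull(line), "collinear|rank 1")
  plane <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(compute_hull(plane), "coplanar|rank 2")
})

test_that("hull vertices and edges match the LP brute-force oracle", {
  set.seed(71)
  clouds <- lapply(c(15, 25, 35), function(n) matrix(rnorm(3 * n), ncol = 3))
  oracle <- lp_hull_oracle(clouds)
  for (i in seq_along(clouds)) {
    h <- compute_hull(clouds[[i]])
    expect_equal(sort(h$vertices), oracle[[i]]$vertices)
    expect_equal(edge_key(h$edges), edge_key(oracle[[i]]$edges))
  }
})

test_that("coplanar facets merge: a cube has 8 vertices and 12 edges", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- compute_hull(cube)
  expect_setequal(h$vertices, 1:8)
  expect_equal(nrow(h$edges), 12)
})

test_that("local density counts the residue's own atoms and is boundary-inclusive", {
  # isolated residue: own CA (0.15 nm away) + own CB
  m <- make_coarse(matrix(c(0.15, 0, 0), 1), matrix(c(0, 0, 0), 1))
  expect_equal(local_density(m), 2L)
  # neighbors at 0.99, 1.00 and 1.01 nm from the C-beta
  probe <- function(dist) {
    m <- make_coarse(rbind(c(0.15, 0, 0), c(-dist, 0, 0)),
                     rbind(c(0, 0, 0), NA), c("ALA", "GLY"))
    local_density(m)[1]
  }
  expect_equal(probe(0.99), 3L)
  expect_equal(probe(1.00), 3L)
  expect_equal(probe(1.01), 2L)
})

test_that("local density matches a brute-force pairwise recount", {
  set.seed(5)
  ca <- matrix(rnorm(150, sd = 0.8), ncol = 3)
  u <- matrix(rnorm(150), ncol = 3)
  cb <- ca + 0.15 * u / sqrt(rowSums(u^2))
  cb[3, ] <- NA # one glycine-like residue
  m <- make_coarse(ca, cb)
  d <- local_density(m)
  pts <- structure_points(m)$coords
  for (i in seq_len(50)) {
    if (is.na(d[i])) next
    ref <- sum(sqrt(colSums((t(pts) - cb[i, ])^2)) <= 1.0)
    expect_identical(d[i], as.integer(ref))
  }
  expect_true(is.na(d[3]))
})

test_that("protrusions are vertex residues with d below the threshold", {
  fit21 <- protrusion_model(make_density_probe(19)) # d = 21
  expect_equal(fit21$residues$d[TARGET_ROW], 21L)
  expect_true(fit21$residues$is_vertex[TARGET_ROW])
  expect_true(fit21$residues$is_protrusion[TARGET_ROW])
  fit22 <- protrusion_model(make_density_probe(20)) # d = 22
  expect_equal(fit22$residues$d[TARGET_ROW], 22L)
  expect_true(fit22$residues$is_vertex[TARGET_ROW])
  expect_false(fit22$residues$is_protrusion[TARGET_ROW])
})

test_that("residues without a C-beta can never be vertex residues", {
  fit <- protrusion_model(make_density_probe(3))
  gly <- fit$residues$amino_acid == "GLY"
  expect_false(any(fit$residues$is_vertex[gly]))
  expect_false(any(fit$residues$is_protrusion[gly]))
})

test_that("raising the density threshold never removes a protrusion", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 8, seed = 2))
  p22 <- which(protrusion_model(fx$model,
                                protrusion_config(density_threshold = 22))$residues$is_protrusion)
  p30 <- which(protrusion_model(fx$model,
                                protrusion_config(density_threshold = 30))$residues$is_protrusion)
  expect_true(all(p22 %in% p30))
})

test_that("lowering the density radius never increases any density", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 5, seed = 9))
  d1 <- local_density(fx$model, protrusion_config(density_radius = 1.0))
  d07 <- local_density(fx$model, protrusion_config(density_radius = 0.7))
  expect_true(all(d07 <= d1, na.rm = TRUE))
})

test_that("co-insertable pairs are protrusion pairs joined by hull edges", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 8, seed = 4))
  fit <- fx$fit
  pairs <- co_insertable_pairs(fit)
  expect_true(all(fit$residues$is_protrusion[pairs$a]))
  expect_true(all(fit$residues$is_protrusion[pairs$b]))
  expect_true(all(pairs$a != pairs$b))
  expect_true(all(pairs$one_hydrophobe[pairs$both_hydrophobe]))
  # pair set equals {hull edges} intersected with {protrusion CB points}
  pts <- fit$hull$points
  cb_of <- function(i) which(pts$residue == i & pts$type == "CB")
  expected <- edge_key(fit$hull$edges)
  got <- vapply(seq_len(nrow(pairs)), function(k) {
    e <- sort(c(cb_of(pairs$a[k]), cb_of(pairs$b[k])))
    paste(e[1], e[2], sep = "-")
  }, character(1))
  expect_true(all(got %in% expected))
  # and every hull edge between two protrusion C-betas is a pair
  prot_pts <- vapply(which(fit$residues$is_protrusion), cb_of, integer(1))
  on_prot <- fit$hull$edges[, 1] %in% prot_pts & fit$hull$edges[, 2] %in% prot_pts
  expect_equal(nrow(pairs), sum(on_prot))
})

test_that("co-insertable hydrophobe counts agree with a per-pair recount", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 10,
                                        hydrophobe_placement = 0.5, seed = 8))
  fit <- fx$fit
  r <- fit$residues
  pairs <- fit$pairs
  recount <- integer(nrow(r))
  for (k in seq_len(nrow(pairs))) {
    if (r$is_hydrophobe[pairs$b[k]])
      recount[pairs$a[k]] <- recount[pairs$a[k]] + 1L
    if (r$is_hydrophobe[pairs$a[k]])
      recount[pairs$b[k]] <- recount[pairs$b[k]] + 1L
  }
  expect_identical(r$co_insertable_hydrophobes, recount)
  expect_true(all(r$co_insertable_hydrophobes[!r$is_protrusion] == 0))
})

test_that("with all residues hydrophobic, one_hydrophobe equals both_hydrophobe", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 8,
                                        hydrophobe_placement = 1, seed = 3))
  pairs <- fx$fit$pairs
  expect_gt(nrow(pairs), 0)
  expect_identical(pairs$one_hydrophobe, pairs$both_hydrophobe)
})

test_that("LIH selection maximizes co-insertable count, then minimizes density", {
  r <- data.frame(is_protrusion = TRUE, is_hydrophobe = TRUE,
                  co_insertable_hydrophobes = c(3L, 1L), d = c(10L, 5L))
  expect_equal(prothull:::select_lih(r, protrusion_config(), "x"), 1L)
  r2 <- data.frame(is_protrusion = TRUE, is_hydrophobe = TRUE,
                   co_insertable_hydrophobes = c(2L, 2L), d = c(10L, 15L))
  expect_equal(prothull:::select_lih(r2, protrusion_config(), "x"), 1L)
  # non-hydrophobes and non-protrusions are never candidates
  r3 <- data.frame(is_protrusion = c(TRUE, TRUE, FALSE),
                   is_hydrophobe = c(FALSE, TRUE, TRUE),
                   co_insertable_hydrophobes = c(9L, 1L, 9L), d = c(2L, 8L, 2L))
  expect_equal(prothull:::select_lih(r3, protrusion_config(), "x"), 2L)
  # no protruding hydrophobe at all
  r4 <- data.frame(is_protrusion = FALSE, is_hydrophobe = TRUE,
                   co_insertable_hydrophobes = 0L, d = 3L)
  expect_true(is.na(prothull:::select_lih(r4, protrusion_config(), "x")))
})

test_that("residual LIH ties are broken reproducibly by the seeded stream", {
  r <- data.frame(is_protrusion = TRUE, is_hydrophobe = TRUE,
                  co_insertable_hydrophobes = rep(2L, 4), d = rep(7L, 4))
  picks <- vapply(1:20, function(i) {
    prothull:::select_lih(r, protrusion_config(random_seed = 99), "same-id")
  }, integer(1))
  expect_length(unique(picks), 1) # same seed + id: deterministic
  other <- prothull:::select_lih(r, protrusion_config(random_seed = 99), "zq")
  expect_true(other %in% 1:4)
})

test_that("rigid rotation and translation leave all hull annotations invariant", {
  fx <- make_spiky_protein(fixture_spec(n_spikes = 7,
                                        hydrophobe_placement = 0.6, seed = 13))
  m <- fx$model
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1)) %*%
    rbind(c(1, 0, 0),
          c(0, cos(0.41), -sin(0.41)),
          c(0, sin(0.41), cos(0.41)))
  shift <- c(3.2, -1.1, 0.7)
  rot <- m
  ca <- as.matrix(m$residues[, c("ca_x", "ca_y", "ca_z")]) %*% t(R)
  cb <- as.matrix(m$residues[, c("cb_x", "cb_y", "cb_z")]) %*% t(R)
  rot$residues[, c("ca_x", "ca_y", "ca_z")] <- sweep(ca, 2, shift, "+")
  rot$residues[, c("cb_x", "cb_y", "cb_z")] <- sweep(cb, 2, shift, "+")
  f1 <- protrusion_model(m)
  f2 <- protrusion_model(rot)
  expect_identical(f1$residues$is_vertex, f2$residues$is_vertex)
  expect_identical(f1$residues$d, f2$residues$d)
  expect_identical(f1$residues$is_protrusion, f2$residues$is_protrusion)
  expect_identical(f1$pairs[, c("a", "b")], f2$pairs[, c("a", "b")])
  expect_identical(f1$lih, f2$lih)
})
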