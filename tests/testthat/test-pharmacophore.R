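single_hba_model <- function(tolerance = 1.6, weight = 1) {
  pharmacophore_model("single", list(
    sphere_constraint("HBA", c(0, 0, 0), tolerance, weight)), max_omitted = 0L)
}

test_that("correspondence enumeration counts and kind-filters correctly", {
  feats2 <- make_features(c("HBA", "HBA"), c(0, 0, 0, 1, 0, 0))
  expect_length(enumerate_correspondences(feats2, single_hba_model()), 2L)

  ar_model <- pharmacophore_model("ar", list(
    sphere_constraint("AR", c(0, 0, 0)), sphere_constraint("AR", c(3, 0, 0))))
  hy_feats <- make_features(c("HY", "HY"), c(0, 0, 0, 3, 0, 0))
  expect_length(enumerate_correspondences(hy_feats, ar_model), 0L)

  # 3 same-kind constraints vs 4 same-kind features, unpruned: 4*3*2 orderings
  m3 <- pharmacophore_model("m3", list(
    sphere_constraint("HY", c(0, 0, 0)), sphere_constraint("HY", c(3, 0, 0)),
    sphere_constraint("HY", c(0, 3, 0))))
  f4 <- make_features(rep("HY", 4), c(0, 0, 0, 3, 0, 0, 0, 3, 0, 9, 9, 9))
  maps <- enumerate_correspondences(f4, m3, prune = FALSE)
  expect_length(maps, 24L)
  expect_identical(anyDuplicated(vapply(maps, paste, character(1),
                                        collapse = ",")), 0L)
  # pruning keeps only distance-compatible assignments, a strict subset
  expect_lt(length(enumerate_correspondences(f4, m3)), 24L)
})

test_that("fit partial scores follow the quadratic fall-off closed form", {
  m <- single_hba_model()
  at <- function(d) make_features("HBA", c(d, 0, 0))
  expect_equal(fit_value(at(0), m, optimize = FALSE)$fit, 1.0)
  expect_equal(fit_value(at(1.6), m, optimize = FALSE)$fit, 0.0)
  expect_equal(fit_value(at(0.8), m, optimize = FALSE)$fit, 0.75)
  # beyond tolerance the molecule does not map in the fixed pose
  res <- fit_value(at(2.0), m, optimize = FALSE)
  expect_identical(res$n_mapped, 0L)
  expect_identical(res$fit, 0)
  # with pose optimization a single sphere is always centred exactly
  expect_equal(fit_value(at(2.0), m)$fit, 1.0)
})

test_that("fit splits pair mismatch evenly after superposition", {
  t0 <- 1.6
  m <- pharmacophore_model("pair", list(
    sphere_constraint("HBA", c(0, 0, 0), t0),
    sphere_constraint("HY", c(4, 0, 0), t0)))
  for (e in c(0, 0.4, 0.8, 1.2)) {
    f <- make_features(c("HBA", "HY"), c(0, 0, 0, 4 + e, 0, 0))
    expect_equal(fit_value(f, m)$fit, 2 * (1 - (e / (2 * t0))^2),
                 tolerance = 1e-9)
  }
})

test_that("fit is invariant to rigid motion and bounded by total weight", {
  model <- pharmacophore_model("m", list(
    sphere_constraint("HBA", c(0, 0, 0), weight = 2),
    sphere_constraint("HY", c(3.5, 0, 0), weight = 2),
    sphere_constraint("AR", c(0, 4, 1), weight = 2)))
  set.seed(11)
  base <- make_features(c("HBA", "HY", "AR", "HY"),
                        c(0.2, 0.1, 0, 3.4, -0.3, 0.2, 0.1, 3.8, 1.2, 8, 8, 8))
  f0 <- fit_value(base, model)$fit
  expect_gt(f0, 0)
  expect_lte(f0, sum(model$constraints$weight))
  for (i in 1:5) {
    moved <- transform_features(base, random_rotation(), stats::runif(3, -9, 9))
    expect_equal(fit_value(moved, model)$fit, f0, tolerance = 1e-6)
  }
})

test_that("fit decreases monotonically under radial displacement", {
  m <- pharmacophore_model("pair", list(
    sphere_constraint("HBA", c(0, 0, 0)),
    sphere_constraint("HY", c(4, 0, 0))))
  fits <- vapply(seq(0, 2.5, by = 0.25), function(e) {
    fit_value(make_features(c("HBA", "HY"), c(0, 0, 0, 4 + e, 0, 0)), m)$fit
  }, numeric(1))
  expect_true(all(diff(fits) <= 1e-12))
})

test_that("fit equals the brute-force correspondence oracle", {
  skip_if_not_installed("bio3d")
  set.seed(5)
  model <- pharmacophore_model("m", list(
    sphere_constraint("HBA", c(0, 0, 0)), sphere_constraint("HY", c(3, 1, 0)),
    sphere_constraint("HY", c(1, 4, 2)), sphere_constraint("AR", c(-2, 2, -1))),
    max_omitted = 1L)
  cons <- as.matrix(model$constraints[, c("x", "y", "z")])
  for (i in 1:6) {
    f <- rbind(cons + matrix(stats::rnorm(12, 0, 0.15), 4, 3),
               matrix(stats::runif(6, -6, 6), 2, 3))
    kinds <- c(model$constraints$kind, "HY", "HBA")
    pose <- f %*% t(random_rotation()) +
      matrix(stats::runif(3, -5, 5), 6, 3, byrow = TRUE)
    feats <- make_features(kinds, as.numeric(t(pose)))
    expect_equal(fit_value(feats, model)$fit, oracle_fit(feats, model),
                 tolerance = 1e-3)
  }
})

test_that("unmappable molecules return fit zero with an empty mapping", {
  m <- pharmacophore_model("m", list(
    sphere_constraint("HBA", c(0, 0, 0)), sphere_constraint("HBA", c(30, 0, 0))))
  f <- make_features(c("HBA", "HBA"), c(0, 0, 0, 1, 0, 0))
  res <- fit_value(f, m)
  expect_identical(res$fit, 0)
  expect_true(all(is.na(res$correspondence)))
})

test_that("conformer selection maximizes fit with lowest-index tie-break", {
  t0 <- 1.6
  m <- pharmacophore_model("pair", list(
    sphere_constraint("HBA", c(0, 0, 0), t0),
    sphere_constraint("HY", c(4, 0, 0), t0)))
  # HBA group: C(anchor)+O ; HY group: C3.  Place O at origin.
  conf_with_gap <- function(e) {
    ang <- c(0, 2, 4) * pi / 3
    rbind(c(-1.22, 0, 0), c(0, 0, 0),                       # C=O
          cbind(4 + e, 0.87 * cos(ang), 0.87 * sin(ang)))   # C3 centroid exact
  }
  atoms <- data.frame(elem = c("C", "O", "C", "C", "C"))
  bonds <- data.frame(a1 = c(1, 3, 4), a2 = c(2, 4, 5), order = c(2, 1, 1))
  gaps <- c(1.8, 0.4, 1.2)  # planted fits low, high, mid
  mol <- mol_record("multi", atoms, bonds,
                    conformers = lapply(gaps, conf_with_gap))
  best <- best_fit_over_conformers(mol, m)
  expect_identical(best$conformer, 2L)
  expect_equal(best$fit, 2 * (1 - (0.4 / (2 * t0))^2), tolerance = 1e-6)

  mol2 <- mol_record("dup", atoms, bonds,
                     conformers = list(conf_with_gap(0.4), conf_with_gap(0.4)))
  expect_identical(best_fit_over_conformers(mol2, m)$conformer, 1L)
  expect_error(best_fit_over_conformers(
    mol_record("none", atoms, bonds), m), "no conformers")
})
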