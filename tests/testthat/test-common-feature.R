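# independent brute-force oracle: maximal reference-feature subsets that
# have an injective, kind- and distance-compatible image in every other
# molecule's feature set
oracle_common_sets <- function(feat_list, ref_idx, bin, min_size = 2L) {
  ref <- feat_list[[ref_idx]]
  others <- feat_list[-ref_idx]
  dref <- as.matrix(stats::dist(as.matrix(ref[, c("x", "y", "z")])))
  supported <- function(subset, other) {
    doth <- as.matrix(stats::dist(as.matrix(other[, c("x", "y", "z")])))
    ok <- FALSE
    recurse <- function(k, img) {
      if (ok) return(invisible())
      if (k > length(subset)) { ok <<- TRUE; return(invisible()) }
      for (f in seq_len(nrow(other))) {
        if (f %in% img) next
        if (other$kind[f] != ref$kind[subset[k]]) next
        good <- TRUE
        for (j in seq_len(k - 1)) {
          if (abs(dref[subset[k], subset[j]] - doth[f, img[j]]) > bin) {
            good <- FALSE; break
          }
        }
        if (good) recurse(k + 1L, c(img, f))
      }
    }
    recurse(1L, integer(0))
    ok
  }
  nf <- nrow(ref)
  all_sets <- unlist(lapply(min_size:nf, function(sz) {
    asplit(utils::combn(nf, sz), 2)
  }), recursive = FALSE)
  common <- Filter(function(s) all(vapply(others, function(o) supported(s, o),
                                          logical(1))), all_sets)
  common <- lapply(common, as.integer)
  keep <- vapply(seq_along(common), function(i) {
    !any(vapply(seq_along(common), function(j) {
      i != j && length(common[[i]]) < length(common[[j]]) &&
        all(common[[i]] %in% common[[j]])
    }, logical(1)))
  }, logical(1))
  common[keep]
}

test_that("a planted shared triangle is recovered from two actives", {
  pair <- planted_triangle_pair()
  cand <- build_common_feature_models(pair, common_feature_params())
  expect_gt(nrow(cand), 0L)
  top <- cand$model[[1]]
  expect_identical(cand$n_constraints[1], 3L)
  expect_setequal(top$constraints$kind, c("HBA", "HY", "AR"))
  d <- sort(as.numeric(stats::dist(as.matrix(
    top$constraints[, c("x", "y", "z")]))))
  expect_equal(d, c(3, 4, 5), tolerance = 0.35)
  expect_identical(cand$support[1], 2L)
})

test_that("a duplicated active recovers its full feature arrangement", {
  spec <- sim_spec(n_actives = 1, n_decoys = 0, seed = 17)
  a <- generate_feature_molecules(spec)$mol[[1]]
  b <- a; b$id <- "copy"
  pair <- molecule_table(list(a, b))
  nf <- nrow(perceive_features(a))
  cand <- build_common_feature_models(pair, common_feature_params())
  expect_identical(cand$n_constraints[1], nf)
})

test_that("kind-disjoint actives share no arrangement", {
  hy_model <- pharmacophore_model("hy", list(
    sphere_constraint("HY", c(0, 0, 0)), sphere_constraint("HY", c(5, 0, 0)),
    sphere_constraint("HY", c(0, 6, 0))))
  ar_model <- pharmacophore_model("ar", list(
    sphere_constraint("AR", c(0, 0, 0)), sphere_constraint("AR", c(6, 0, 0)),
    sphere_constraint("AR", c(0, 7, 0))))
  a <- generate_feature_molecules(sim_spec(1, 0, hy_model, jitter = 0,
                                           seed = 5))$mol[[1]]
  b <- generate_feature_molecules(sim_spec(1, 0, ar_model, jitter = 0,
                                           seed = 6))$mol[[1]]
  b$id <- "ar_only"
  cand <- build_common_feature_models(molecule_table(list(a, b)),
                                      common_feature_params(min_features = 2L))
  expect_identical(nrow(cand), 0L)
})

test_that("clique intersection matches the brute-force subset oracle", {
  pair <- planted_triangle_pair()
  params <- common_feature_params(min_features = 2L)
  feat_list <- lapply(pair$mol, perceive_features)
  nfeat <- vapply(feat_list, nrow, integer(1))
  ref_idx <- order(-nfeat, pair$id)[1]
  oracle <- oracle_common_sets(feat_list, ref_idx, params$distance_bin)
  cand <- build_common_feature_models(pair, params)
  # compare as kind-multiset + sorted pairwise distances signatures
  sig <- function(kinds, xyz) {
    paste(paste(sort(kinds), collapse = ","),
          paste(round(sort(as.numeric(stats::dist(xyz))), 1), collapse = ","))
  }
  ref_feats <- feat_list[[ref_idx]]
  oracle_sigs <- sort(vapply(oracle, function(s) {
    sig(ref_feats$kind[s], as.matrix(ref_feats[s, c("x", "y", "z")]))
  }, character(1)))
  cand_sigs <- sort(vapply(cand$model, function(m) {
    sig(m$constraints$kind, as.matrix(m$constraints[, c("x", "y", "z")]))
  }, character(1)))
  expect_identical(cand_sigs, oracle_sigs)
})

test_that("candidate generation is invariant to active input order", {
  pair <- planted_triangle_pair()
  rev_pair <- pair[2:1, ]
  c1 <- build_common_feature_models(pair, common_feature_params())
  c2 <- build_common_feature_models(rev_pair, common_feature_params())
  expect_identical(c1$n_constraints, c2$n_constraints)
  expect_identical(c1$kinds, c2$kinds)
  expect_equal(c1$model[[1]]$constraints, c2$model[[1]]$constraints)
})

test_that("discrimination ranking puts the planted model first", {
  model <- planted_model_default()
  actives <- generate_feature_molecules(
    sim_spec(4, 0, model, jitter = 0.15, seed = 8))
  inactives <- generate_feature_molecules(
    sim_spec(0, 4, model, separation = 4, seed = 9))
  planted_cand <- tibble::tibble(
    model = list(model,
                 pharmacophore_model("loose", dplyr::mutate(
                   model$constraints, tolerance = 8), max_omitted = 1L)),
    n_constraints = c(5L, 5L), kinds = "x", support = 4L)
  ranked <- rank_by_discrimination(planted_cand, actives, inactives)
  expect_gt(ranked$discrimination[1], 0)
  expect_true(all(diff(ranked$discrimination) <= 0))
  expect_identical(ranked$model[[1]]$name, "planted")

  same <- rank_by_discrimination(planted_cand[1, ], actives, actives)
  expect_equal(same$discrimination, 0)
  one <- rank_by_discrimination(planted_cand[1, ], actives, inactives)
  expect_identical(nrow(one), 1L)
  expect_error(rank_by_discrimination(planted_cand, actives[0, ], inactives),
               "non-empty")
})
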