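test_that("rotatable-bond definition excludes terminal, ring and amide bonds", {
  expect_identical(count_rotatable_bonds(toy_ethanol()), 0L)
  expect_identical(count_rotatable_bonds(toy_benzene()), 0L)
  expect_identical(count_rotatable_bonds(toy_acetamide()), 0L)
  butane <- mol_record("butane", data.frame(elem = rep("C", 4)),
                       data.frame(a1 = 1:3, a2 = 2:4, order = 1),
                       list(cbind(1.5 * (0:3), 0, 0)))
  expect_identical(count_rotatable_bonds(butane), 1L)
  expect_identical(count_rotatable_bonds(toy_alkane(10)), 7L)
})

test_that("Lipinski filter applies inclusive bounds with named violations", {
  mols <- molecule_table(list(toy_ethanol(), toy_alkane(40)))
  res <- lipinski_filter(mols)
  eth <- res[res$id == "ethanol", ]
  expect_equal(eth$mw, 46.07, tolerance = 0.01)
  expect_identical(eth$rotatable, 0L)
  expect_identical(eth$hba, 1L)
  expect_identical(eth$hbd, 1L)
  expect_true(eth$pass)
  alk <- res[res$id != "ethanol", ]
  expect_equal(alk$mw, 40 * 12.011 + 82 * 1.008, tolerance = 0.5)
  expect_false(alk$pass)
  expect_true("mw" %in% alk$violations[[1]])
  # the MW bound is inclusive: a molecule exactly at the limit passes
  at_limit <- filter_thresholds(mw_max = alk$mw, rotatable_max = 40)
  expect_true(lipinski_filter(mols, at_limit)$pass[2])
})

test_that("ADMET levels follow the documented surrogate bins", {
  mols <- molecule_table(list(toy_ethanol(), toy_alkane(40)))
  pr <- molecular_properties(mols)
  res <- admet_filter(mols, properties = pr)
  # ESOL-style estimate binned as documented
  expect_equal(res$log_s,
               0.16 - 0.63 * pr$logp - 0.0062 * pr$mw + 0.066 * pr$rotatable -
                 0.74 * pr$aromatic_prop)
  eth <- res[res$id == "ethanol", ]
  expect_identical(eth$absorption_level, 0L)     # small polar molecule
  alk <- res[res$id != "ethanol", ]
  expect_gt(pr$logp[pr$id != "ethanol"], 5.88)   # extreme lipophilicity
  expect_false(alk$absorption_level == 0L)
  # equality semantics: passing requires hitting the cutoff levels exactly,
  # and re-targeting the cutoffs to the measured levels flips the outcome
  expect_false(eth$pass)
  tuned <- filter_thresholds(admet_cutoffs = list(
    solubility = eth$solubility_level, absorption = eth$absorption_level,
    bbb = eth$bbb_level))
  expect_true(admet_filter(mols, tuned, properties = pr)$pass[1])
})

test_that("similarity search matches a hand-computed Tanimoto oracle", {
  db <- molecule_table(list(toy_benzene(), toy_hexane(), toy_ethanol(),
                            toy_methanol(), toy_alkane(8), toy_acetamide()))
  hits <- similarity_search(toy_hexane(), db, min_similarity = 0)
  expect_equal(hits$similarity[hits$id == "hexane"], 1.0)
  expect_true(all(diff(hits$similarity) <= 1e-12))

  # oracle: Tanimoto on explicitly enumerated atom-pair descriptor sets
  sdf <- pharmscreen:::.as_sdfset(db)
  ap <- ChemmineR::sdf2ap(sdf)
  descs <- lapply(seq_along(ChemmineR::cid(ap)), function(i) ap[[i]]@AP)
  names(descs) <- ChemmineR::cid(ap)
  q <- descs[["hexane"]]
  manual <- vapply(db$id, function(id) {
    x <- descs[[id]]
    length(intersect(q, x)) / length(union(q, x))
  }, numeric(1))
  for (i in seq_len(nrow(hits))) {
    expect_equal(hits$similarity[i], unname(manual[hits$id[i]]),
                 tolerance = 1e-9)
  }
  # threshold keeps exactly the oracle's admissible set
  thr_hits <- similarity_search(toy_hexane(), db, min_similarity = 0.4)
  expect_setequal(thr_hits$id, names(manual)[manual >= 0.4])

  # anchor substructure: an aromatic ring requirement excludes alkanes
  anchored <- similarity_search(toy_benzene(), db, min_similarity = 0,
                                anchor = "c1ccccc1")
  expect_true("benzene" %in% anchored$id)
  expect_false(any(c("hexane", "ethanol") %in% anchored$id))

  empty <- similarity_search(toy_benzene(), db[0, ], min_similarity = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("docking scores ingest with last-wins duplicates and drop rules", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tscore", "a\t62", "b\t59", "c\t61", "d\t60"), tsv)
  sc <- ingest_docking_scores(tsv)
  hits <- c("a", "b", "c", "d", "e")
  expect_warning(out <- apply_score_filter(hits, sc, 60), "without docking")
  expect_identical(out, c("a", "c", "d"))  # >= is inclusive
  expect_identical(suppressWarnings(
    apply_score_filter(hits, sc[0, ], 60)), character(0))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tscore", "a\t10", "a\t70"), dup)
  expect_warning(sc2 <- ingest_docking_scores(dup), "duplicate")
  expect_equal(sc2$score, 70)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tscore", "a\tnot_a_number"), bad)
  expect_error(ingest_docking_scores(bad), "malformed")
})

test_that("the cascade retains planted survivors and accounts stage by stage", {
  w <- make_screen_world()
  rep <- run_cascade(w$db, w$models, w$fit, w$thr)
  expect_setequal(rep$final_hits, w$actives)
  st <- rep$stages
  expect_true(all(st$n_out <= st$n_in))
  # stage k input ids are stage k-1 survivors within each arm
  for (arm in unique(st$arm[st$arm != "both"])) {
    s <- st[st$arm == arm, ]
    for (k in 2:nrow(s)) {
      expect_true(all(s$survivors[[k]] %in% s$survivors[[k - 1]]))
    }
    expect_true(all(rep$final_hits %in% s$survivors[[nrow(s)]]))
  }
  expect_identical(st$stage[nrow(st)], "intersection")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_identical(glance(rep)$n_hits, length(w$actives))
})

test_that("arm intersection is symmetric and filter order is immaterial", {
  w <- make_screen_world(n_act = 5, n_dec = 6, seed = 41)
  r12 <- run_cascade(w$db, w$models, w$fit, w$thr)
  r21 <- run_cascade(w$db, w$models[2:1], w$fit[2:1], w$thr)
  expect_setequal(r12$final_hits, r21$final_hits)
  swapped <- run_cascade(w$db, w$models, w$fit, w$thr,
                         stage_order = c("admet", "lipinski", "docking"))
  expect_setequal(r12$final_hits, swapped$final_hits)
})

test_that("degenerate cascades behave: no hits, single arm, empty input", {
  w <- make_screen_world(n_act = 3, n_dec = 3, seed = 51)
  ceiling_fit <- sum(w$models[[1]]$constraints$weight)
  rep <- run_cascade(w$db, w$models[1], ceiling_fit + 1, w$thr)
  expect_identical(rep$final_hits, character(0))
  expect_true(all(rep$stages$n_out[-1] == 0))
  expect_false(rep$intersection)
  expect_error(run_cascade(w$db[0, ], w$models[1], 8, w$thr), "empty")
})
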