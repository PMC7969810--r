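# Toy molecules and independent oracles shared across the suite.

toy_benzene <- function(order = 4L) {
  ord <- if (order == 4L) rep(4L, 6) else rep(c(2L, 1L), 3)
  mol_record(
    "benzene",
    atoms = data.frame(elem = rep("C", 6)),
    bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = ord),
    conformers = list(cbind(1.4 * cos(0:5 * pi / 3), 1.4 * sin(0:5 * pi / 3), 0))
  )
}

toy_methanol <- function() {
  mol_record(
    "methanol",
    atoms = data.frame(elem = c("C", "O", "H")),
    bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1),
    conformers = list(rbind(c(0, 0, 0), c(1.43, 0, 0), c(1.85, 0.9, 0)))
  )
}

toy_ethanol <- function() {
  mol_record(
    "ethanol",
    atoms = data.frame(elem = c("C", "C", "O")),
    bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1),
    conformers = list(rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.1, 1.3, 0)))
  )
}

toy_hexane <- function() {
  xyz <- cbind(1.3 * (0:5), rep(c(0, 0.8), 3), 0)
  mol_record(
    "hexane",
    atoms = data.frame(elem = rep("C", 6)),
    bonds = data.frame(a1 = 1:5, a2 = 2:6, order = 1),
    conformers = list(xyz)
  )
}

toy_acetamide <- function() {
  # CH3-C(=O)-NH2
  mol_record(
    "acetamide",
    atoms = data.frame(elem = c("C", "C", "O", "N")),
    bonds = data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1, 2, 1)),
    conformers = list(rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.05, 0),
                            c(2.2, -1.2, 0)))
  )
}

toy_alkane <- function(n = 40L) {
  mol_record(
    sprintf("C%d_alkane", n),
    atoms = data.frame(elem = rep("C", n)),
    bonds = data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1),
    conformers = list(cbind(1.4 * seq_len(n), rep(c(0, 0.7), length.out = n), 0))
  )
}

# bare feature tibble for direct fit_value checks (no perception involved)
make_features <- function(kinds, centers) {
  centers <- matrix(centers, ncol = 3, byrow = TRUE)
  tibble::tibble(kind = kinds, x = centers[, 1], y = centers[, 2],
                 z = centers[, 3], dx = NA_real_, dy = NA_real_, dz = NA_real_,
                 atoms = lapply(seq_along(kinds), identity))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_features <- function(features, R, t) {
  xyz <- as.matrix(features[, c("x", "y", "z")]) %*% t(R)
  features$x <- xyz[, 1] + t[1]
  features$y <- xyz[, 2] + t[2]
  features$z <- xyz[, 3] + t[3]
  features
}

# --- independent brute-force fit oracle -----------------------------------
# Enumerates every injective kind-compatible correspondence (no pruning,
# own recursion) and superposes with bio3d::fit.xyz, an implementation
# unrelated to the package's Kabsch.  Valid for equal-weight models, where
# the least-squares pose is also the score-optimal pose.
oracle_fit <- function(features, model) {
  cons <- model$constraints
  nc <- nrow(cons); nf <- nrow(features)
  best <- 0
  assignments <- list()
  recurse <- function(k, cur, omitted) {
    if (k > nc) {
      if (any(!is.na(cur))) assignments[[length(assignments) + 1L]] <<- cur
      return(invisible())
    }
    if (omitted < model$max_omitted) recurse(k + 1L, c(cur, NA_integer_),
                                             omitted + 1L)
    for (f in seq_len(nf)) {
      if (features$kind[f] == cons$kind[k] && !(f %in% cur)) {
        recurse(k + 1L, c(cur, f), omitted)
      }
    }
  }
  recurse(1L, integer(0), 0L)
  for (corr in assignments) {
    mapped <- which(!is.na(corr))
    ref <- as.matrix(cons[mapped, c("x", "y", "z")])
    mov <- as.matrix(features[corr[mapped], c("x", "y", "z")])
    if (length(mapped) == 1) {
      fitted <- ref  # translation alone centres a single point exactly
    } else {
      fitted_v <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                                 mobile = as.numeric(t(mov)),
                                 fixed.inds = seq_len(3 * nrow(ref)),
                                 mobile.inds = seq_len(3 * nrow(mov)))
      fitted <- matrix(fitted_v, ncol = 3, byrow = TRUE)
    }
    d <- sqrt(rowSums((fitted - ref)^2))
    if (any(d > cons$tolerance[mapped] + 1e-9)) next
    fit <- sum(cons$weight[mapped] * pmax(0, 1 - (d / cons$tolerance[mapped])^2))
    if (fit > best) best <- fit
  }
  best
}

# planted two-molecule pair sharing a 3-4-5 triangle of distinct kinds plus
# an unshared extra feature each
planted_triangle_pair <- function() {
  tri <- list(
    sphere_constraint("HBA", c(0, 0, 0)),
    sphere_constraint("HY", c(3, 0, 0)),
    sphere_constraint("AR", c(0, 4, 0))
  )
  m1 <- pharmacophore_model("m1", c(tri, list(sphere_constraint("HY", c(12, 12, 0)))),
                            max_omitted = 1L)
  m2 <- pharmacophore_model("m2", c(tri, list(sphere_constraint("AR", c(-15, 4, 8)))),
                            max_omitted = 1L)
  s1 <- sim_spec(n_actives = 1, n_decoys = 0, model = m1, jitter = 0, seed = 11)
  s2 <- sim_spec(n_actives = 1, n_decoys = 0, model = m2, jitter = 0, seed = 12)
  a <- generate_feature_molecules(s1)$mol[[1]]; a$id <- "tri_a"
  b <- generate_feature_molecules(s2)$mol[[1]]; b$id <- "tri_b"
  molecule_table(list(a, b))
}

# two-arm screening world with planted survivors; filter thresholds are
# targeted at the generated chemistry's measured property levels
make_screen_world <- function(n_act = 8, n_dec = 12, seed = 31) {
  model_a <- planted_model_default()
  model_b <- pharmacophore_model("arm_b", model_a$constraints[1:4, ],
                                 max_omitted = 0L)
  actives <- generate_feature_molecules(
    sim_spec(n_act, 0, model_a, jitter = 0.15, seed = seed))
  decoys <- generate_feature_molecules(
    sim_spec(0, n_dec, model_a, separation = 4, seed = seed + 1))
  db <- dplyr::bind_rows(actives, decoys)
  pr <- molecular_properties(db)
  adm <- admet_filter(db, properties = pr)
  thr <- filter_thresholds(
    rotatable_max = max(pr$rotatable),
    admet_cutoffs = list(solubility = adm$solubility_level[1],
                         absorption = adm$absorption_level[1],
                         bbb = adm$bbb_level[1]))
  list(db = db, models = list(model_a, model_b), fit = c(8, 6), thr = thr,
       actives = actives$id)
}

# small quantitative training world reused by several tests: graded jitter
# spreads the fit values so activities span several log units, the way a
# real training set mixes strong and weak binders
quant_training_world <- function(n = 10L, noise = 0.2, seed = 21L,
                                 jitters = c(0.1, 0.7, 1.3)) {
  model <- pharmacophore_model("quadpl", list(
    sphere_constraint("HBA", c(0, 0, 0), weight = 2.4),
    sphere_constraint("HY", c(4.5, 0, 0), weight = 2.4),
    sphere_constraint("HY", c(0, 5.5, 0), weight = 2.4),
    sphere_constraint("AR", c(-3, -3, 2), weight = 2.4)
  ), max_omitted = 0L)
  counts <- diff(round(seq(0, n, length.out = length(jitters) + 1)))
  recs <- list()
  for (g in seq_along(jitters)) {
    if (counts[g] == 0) next
    batch <- generate_feature_molecules(
      sim_spec(n_actives = counts[g], n_decoys = 0, model = model,
               jitter = jitters[g], seed = seed + g))
    for (m in batch$mol) {
      m$id <- sprintf("T%d_%s", g, m$id)
      recs[[length(recs) + 1L]] <- m
    }
  }
  mols <- molecule_table(recs)
  acts <- generate_activities(mols, model, true_C = 8.3,
                              noise_sigma_log10 = noise, seed = seed + 99L)
  list(model = model, mols = mols,
       activities = acts[, c("id", "ic50")], fits = acts)
}
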