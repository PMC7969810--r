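#' Specification for synthetic screening data
#'
#' The generator emulates the study conditions the rest of the package is
#' exercised under: a training/decoy chemistry in which a known feature
#' arrangement (the planted model) drives activity through the log-linear
#' law `IC50 = 10^(C - fit + eps)`, and decoy compounds carry the same
#' chemistry with perturbed geometry.  Defaults mirror a desk-scale version
#' of a kinase-inhibitor campaign: activities spanning several log units
#' around a calibration constant of 8.3 log10-uM, lognormal activity noise
#' of 0.3 log units, and a 25-active / 300-decoy validation database with a
#' 3 Angstrom decoy perturbation against 1.6 Angstrom tolerance spheres.
#'
#' @param n_actives,n_decoys Compound counts (>= 0).
#' @param model Planted [pharmacophore_model()]; defaults to a 5-point
#'   arrangement (1 HBA + 4 HY at weight 2.4) echoing a quantitative
#'   kinase-inhibitor model with a fit ceiling of 12.
#' @param true_C Calibration constant of the activity law (log10 uM).
#' @param noise_sigma_log10 Lognormal activity noise (log10 units, >= 0).
#' @param jitter Coordinate jitter applied to active feature centers
#'   (Angstrom standard deviation).
#' @param separation Perturbation magnitude applied to decoy feature centers
#'   (Angstrom).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_actives = 25L, n_decoys = 300L,
                     model = planted_model_default(),
                     true_C = 8.3, noise_sigma_log10 = 0.3,
                     jitter = 0.25, separation = 3.0, seed = 1L) {
  stopifnot(n_actives >= 0, n_decoys >= 0, noise_sigma_log10 >= 0,
            jitter >= 0, separation >= 0)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys), model = model,
                 true_C = true_C, noise_sigma_log10 = noise_sigma_log10,
                 jitter = jitter, separation = separation,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Default planted pharmacophore for simulations
#'
#' One hydrogen-bond acceptor and four hydrophobes at weight 2.4 and
#' tolerance 1.6 Angstrom: a 5-feature quantitative-style arrangement with
#' fit ceiling 12, on inter-feature distances of 4-8 Angstrom.
#'
#' @param weight,tolerance Constraint parameters.
#' @return A [pharmacophore_model()].
#' @export
planted_model_default <- function(weight = 2.4, tolerance = 1.6) {
  pharmacophore_model("planted", list(
    sphere_constraint("HBA", c(0, 0, 0), tolerance, weight),
    sphere_constraint("HY", c(4.2, 0, 0), tolerance, weight),
    sphere_constraint("HY", c(0, 4.8, 0), tolerance, weight),
    sphere_constraint("HY", c(-3.6, -2.4, 1.8), tolerance, weight),
    sphere_constraint("AR", c(1.8, -4.2, -2.2), tolerance, weight)
  ), max_omitted = 0L)
}

# Build one feature group at a planted center.  Groups use chemistry the
# perception rules type unambiguously: a carbonyl for HBA, a hydroxyl for
# HBD (which also accepts), a three-carbon chain for HY, benzene for AR.
# Returns atoms/bonds/coords plus the index of the anchor atom linkers
# attach to.
.feature_group <- function(kind, center, outward, phase = 0) {
  u <- .unit(outward); if (anyNA(u)) u <- c(0, 0, 1)
  # orthonormal frame around u
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(pracma_cross(u, ref)); e2 <- .unit(pracma_cross(u, e1))
  if (kind == "HBA") {
    xyz <- rbind(center + 1.22 * u, center)           # C=O, O at center
    list(elem = c("C", "O"), xyz = xyz,
         bonds = data.frame(a1 = 1, a2 = 2, order = 2), anchor = 1L)
  } else if (kind == "HBD") {
    xyz <- rbind(center + 1.43 * u, center)           # C-O(H), O at center
    list(elem = c("C", "O"), xyz = xyz,
         bonds = data.frame(a1 = 1, a2 = 2, order = 1), anchor = 1L)
  } else if (kind == "HY") {
    r <- 1.5 / sqrt(3)                                # C3 with centroid at center
    ang <- phase + c(0, 2, 4) * pi / 3
    xyz <- t(vapply(ang, function(a) {
      center + r * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
    list(elem = c("C", "C", "C"), xyz = xyz,
         bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1), anchor = 1L)
  } else {                                            # AR: benzene hexagon
    ang <- phase + (0:5) * pi / 3
    xyz <- t(vapply(ang, function(a) {
      center + 1.40 * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
    list(elem = rep("C", 6), xyz = xyz,
         bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4), anchor = 1L)
  }
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Assemble a connected molecule carrying groups at the given centers.
# Consecutive anchors are linked through CF2 carbons at the midpoints;
# fluorinated linker carbons are polar by the hydrophobe rule, so linking
# neither merges nor shifts planted hydrophobic components.
.planted_molecule <- function(id, kinds, centers, phases = NULL, ic50 = NA_real_) {
  overall <- colMeans(centers)
  elem <- character(0); bonds <- NULL
  xyz <- matrix(0, 0, 3); anchors <- integer(0)
  for (gi in seq_along(kinds)) {
    outward <- centers[gi, ] - overall
    grp <- .feature_group(kinds[gi], centers[gi, ], outward,
                          phase = if (is.null(phases)) 0 else phases[gi])
    off <- length(elem)
    elem <- c(elem, grp$elem)
    xyz <- rbind(xyz, grp$xyz)
    gb <- grp$bonds
    gb$a1 <- gb$a1 + off; gb$a2 <- gb$a2 + off
    bonds <- rbind(bonds, gb)
    anchors <- c(anchors, grp$anchor + off)
  }
  if (length(anchors) > 1) {
    for (gi in seq_len(length(anchors) - 1)) {
      a <- anchors[gi]; b <- anchors[gi + 1]
      mid <- (xyz[a, ] + xyz[b, ]) / 2
      axis <- .unit(xyz[b, ] - xyz[a, ]); if (anyNA(axis)) axis <- c(1, 0, 0)
      perp <- .unit(pracma_cross(axis, if (abs(axis[3]) < 0.9) c(0, 0, 1)
                                       else c(1, 0, 0)))
      ci <- length(elem) + 1L
      elem <- c(elem, "C", "F", "F")
      xyz <- rbind(xyz, mid, mid + 1.35 * perp, mid - 1.35 * perp)
      bonds <- rbind(bonds,
                     data.frame(a1 = c(a, ci, ci, ci), a2 = c(ci, b, ci + 1L, ci + 2L),
                                order = 1))
    }
  }
  mol_record(id, atoms = data.frame(elem = elem, charge = 0),
             bonds = bonds, conformers = list(unname(xyz)), ic50 = ic50)
}

#' Generate molecules carrying planted pharmacophore geometry
#'
#' Actives realize the planted model's constraint arrangement as connected
#' small molecules whose perceived features reproduce the planted geometry
#' to within the requested jitter; decoys carry the same chemistry with
#' feature centers perturbed by `separation` Angstrom.  Every molecule
#' receives a random rigid reorientation, so nothing aligns with the model
#' frame by construction.  Fully deterministic per seed.
#'
#' @param spec A [sim_spec()].
#' @return Molecule table with ids `ACT...`/`DEC...` and attribute
#'   `active_ids`.
#' @export
generate_feature_molecules <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  cons <- spec$model$constraints
  centers0 <- as.matrix(cons[, c("x", "y", "z")])
  if (nrow(centers0) >= 3) {
    dd <- as.matrix(stats::dist(centers0))
    for (i in seq_len(nrow(dd))) {
      for (j in seq_len(nrow(dd))) {
        for (k in seq_len(nrow(dd))) {
          if (i != j && j != k && i != k &&
              dd[i, k] > dd[i, j] + dd[j, k] + 1e-9) {
            stop("planted geometry violates the triangle inequality")
          }
        }
      }
    }
  }
  withr::with_seed(spec$seed, {
    recs <- list()
    mk <- function(id, perturb, ic50 = NA_real_) {
      centers <- centers0 + matrix(perturb, nrow(centers0), 3)
      phases <- stats::runif(nrow(centers), 0, 2 * pi)
      m <- .planted_molecule(id, cons$kind, centers, phases, ic50)
      # random rigid reorientation
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      R <- .quat_to_rot(q)
      transform_molecule(m, R, stats::runif(3, -10, 10))
    }
    for (i in seq_len(spec$n_actives)) {
      jit <- stats::rnorm(3 * nrow(centers0), 0, spec$jitter)
      recs[[length(recs) + 1L]] <- mk(sprintf("ACT%04d", i), jit)
    }
    for (i in seq_len(spec$n_decoys)) {
      dirs <- matrix(stats::rnorm(3 * nrow(centers0)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      mag <- abs(stats::rnorm(nrow(centers0), spec$separation,
                              spec$separation / 4))
      recs[[length(recs) + 1L]] <- mk(sprintf("DEC%04d", i), dirs * mag)
    }
    tbl <- molecule_table(recs)
    attr(tbl, "active_ids") <- sprintf("ACT%04d", seq_len(spec$n_actives))
    tbl
  })
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate activities from the planted fit-to-IC50 law
#'
#' `IC50_i = 10^(true_C - fit_i + eps_i)` with `eps_i ~ N(0, sigma)` in
#' log10 units, fits taken against the planted model.  With zero noise,
#' [calibrate_constant()] recovers `true_C` exactly.
#'
#' @param mols Molecule table (with conformers).
#' @param model Planted [pharmacophore_model()].
#' @param true_C Calibration constant (log10 uM).
#' @param noise_sigma_log10 Noise standard deviation in log10 units.
#' @param seed Integer seed.
#' @param rules Feature perception rules.
#' @return Tibble with `id`, `fit`, `ic50`.
#' @export
generate_activities <- function(mols, model, true_C = 8.3,
                                noise_sigma_log10 = 0.3, seed = 1L,
                                rules = .default_rules()) {
  fits <- fit_molecules(mols, model, rules)
  eps <- withr::with_seed(as.integer(seed),
                          stats::rnorm(nrow(fits), 0, noise_sigma_log10))
  tibble::tibble(id = fits$id, fit = fits$fit,
                 ic50 = 10^(true_C - fits$fit + eps))
}

#' Generate an active/decoy validation database
#'
#' @param n_actives,n_decoys Counts.
#' @param model Planted model.
#' @param separation Decoy geometric perturbation in Angstrom.
#' @param seed Integer seed.
#' @param jitter Active-feature jitter (Angstrom).
#' @return List with `molecules` (molecule table) and `active_ids`.
#' @export
generate_decoy_database <- function(n_actives = 25L, n_decoys = 300L,
                                    model = planted_model_default(),
                                    separation = 3.0, seed = 1L,
                                    jitter = 0.25) {
  spec <- sim_spec(n_actives = n_actives, n_decoys = n_decoys, model = model,
                   separation = separation, jitter = jitter, seed = seed)
  mols <- generate_feature_molecules(spec)
  list(molecules = mols, active_ids = attr(mols, "active_ids"))
}
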