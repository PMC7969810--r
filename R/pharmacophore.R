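#' Sphere constraint of a pharmacophore model
#'
#' @param kind Feature kind: `"HBA"`, `"HBD"`, `"HY"`, or `"AR"`.
#' @param center Length-3 numeric, Angstrom.
#' @param tolerance Sphere radius in Angstrom (> 0); default 1.6, the
#'   conventional Catalyst location tolerance.
#' @param weight Nonnegative score weight; the fit ceiling of a model is the
#'   sum of its weights.
#' @return A one-row tibble describing the constraint.
#' @export
sphere_constraint <- function(kind, center, tolerance = 1.6, weight = 1) {
  kind <- match.arg(kind, c("HBA", "HBD", "HY", "AR"))
  stopifnot(length(center) == 3, is.finite(tolerance), tolerance > 0,
            is.finite(weight), weight >= 0)
  tibble::tibble(kind = kind, x = center[1], y = center[2], z = center[3],
                 tolerance = tolerance, weight = weight)
}

#' Pharmacophore model
#'
#' A named set of typed sphere constraints, an allowance for omitted
#' constraints during mapping, and an optional calibration constant `C`
#' (log10 micromolar) linking fit values to predicted IC50 via
#' `log10(IC50) = C - fit`.
#'
#' @param name Model name.
#' @param constraints List of [sphere_constraint()] rows (or a tibble of
#'   them); a usable model has at least 2.
#' @param max_omitted Maximum constraints that may be left unmapped
#'   (default 0, the quantitative-model convention; common-feature models
#'   typically use 1).
#' @param calibration_C Optional calibration constant.
#' @return Object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(name, constraints, max_omitted = 0L,
                                calibration_C = NULL) {
  if (is.data.frame(constraints)) {
    cons <- tibble::as_tibble(constraints)
  } else {
    cons <- dplyr::bind_rows(constraints)
  }
  stopifnot(all(c("kind", "x", "y", "z", "tolerance", "weight") %in% names(cons)))
  # a usable screening model carries >= 2 constraints; single-sphere models
  # are accepted for composition and closed-form checks
  if (nrow(cons) < 1) stop("a model needs at least 1 constraint")
  max_omitted <- as.integer(max_omitted)
  if (max_omitted < 0 || max_omitted >= nrow(cons)) {
    stop("max_omitted must be in [0, n_constraints - 1]")
  }
  if (!is.null(calibration_C)) calibration_C <- as.numeric(calibration_C)
  structure(list(name = name, constraints = cons, max_omitted = max_omitted,
                 calibration_C = calibration_C),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %s: %d constraints (%s), max_omitted %d%s\n",
              x$name, nrow(x$constraints),
              paste(x$constraints$kind, collapse = ","), x$max_omitted,
              if (!is.null(x$calibration_C))
                sprintf(", C = %.4f", x$calibration_C) else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pharmacophore_model <- function(x, ...) {
  dplyr::mutate(x$constraints, constraint = dplyr::row_number(), .before = 1)
}

.constraint_centers <- function(model) {
  as.matrix(model$constraints[, c("x", "y", "z")])
}

.feature_centers <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}

#' Enumerate candidate constraint-to-feature correspondences
#'
#' Yields every injective, kind-compatible assignment of model constraints to
#' perceived features with at most `max_omitted` omissions.  With
#' `prune = TRUE` (default) partial assignments are discarded as soon as a
#' pair of assigned features disagrees with the corresponding constraint
#' distance by more than the sum of the two tolerances.
#'
#' @param features Feature tibble from [perceive_features()].
#' @param model A [pharmacophore_model()].
#' @param prune Apply pairwise-distance compatibility pruning.
#' @return List of integer vectors of length `n_constraints`; entry `k` is
#'   the feature row assigned to constraint `k`, or `NA` if omitted.
#' @export
enumerate_correspondences <- function(features, model, prune = TRUE) {
  cons <- model$constraints
  nc <- nrow(cons); nf <- nrow(features)
  if (nf == 0) return(list())
  cc <- .constraint_centers(model)
  fc <- .feature_centers(features)
  dcon <- as.matrix(stats::dist(cc))
  dfeat <- as.matrix(stats::dist(fc))
  compat <- lapply(seq_len(nc), function(k) which(features$kind == cons$kind[k]))

  out <- list()
  assign_next <- function(k, cur, omitted) {
    if (k > nc) {
      if (any(!is.na(cur))) out[[length(out) + 1L]] <<- cur
      return(invisible())
    }
    if (omitted < model$max_omitted) {
      cur2 <- cur; cur2[k] <- NA_integer_
      assign_next(k + 1L, cur2, omitted + 1L)
    }
    for (f in compat[[k]]) {
      if (f %in% cur) next
      if (prune) {
        ok <- TRUE
        for (j in seq_len(k - 1L)) {
          if (!is.na(cur[j]) &&
              abs(dfeat[f, cur[j]] - dcon[k, j]) >
              cons$tolerance[k] + cons$tolerance[j]) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      cur2 <- cur; cur2[k] <- f
      assign_next(k + 1L, cur2, omitted)
    }
  }
  assign_next(1L, rep(NA_integer_, nc), 0L)
  out
}

# zero-padded so string order equals numeric lexicographic order; omissions
# sort after any feature index
.lex_key <- function(corr) {
  paste(sprintf("%09d", ifelse(is.na(corr), 999999999L, corr)), collapse = ",")
}

#' Pharmacophore fit value of a feature set against a model
#'
#' The Catalyst-style fit: for each mapped constraint with displacement `d`
#' and tolerance `t`, the partial score is `weight * max(0, 1 - (d/t)^2)`;
#' the fit is the sum of partials, maximized over all admissible
#' correspondences after least-squares rigid superposition of the mapped
#' feature centers onto the constraint centers (one refinement pass
#' re-weights the superposition by constraint weight).  A correspondence is
#' admissible only if every mapped displacement stays within its constraint
#' tolerance.  The fit is bounded by the sum of the model weights and is
#' invariant to rigid motion of the molecule.
#'
#' @inheritParams enumerate_correspondences
#' @param optimize Superpose the mapped feature centers onto the constraint
#'   centers before scoring (the default).  With `optimize = FALSE` the
#'   features are scored in their given pose, which is what a pre-aligned
#'   conformation or a closed-form displacement check calls for.
#' @return Object of class `fit_result`: list with `fit`, `correspondence`
#'   (constraint index -> feature row, NA = omitted), `displacements`,
#'   `transform`, `n_mapped`, `n_omitted`.
#' @export
fit_value <- function(features, model, optimize = TRUE) {
  stopifnot(inherits(model, "pharmacophore_model"))
  cons <- model$constraints
  empty <- structure(list(fit = 0, correspondence = rep(NA_integer_, nrow(cons)),
                          displacements = rep(NA_real_, nrow(cons)),
                          transform = NULL, n_mapped = 0L,
                          n_omitted = nrow(cons)), class = "fit_result")
  if (nrow(features) == 0) return(empty)
  cc <- .constraint_centers(model)
  fc <- .feature_centers(features)
  best <- empty; best_key <- NULL; found <- FALSE
  for (corr in enumerate_correspondences(features, model)) {
    mapped <- which(!is.na(corr))
    ref <- cc[mapped, , drop = FALSE]
    mov <- fc[corr[mapped], , drop = FALSE]
    if (optimize) {
      tf <- superpose(ref, mov)
      # one refinement pass weighted by constraint weight
      if (length(mapped) > 1 && stats::sd(cons$weight[mapped]) > 0) {
        tf <- superpose(ref, mov, weights = cons$weight[mapped])
      }
    } else {
      tf <- list(rotation = diag(3), translation = c(0, 0, 0), rmsd = NA_real_)
    }
    fitted <- apply_transform(mov, tf)
    d <- sqrt(rowSums((fitted - ref)^2))
    if (any(d > cons$tolerance[mapped] + 1e-9)) next
    partial <- cons$weight[mapped] * pmax(0, 1 - (d / cons$tolerance[mapped])^2)
    fit <- sum(partial)
    key <- .lex_key(corr)
    if (!found || fit > best$fit + 1e-12 ||
        (abs(fit - best$fit) <= 1e-12 && key < best_key)) {
      disp <- rep(NA_real_, nrow(cons)); disp[mapped] <- d
      best <- structure(list(fit = fit, correspondence = corr,
                             displacements = disp, transform = tf,
                             n_mapped = length(mapped),
                             n_omitted = nrow(cons) - length(mapped)),
                        class = "fit_result")
      best_key <- key; found <- TRUE
    }
  }
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> fit %.4f (%d mapped, %d omitted)\n",
              x$fit, x$n_mapped, x$n_omitted))
  invisible(x)
}

#' Best fit over all conformers of a molecule
#'
#' @param mol A [mol_record()] with at least one conformer.
#' @param model A [pharmacophore_model()].
#' @param rules Feature perception rules.
#' @return A `fit_result` with an added `conformer` element; ties between
#'   conformers resolve to the lowest index.
#' @export
best_fit_over_conformers <- function(mol, model, rules = .default_rules()) {
  if (length(mol$conformers) == 0) {
    stop("molecule '", mol$id, "' has no conformers")
  }
  best <- NULL
  for (ci in seq_along(mol$conformers)) {
    fr <- fit_value(perceive_features(mol, ci, rules), model)
    if (is.null(best) || fr$fit > best$fit + 1e-12) {
      fr$conformer <- ci
      best <- fr
    }
  }
  best
}

#' Fit every molecule in a table against a model
#'
#' @param mols A molecule table.
#' @inheritParams best_fit_over_conformers
#' @return Tibble with `id`, `fit`, `n_mapped`, `n_omitted`, `conformer`.
#' @export
fit_molecules <- function(mols, model, rules = .default_rules()) {
  purrr::map2_dfr(mols$id, mols$mol, function(id, m) {
    fr <- best_fit_over_conformers(m, model, rules)
    tibble::tibble(id = id, fit = fr$fit, n_mapped = fr$n_mapped,
                   n_omitted = fr$n_omitted, conformer = fr$conformer)
  })
}
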