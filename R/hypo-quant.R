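#' Calibrate the fit-to-activity constant
#'
#' The quantitative layer maps fit values to predicted IC50 through
#' `log10(IC50_pred) = C - fit`; `C` is estimated by least squares as the
#' mean of `fit_i + log10(IC50_i)` over the calibration pairs (log10
#' micromolar units).
#'
#' @param fits Numeric fit values.
#' @param activities Experimental IC50 values in micromolar (> 0).
#' @return The calibration constant `C`.
#' @export
calibrate_constant <- function(fits, activities) {
  if (length(fits) == 0 || length(fits) != length(activities)) {
    stop("fits and activities must be non-empty and of equal length")
  }
  if (any(!is.finite(activities)) || any(activities <= 0)) {
    stop("activities must be positive and finite")
  }
  mean(fits + log10(activities))
}

#' Predict IC50 from a fit value
#' @param fit Fit value(s).
#' @param calibration_C Calibration constant from [calibrate_constant()].
#' @return Predicted IC50 in micromolar: `10^(C - fit)`.
#' @export
predict_activity <- function(fit, calibration_C) {
  10^(calibration_C - fit)
}

#' Signed prediction error factor
#'
#' Fold-error between predicted and experimental IC50, signed by direction:
#' `+pred/exp` when the prediction is high (or exact), `-exp/pred` when low.
#' Its magnitude is always at least 1; a value of +1 is a perfect prediction.
#'
#' @param experimental,predicted Positive IC50 values (micromolar).
#'   Vectorized.
#' @return Signed error factor(s).
#' @export
error_factor <- function(experimental, predicted) {
  if (any(!is.finite(experimental)) || any(!is.finite(predicted)) ||
      any(experimental <= 0) || any(predicted <= 0)) {
    stop("error_factor needs positive finite IC50 values")
  }
  ifelse(predicted >= experimental, predicted / experimental,
         -experimental / predicted)
}

#' Classify an IC50 on the three-level activity scale
#'
#' Highly active (`"+++"`) at IC50 <= 0.1 uM, least active (`"+"`) at
#' IC50 >= 3 uM, moderately active (`"++"`) in between.  Both boundaries are
#' inclusive toward the outer classes, so the labels partition (0, Inf).
#'
#' @param ic50 Positive IC50 value(s) in micromolar.
#' @return Character vector of `"+++"`, `"++"`, `"+"`.
#' @export
activity_scale <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("activity_scale needs positive finite IC50 values")
  }
  ifelse(ic50 <= 0.1, "+++", ifelse(ic50 >= 3, "+", "++"))
}

#' Assess predicted against experimental activities
#'
#' Computes the Pearson correlation of log10 experimental vs log10 predicted
#' IC50 (and its square, the log-log regression R-squared), per-compound
#' error factors, and agreement of the three-level activity scales.
#'
#' @param data Data frame with experimental and predicted IC50 columns
#'   (micromolar).
#' @param experimental,predicted Column names (tidy-eval) holding the two
#'   IC50 sets; defaults `experimental` and `predicted`.
#' @return Object of class `pharm_assessment` with [tidy()] (per-compound
#'   table), [glance()] (one-row summary) and [ggplot2::autoplot()] methods.
#' @export
assess_predictions <- function(data, experimental = "experimental",
                               predicted = "predicted") {
  exp_v <- data[[experimental]]
  pred_v <- data[[predicted]]
  if (is.null(exp_v) || is.null(pred_v)) {
    stop("data must contain columns '", experimental, "' and '", predicted, "'")
  }
  n <- length(exp_v)
  if (n < 3) stop("need at least 3 prediction pairs")
  if (any(exp_v <= 0) || any(pred_v <= 0)) stop("IC50 values must be positive")
  r <- stats::cor(log10(exp_v), log10(pred_v))
  preds <- tibble::tibble(
    id = if ("id" %in% names(data)) as.character(data$id)
         else as.character(seq_len(n)),
    experimental = exp_v,
    predicted = pred_v,
    error_factor = error_factor(exp_v, pred_v),
    experimental_scale = activity_scale(exp_v),
    predicted_scale = activity_scale(pred_v)
  )
  structure(list(
    n = n,
    pearson_r_log = r,
    r_squared_log = r^2,
    scale_agreement = sum(preds$experimental_scale == preds$predicted_scale),
    predictions = preds
  ), class = "pharm_assessment")
}

#' @export
print.pharm_assessment <- function(x, ...) {
  cat(sprintf(paste0("<pharm_assessment> n = %d, log-log Pearson r = %.3f ",
                     "(r^2 = %.3f), scale agreement %d/%d\n"),
              x$n, x$pearson_r_log, x$r_squared_log, x$scale_agreement, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pharm_assessment <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.pharm_assessment <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r_log = x$pearson_r_log,
                 r_squared_log = x$r_squared_log,
                 scale_agreement = x$scale_agreement,
                 scale_agreement_rate = x$scale_agreement / x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pharm_assessment <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$experimental),
                                   y = log10(.data$predicted))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$experimental_scale)) +
    ggplot2::labs(x = "log10 experimental IC50 (uM)",
                  y = "log10 predicted IC50 (uM)", colour = "scale",
                  title = sprintf("n = %d, r = %.3f, r^2 = %.3f", object$n,
                                  object$pearson_r_log, object$r_squared_log)) +
    ggplot2::theme_minimal()
}

#' Configuration for quantitative model construction
#'
#' @param min_features,max_features Candidate constraint-set sizes drawn from
#'   the reference compounds' feature arrangements.
#' @param tolerance,weight Sphere tolerance (Angstrom) and score weight given
#'   to every constraint of a candidate.  The default weight of 2.4 puts the
#'   fit ceiling of a 5-feature model near 12, the scale on which published
#'   quantitative models operate.
#' @param max_candidates Cap on evaluated candidates (deterministic
#'   truncation in enumeration order).
#' @param rules Feature perception rules.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(min_features = 4L, max_features = 6L,
                         tolerance = 1.6, weight = 2.4,
                         max_candidates = 500L, rules = .default_rules()) {
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 tolerance = tolerance, weight = weight,
                 max_candidates = as.integer(max_candidates),
                 rules = rules), class = "quant_config")
}

# Candidate constraint sets drawn from the feature arrangements of the two
# most active training compounds: every subset of min_features..max_features
# features, realized at the reference geometry.  Deterministic enumeration
# order; truncated at config$max_candidates.
.quant_candidates <- function(data, config) {
  refs <- utils::head(dplyr::arrange(data, .data$ic50), 2)
  candidates <- list()
  for (ri in seq_len(nrow(refs))) {
    feats <- perceive_features(refs$mol[[ri]], 1L, config$rules)
    nf <- nrow(feats)
    if (nf < 2) next
    sizes <- seq(min(config$min_features, nf), min(config$max_features, nf))
    sizes <- sizes[sizes >= 2]
    for (sz in sizes) {
      for (subset in asplit(utils::combn(nf, sz), 2)) {
        if (length(candidates) >= config$max_candidates) return(candidates)
        cons <- dplyr::mutate(feats[subset, c("kind", "x", "y", "z")],
                              tolerance = config$tolerance,
                              weight = config$weight)
        candidates[[length(candidates) + 1L]] <- list(
          ref = refs$id[ri], size = sz,
          model = pharmacophore_model(
            sprintf("cand_%s_%d", refs$id[ri], length(candidates) + 1L),
            cons, max_omitted = 0L))
      }
    }
  }
  candidates
}

#' Construct a quantitative pharmacophore model from training data
#'
#' Candidate constraint sets are generated from the perceived feature
#' arrangements of the two most active training compounds (subsets of
#' `min_features` to `max_features` features, realized as sphere constraints
#' at the reference geometry).  Each candidate is scored by the Pearson
#' correlation between training-set fit values and -log10(IC50); the best
#' scoring candidate is returned with its calibration constant fitted on the
#' full training set.  The complete candidate evaluation log is attached as
#' attribute `evaluation_log`.
#'
#' @param mols A molecule table of training compounds (with conformers).
#' @param activities Tibble with `id` and `ic50` columns (micromolar), one
#'   row per training compound.
#' @param config A [quant_config()].
#' @return A [pharmacophore_model()] with `calibration_C` set.
#' @export
construct_quantitative_model <- function(mols, activities, config = quant_config()) {
  data <- dplyr::inner_join(mols, activities, by = "id")
  if (nrow(data) < 8) stop("need at least 8 training compounds with activities")
  span <- diff(range(log10(data$ic50)))
  if (span < 1) stop("activity span below 1 log unit: unlearnable training set")
  if (span < 3) warning("training activity span below 3 log units; ",
                        "calibration may be unstable")

  candidates <- .quant_candidates(data, config)
  if (length(candidates) == 0) stop("reference compounds yielded no features")

  neg_log_ic50 <- -log10(data$ic50)
  log <- purrr::map_dfr(seq_along(candidates), function(ci) {
    cand <- candidates[[ci]]
    fits <- fit_molecules(data, cand$model, config$rules)$fit
    score <- if (stats::sd(fits) > 0) stats::cor(fits, neg_log_ic50) else -Inf
    tibble::tibble(candidate = ci, reference = cand$ref, size = cand$size,
                   kinds = paste(cand$model$constraints$kind, collapse = ","),
                   score = score)
  })
  best_i <- which.max(log$score)
  best <- candidates[[best_i]]$model
  fits <- fit_molecules(data, best, config$rules)$fit
  best$calibration_C <- calibrate_constant(fits, data$ic50)
  best$name <- "hypogen_quantitative"
  attr(best, "evaluation_log") <- log
  attr(best, "training_score") <- log$score[best_i]
  best
}
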