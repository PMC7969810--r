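#' Decoy-set retrieval statistics
#'
#' Given a screening database of `D` compounds containing `A` known actives,
#' from which a model retrieves `Ht` hits of which `Ha` are active, computes
#' the standard retrieval metrics:
#'
#' * percent yield of actives: `100 * Ha / Ht`
#' * percent ratio of actives: `100 * Ha / A`
#' * enrichment factor: `EF = (Ha * D) / (Ht * A)`
#' * Guner-Henry goodness-of-fit:
#'   `GF = (Ha / (4 * Ht * A)) * (3 * A + Ht) * (1 - (Ht - Ha) / (D - A))`
#' * false negatives `A - Ha` and false positives `Ht - Ha`
#'
#' Values are kept at full precision; round only in reports.  With `Ht = 0`
#' the yield, EF and GF are undefined and returned as `NA`.
#'
#' @param D Database size.
#' @param A Actives in the database (`0 < A < D`).
#' @param Ht Hits retrieved (`0 <= Ht <= D`).
#' @param Ha Active hits (`0 <= Ha <= min(Ht, A)`).
#' @return A one-row tibble of class `decoy_stats`.
#' @examples
#' decoy_statistics(325, 25, 26, 21)
#' @export
decoy_statistics <- function(D, A, Ht, Ha) {
  vals <- c(D = D, A = A, Ht = Ht, Ha = Ha)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be nonnegative integers")
  }
  if (A <= 0 || A >= D) stop("need 0 < A < D")
  if (Ht > D) stop("Ht cannot exceed D")
  if (Ha > min(Ht, A)) stop("Ha cannot exceed min(Ht, A)")
  if (Ht - Ha > D - A) {
    stop("inconsistent counts: the hit list holds more inactives (Ht - Ha) ",
         "than the database contains (D - A)")
  }
  if (Ht > 0) {
    yield <- 100 * Ha / Ht
    ef <- (Ha * D) / (Ht * A)
    gf <- (Ha / (4 * Ht * A)) * (3 * A + Ht) * (1 - (Ht - Ha) / (D - A))
  } else {
    yield <- NA_real_; ef <- NA_real_; gf <- NA_real_
  }
  out <- tibble::tibble(
    D = as.integer(D), A = as.integer(A), Ht = as.integer(Ht),
    Ha = as.integer(Ha),
    yield_pct = yield, ratio_pct = 100 * Ha / A,
    EF = ef, GF = gf,
    false_neg = as.integer(A - Ha), false_pos = as.integer(Ht - Ha)
  )
  class(out) <- c("decoy_stats", class(out))
  out
}

#' @exportS3Method generics::glance
glance.decoy_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Screen a database against a model and tabulate decoy statistics
#'
#' @param mols A molecule table (the decoy database).
#' @param active_ids Identifiers of the known actives in `mols`.
#' @param model A [pharmacophore_model()].
#' @param fit_threshold Compounds with fit strictly greater than this value
#'   count as hits.
#' @param rules Feature perception rules.
#' @return A `decoy_stats` row with attribute `hits` (the hit id vector).
#' @export
decoy_screen_statistics <- function(mols, active_ids, model, fit_threshold,
                                    rules = .default_rules()) {
  fits <- fit_molecules(mols, model, rules)
  hits <- fits$id[fits$fit > fit_threshold]
  st <- decoy_statistics(nrow(mols), length(intersect(active_ids, mols$id)),
                         length(hits), length(intersect(hits, active_ids)))
  attr(st, "hits") <- hits
  st
}

#' Number of permutations prescribed by the Fischer randomization design
#'
#' At confidence level `CL` (percent), the design calls for
#' `100 / (100 - CL) - 1` random label permutations, so that the true model
#' ranking first among `100 / (100 - CL)` scores achieves the stated
#' confidence.  Only levels for which that count is integral are valid
#' (90, 95, 98, 99, ...).
#'
#' @param confidence_pct Confidence level in percent, strictly between 0
#'   and 100.
#' @return Integer permutation count (19 at the conventional 95 percent).
#' @export
fischer_permutation_count <- function(confidence_pct) {
  if (!is.finite(confidence_pct) || confidence_pct <= 0 || confidence_pct >= 100) {
    stop("confidence_pct must be strictly between 0 and 100")
  }
  ratio <- 100 / (100 - confidence_pct)
  if (abs(ratio - round(ratio)) > 1e-9) {
    lower <- 100 * (1 - 1 / floor(ratio))
    upper <- 100 * (1 - 1 / ceiling(ratio))
    stop(sprintf(paste0("confidence level %.6g%% does not yield an integral ",
                        "permutation count; nearest valid levels are %.6g%% ",
                        "and %.6g%%"), confidence_pct, lower, upper))
  }
  as.integer(round(ratio)) - 1L
}

#' Fischer randomization test
#'
#' Rebuilds (or rescores) the model after randomly permuting the activity
#' labels and asks whether the true training data scores strictly better
#' than every permuted replicate.  The scoring statistic is the builder's
#' training score, conventionally the Pearson correlation between fit values
#' and -log10(IC50); significance at confidence level `CL` requires rank 1
#' among `1 + 100/(100-CL) - 1` scores, with ties counting against
#' significance.
#'
#' @param data Tibble holding the training records; must contain an `ic50`
#'   column (micromolar).
#' @param builder Function `function(data) -> numeric score` that rebuilds
#'   or rescores the model on (possibly permuted) training data.  Must be
#'   deterministic given its input.  See [fit_correlation_builder()].
#' @param confidence_pct Confidence level (default 95, giving 19
#'   permutations).
#' @param seed Integer seed controlling the label shuffles.
#' @return Object of class `fischer_result` with `true_score`,
#'   `permuted_scores`, `rank`, `significant`, plus [tidy()] and [glance()]
#'   methods.
#' @export
fischer_randomization <- function(data, builder, confidence_pct = 95, seed = 1L) {
  stopifnot(is.function(builder), "ic50" %in% names(data))
  n_perm <- fischer_permutation_count(confidence_pct)
  true_score <- builder(data)
  permuted <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(k) {
      pdata <- data
      pdata$ic50 <- sample(pdata$ic50)
      builder(pdata)
    }, numeric(1))
  })
  rank <- 1L + sum(permuted >= true_score)
  structure(list(
    confidence_pct = confidence_pct,
    n_permutations = n_perm,
    true_score = true_score,
    permuted_scores = permuted,
    rank = rank,
    significant = all(permuted < true_score)
  ), class = "fischer_result")
}

#' @export
print.fischer_result <- function(x, ...) {
  cat(sprintf(paste0("<fischer_result> CL %.4g%%: true score %.4f, rank %d of %d",
                     " -> %ssignificant\n"),
              x$confidence_pct, x$true_score, x$rank, x$n_permutations + 1L,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fischer_result <- function(x, ...) {
  tibble::tibble(
    replicate = c(0L, seq_len(x$n_permutations)),
    kind = c("true", rep("permuted", x$n_permutations)),
    score = c(x$true_score, x$permuted_scores)
  )
}

#' @exportS3Method generics::glance
glance.fischer_result <- function(x, ...) {
  tibble::tibble(confidence_pct = x$confidence_pct,
                 n_permutations = x$n_permutations,
                 true_score = x$true_score, rank = x$rank,
                 significant = x$significant)
}

#' @exportS3Method ggplot2::autoplot
autoplot.fischer_result <- function(object, ...) {
  df <- tibble::tibble(score = object$permuted_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$true_score, colour = "red") +
    ggplot2::labs(x = "training score", y = "permuted replicates",
                  title = sprintf("Fischer randomization: rank %d of %d",
                                  object$rank, object$n_permutations + 1L)) +
    ggplot2::theme_minimal()
}

#' Builder scoring a fixed fit table against (permuted) activities
#'
#' Fit values are a property of the molecules and the model only, so under
#' activity permutation they never change; precomputing them makes Fischer
#' randomization cheap.  The returned builder joins the stored fits to the
#' incoming activity table by `id` and returns the Pearson correlation of
#' fit with -log10(IC50).
#'
#' @param fits Tibble with `id` and `fit` columns (e.g. from
#'   [fit_molecules()]), or a matrix of candidate fits (candidates in rows,
#'   columns named by compound id) in which case the builder returns the
#'   best candidate score, mirroring model re-selection per permutation.
#' @return A function `function(data) -> numeric`.
#' @export
fit_correlation_builder <- function(fits) {
  if (is.matrix(fits)) {
    ids <- colnames(fits)
    return(function(data) {
      y <- -log10(data$ic50[match(ids, data$id)])
      if (stats::sd(y) == 0) return(-Inf)
      scores <- apply(fits, 1, function(f) {
        if (stats::sd(f) > 0) stats::cor(f, y) else -Inf
      })
      max(scores)
    })
  }
  stopifnot(all(c("id", "fit") %in% names(fits)))
  function(data) {
    y <- -log10(data$ic50[match(fits$id, data$id)])
    if (stats::sd(fits$fit) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(fits$fit, y)
  }
}

#' Candidate-fit matrix for model re-selection under permutation
#'
#' Runs the candidate generation of [construct_quantitative_model()] once
#' and returns the candidates-by-compounds fit matrix, suitable for
#' [fit_correlation_builder()]: each Fischer permutation then re-selects the
#' best candidate against the shuffled activities without re-fitting
#' geometry.
#'
#' @inheritParams construct_quantitative_model
#' @return Numeric matrix, candidates in rows, compound ids as column names.
#' @export
candidate_fit_matrix <- function(mols, activities, config = quant_config()) {
  data <- dplyr::inner_join(mols, activities, by = "id")
  candidates <- .quant_candidates(data, config)
  if (length(candidates) == 0) stop("reference compounds yielded no features")
  m <- do.call(rbind, lapply(candidates, function(cand) {
    fit_molecules(data, cand$model, config$rules)$fit
  }))
  colnames(m) <- data$id
  m
}

#' Selectivity index
#'
#' Ratio of the IC50 in a reference (typically normal) cell line to the IC50
#' in a target line; values much greater than 1 indicate selective toxicity
#' toward the target cells.  Full precision is returned; report rounded to
#' two decimals.
#'
#' @param ic50_reference,ic50_target Positive IC50 values (same units).
#' @return `ic50_reference / ic50_target`.
#' @examples
#' selectivity_index(89.587, 0.531)  # 168.71...
#' @export
selectivity_index <- function(ic50_reference, ic50_target) {
  if (any(!is.finite(ic50_reference)) || any(!is.finite(ic50_target)) ||
      any(ic50_reference <= 0) || any(ic50_target <= 0)) {
    stop("selectivity_index needs positive finite IC50 values")
  }
  ic50_reference / ic50_target
}
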