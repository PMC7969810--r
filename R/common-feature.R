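#' Parameters for common-feature model generation
#'
#' @param min_features,max_features Bounds on the size of returned feature
#'   arrangements.
#' @param distance_bin Pairwise-distance agreement tolerance in Angstrom when
#'   matching arrangements across molecules (default 1.0, commensurate with
#'   the 1.6 Angstrom sphere tolerance).
#' @param max_omitted Omission allowance given to realized models (default 1,
#'   the qualitative-model convention that lets inactives map partially).
#' @param tolerance,weight Sphere tolerance and weight of realized models.
#' @param rules Feature perception rules.
#' @return A list of class `common_feature_params`.
#' @export
common_feature_params <- function(min_features = 3L, max_features = 8L,
                                  distance_bin = 1.0, max_omitted = 1L,
                                  tolerance = 1.6, weight = 1.0,
                                  rules = .default_rules()) {
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 distance_bin = distance_bin,
                 max_omitted = as.integer(max_omitted),
                 tolerance = tolerance, weight = weight, rules = rules),
            class = "common_feature_params")
}

# Maximal common arrangements between a reference feature set and another
# molecule's feature set: nodes pair kind-matched features, edges demand
# pairwise-distance agreement within the bin, maximal cliques give maximal
# common sub-arrangements.  Returns a list of reference-index sets.
.common_refsets <- function(ref_feats, other_feats, bin) {
  nr <- nrow(ref_feats); no <- nrow(other_feats)
  pairs <- expand.grid(r = seq_len(nr), o = seq_len(no))
  pairs <- pairs[ref_feats$kind[pairs$r] == other_feats$kind[pairs$o], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(list())
  dref <- as.matrix(stats::dist(.feature_centers(ref_feats)))
  doth <- as.matrix(stats::dist(.feature_centers(other_feats)))
  np <- nrow(pairs)
  adj <- matrix(FALSE, np, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (pairs$r[i] != pairs$r[j] && pairs$o[i] != pairs$o[j] &&
          abs(dref[pairs$r[i], pairs$r[j]] - doth[pairs$o[i], pairs$o[j]]) <= bin) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 1)
  refsets <- lapply(cliques, function(cl) sort(pairs$r[as.integer(cl)]))
  unique(refsets)
}

.maximal_sets <- function(sets) {
  sets <- unique(sets)
  if (length(sets) <= 1) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) { keep[i] <- FALSE; break }
    }
  }
  sets[keep]
}

#' Generate common-feature pharmacophore models from active compounds
#'
#' The most feature-rich active (ties broken by id order) serves as the
#' reference.  For every other active a correspondence graph is built whose
#' nodes are kind-matched feature pairs and whose edges require
#' pairwise-distance agreement within `distance_bin`; maximal cliques yield
#' that molecule's common sub-arrangements, and intersecting the clique
#' reference-sets across all actives leaves the arrangements shared by every
#' active.  Each maximal shared arrangement is realized as a model on the
#' reference geometry.  The result is invariant to the input order of the
#' actives.
#'
#' @param actives A molecule table of active compounds (>= 2 rows; a single
#'   molecule duplicated recovers its own full feature set).
#' @param params A [common_feature_params()].
#' @return Tibble of candidates ordered by support then size: columns
#'   `model` (list of [pharmacophore_model()]), `n_constraints`, `kinds`,
#'   `support`.
#' @export
build_common_feature_models <- function(actives, params = common_feature_params()) {
  if (nrow(actives) < 2) stop("need at least 2 active molecules")
  feats <- lapply(actives$mol, perceive_features, conformer = 1L,
                  rules = params$rules)
  nfeat <- vapply(feats, nrow, integer(1))
  if (any(nfeat == 0)) {
    stop("active(s) without perceivable features: ",
         paste(actives$id[nfeat == 0], collapse = ", "))
  }
  ord <- order(-nfeat, actives$id)
  ref_i <- ord[1]
  ref_feats <- feats[[ref_i]]
  others <- setdiff(order(actives$id), ref_i)

  common <- list(seq_len(nrow(ref_feats)))
  for (oi in others) {
    refsets <- .common_refsets(ref_feats, feats[[oi]], params$distance_bin)
    if (length(refsets) == 0) return(.empty_candidates())
    inter <- list()
    for (s in common) {
      for (r in refsets) {
        v <- intersect(s, r)
        if (length(v) >= 2) inter[[length(inter) + 1L]] <- sort(v)
      }
    }
    common <- .maximal_sets(unique(inter))
    if (length(common) == 0) return(.empty_candidates())
    if (length(common) > 500) {
      common <- common[order(-lengths(common))][1:500]
    }
  }

  common <- common[lengths(common) >= max(2L, params$min_features)]
  common <- lapply(common, function(s) {
    if (length(s) > params$max_features) s[seq_len(params$max_features)] else s
  })
  common <- .maximal_sets(unique(common))
  if (length(common) == 0) return(.empty_candidates())
  # deterministic order: larger first, then by member indices
  common <- common[order(-lengths(common),
                         vapply(common, function(s) paste(sprintf("%04d", s),
                                                          collapse = ","),
                                character(1)))]

  cand <- purrr::map_dfr(seq_along(common), function(k) {
    s <- common[[k]]
    cons <- dplyr::mutate(ref_feats[s, c("kind", "x", "y", "z")],
                          tolerance = params$tolerance, weight = params$weight)
    mdl <- pharmacophore_model(sprintf("hiphop_candidate_%d", k), cons,
                               max_omitted = min(params$max_omitted,
                                                 nrow(cons) - 1L))
    tibble::tibble(model = list(mdl), n_constraints = nrow(cons),
                   kinds = paste(cons$kind, collapse = ","))
  })

  # every returned candidate must be mapped by every active that built it
  ok <- vapply(cand$model, function(m) {
    all(vapply(actives$mol, function(mol) {
      fr <- best_fit_over_conformers(mol, m, params$rules)
      fr$fit > 0 && fr$n_omitted <= m$max_omitted
    }, logical(1)))
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  cand$support <- nrow(actives)
  dplyr::arrange(cand, dplyr::desc(.data$support), dplyr::desc(.data$n_constraints))
}

.empty_candidates <- function() {
  tibble::tibble(model = list(), n_constraints = integer(),
                 kinds = character(), support = integer())
}

#' Rank common-feature candidates by active/inactive discrimination
#'
#' Scores every candidate by the difference between the mean best fit of the
#' actives and of the inactives (partial mapping allowed through each
#' model's omission allowance), then stable-sorts by that difference,
#' descending.
#'
#' @param candidates Candidate tibble from [build_common_feature_models()].
#' @param actives,inactives Molecule tables.
#' @param rules Feature perception rules.
#' @return The candidate tibble with `mean_fit_active`, `mean_fit_inactive`,
#'   and `discrimination` columns, sorted by discrimination.
#' @export
rank_by_discrimination <- function(candidates, actives, inactives,
                                   rules = .default_rules()) {
  if (nrow(actives) == 0 || nrow(inactives) == 0) {
    stop("both actives and inactives must be non-empty")
  }
  scored <- purrr::map_dfr(candidates$model, function(m) {
    fa <- fit_molecules(actives, m, rules)$fit
    fi <- fit_molecules(inactives, m, rules)$fit
    tibble::tibble(mean_fit_active = mean(fa), mean_fit_inactive = mean(fi),
                   discrimination = mean(fa) - mean(fi))
  })
  out <- dplyr::bind_cols(candidates, scored)
  out[order(-out$discrimination), , drop = FALSE]
}
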