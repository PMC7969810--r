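#' Screening filter thresholds
#'
#' Defaults follow the conventional drug-likeness and property cutoffs for
#' kinase-inhibitor screening: Lipinski bounds (MW <= 500 Da, rotatable
#' bonds <= 10, H-bond acceptors <= 10, H-bond donors <= 5, all inclusive,
#' strict rule with no one-violation allowance), ADMET levels
#' (solubility 3, absorption 0, blood-brain-barrier 3, matched by equality
#' with the favorable level), Tanimoto similarity >= 0.40, and an inclusive
#' minimum docking score.  Fit thresholds are strict (`fit > threshold`);
#' similarity and docking thresholds are inclusive.
#'
#' @param mw_max,rotatable_max,hba_max,hbd_max Lipinski bounds.
#' @param admet_cutoffs Named list/vector with `solubility`, `absorption`,
#'   `bbb` level cutoffs.
#' @param similarity_min Minimum Tanimoto similarity, in `[0, 1]`.
#' @param docking_score_min Minimum external docking score (inclusive), or
#'   `NA` to skip the stage.
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(mw_max = 500, rotatable_max = 10, hba_max = 10,
                              hbd_max = 5,
                              admet_cutoffs = c(solubility = 3, absorption = 0,
                                                bbb = 3),
                              similarity_min = 0.40,
                              docking_score_min = NA_real_) {
  stopifnot(similarity_min >= 0, similarity_min <= 1)
  structure(list(mw_max = mw_max, rotatable_max = rotatable_max,
                 hba_max = hba_max, hbd_max = hbd_max,
                 admet_cutoffs = as.list(admet_cutoffs),
                 similarity_min = similarity_min,
                 docking_score_min = docking_score_min),
            class = "filter_thresholds")
}

.as_sdfset <- function(mols) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_molecules(mols, tmp)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tmp, skipErrors = TRUE))
  ChemmineR::cid(sdf) <- ChemmineR::sdfid(sdf)
  sdf
}

#' Molecular properties for screening
#'
#' Computes molecular weight, LogP, topological polar surface area, Lipinski
#' H-bond acceptor/donor counts (Open Babel descriptors), the rotatable-bond
#' count (non-ring single bonds between two non-terminal heavy atoms, amide
#' C-N excluded), and the aromatic-atom proportion used by the solubility
#' estimate.  Results are cached in the `properties` field downstream.
#'
#' @param mols A molecule table.
#' @return Tibble with columns `id`, `mw`, `logp`, `tpsa`, `hba`, `hbd`,
#'   `rotatable`, `aromatic_prop`.
#' @export
molecular_properties <- function(mols) {
  sdf <- .as_sdfset(mols)
  pr <- ChemmineR::propOB(sdf)
  idx <- match(mols$id, rownames(pr))
  if (anyNA(idx)) idx <- match(mols$id, pr$title)
  tibble::tibble(
    id = mols$id,
    mw = pr$MW[idx],
    logp = pr$logP[idx],
    tpsa = pr$TPSA[idx],
    hba = as.integer(pr$HBA1[idx]),
    hbd = as.integer(pr$HBD[idx]),
    rotatable = vapply(mols$mol, count_rotatable_bonds, integer(1)),
    aromatic_prop = vapply(mols$mol, .aromatic_proportion, numeric(1))
  )
}

#' Rotatable-bond count
#'
#' Non-ring single bonds between two non-terminal heavy atoms, with amide
#' C-N bonds excluded.
#'
#' @param mol A [mol_record()].
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  bonds <- mol$bonds
  if (nrow(bonds) == 0) return(0L)
  heavy <- mol$atoms$elem != "H"
  nb <- .neighbour_list(mol)
  heavy_deg <- vapply(seq_len(nrow(mol$atoms)), function(a) {
    sum(heavy[nb[[a]]])
  }, numeric(1))
  orders <- .bond_order_lookup(mol)
  in_ring <- rep(FALSE, nrow(bonds))
  rings <- .find_rings(mol, sizes = 3:8)
  for (ring in rings) {
    m <- length(ring)
    for (i in seq_len(m)) {
      a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
      hit <- which((bonds$a1 == a & bonds$a2 == b) |
                   (bonds$a1 == b & bonds$a2 == a))
      in_ring[hit] <- TRUE
    }
  }
  is_carbonyl_c <- function(c) {
    mol$atoms$elem[c] == "C" && any(vapply(nb[[c]], function(o) {
      mol$atoms$elem[o] == "O" &&
        identical(unname(orders[paste(min(c, o), max(c, o))]), 2L)
    }, logical(1)))
  }
  n <- 0L
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    if (bonds$order[k] != 1 || in_ring[k]) next
    if (!heavy[a] || !heavy[b]) next
    if (heavy_deg[a] < 2 || heavy_deg[b] < 2) next
    amide <- (mol$atoms$elem[a] == "N" && is_carbonyl_c(b)) ||
             (mol$atoms$elem[b] == "N" && is_carbonyl_c(a))
    if (amide) next
    n <- n + 1L
  }
  n
}

.aromatic_proportion <- function(mol) {
  heavy <- which(mol$atoms$elem != "H")
  if (length(heavy) == 0) return(0)
  orders <- .bond_order_lookup(mol)
  arom <- rep(FALSE, nrow(mol$atoms))
  for (ring in .find_rings(mol, sizes = c(5L, 6L))) {
    if (.ring_is_aromatic(ring, mol, orders)) arom[ring] <- TRUE
  }
  sum(arom[heavy]) / length(heavy)
}

#' Lipinski rule-of-five filter
#'
#' Strict form: a molecule passes only with zero violations of
#' MW <= `mw_max`, rotatable bonds <= `rotatable_max`, H-bond acceptors <=
#' `hba_max`, H-bond donors <= `hbd_max` (all inclusive).
#'
#' @param mols A molecule table.
#' @param thresholds A [filter_thresholds()].
#' @param properties Optional precomputed [molecular_properties()] table.
#' @return Tibble with the property columns plus `pass` and a `violations`
#'   list-column.
#' @export
lipinski_filter <- function(mols, thresholds = filter_thresholds(),
                            properties = NULL) {
  pr <- properties %||% molecular_properties(mols)
  pr$violations <- purrr::pmap(
    list(pr$mw, pr$rotatable, pr$hba, pr$hbd),
    function(mw, rot, hba, hbd) {
      v <- character(0)
      if (mw > thresholds$mw_max) v <- c(v, "mw")
      if (rot > thresholds$rotatable_max) v <- c(v, "rotatable")
      if (hba > thresholds$hba_max) v <- c(v, "hba")
      if (hbd > thresholds$hbd_max) v <- c(v, "hbd")
      v
    })
  pr$pass <- lengths(pr$violations) == 0
  pr
}

#' ADMET level filter with surrogate descriptors
#'
#' Surrogate descriptor models binned into integer levels:
#'
#' * **Solubility**: ESOL-style estimate
#'   `logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`, binned at
#'   edges (-Inf, -8, -6, -4, -2, 0, Inf) into levels 0-5; level 3
#'   (logS in (-4, -2]) is the favorable, drug-like bin.
#' * **Absorption**: polar-surface-area/LogP rule; level 0 (good) inside
#'   TPSA <= 131.6 and -2 <= LogP <= 5.88, level 1 inside TPSA <= 148.1 and
#'   LogP <= 6.8, level 2 inside TPSA <= 165 and LogP <= 7.8, else 3.
#' * **Blood-brain barrier**: level 0 (very high penetration) for TPSA < 40
#'   and LogP > 2, 1 for TPSA < 60, 2 for TPSA < 90, 3 (low penetration,
#'   favorable for a non-CNS target) for TPSA in [90, 150] and LogP <= 7,
#'   else 4 (outside the model).
#'
#' A molecule passes when each level equals its cutoff (equality semantics;
#' override the cutoffs via `thresholds`).
#'
#' @inheritParams lipinski_filter
#' @return Tibble with `id`, the three levels, `log_s`, and `pass`.
#' @export
admet_filter <- function(mols, thresholds = filter_thresholds(),
                         properties = NULL) {
  pr <- properties %||% molecular_properties(mols)
  logS <- 0.16 - 0.63 * pr$logp - 0.0062 * pr$mw + 0.066 * pr$rotatable -
    0.74 * pr$aromatic_prop
  sol <- as.integer(cut(logS, breaks = c(-Inf, -8, -6, -4, -2, 0, Inf),
                        labels = FALSE)) - 1L
  absb <- ifelse(pr$tpsa <= 131.6 & pr$logp >= -2 & pr$logp <= 5.88, 0L,
          ifelse(pr$tpsa <= 148.1 & pr$logp <= 6.8, 1L,
          ifelse(pr$tpsa <= 165 & pr$logp <= 7.8, 2L, 3L)))
  bbb <- ifelse(pr$tpsa > 150 | pr$logp > 7, 4L,
         ifelse(pr$tpsa < 40 & pr$logp > 2, 0L,
         ifelse(pr$tpsa < 60, 1L,
         ifelse(pr$tpsa < 90, 2L, 3L))))
  co <- thresholds$admet_cutoffs
  tibble::tibble(
    id = pr$id, log_s = logS,
    solubility_level = sol, absorption_level = absb, bbb_level = bbb,
    pass = sol == co$solubility & absb == co$absorption & bbb == co$bbb
  )
}

#' Tanimoto similarity search
#'
#' Atom-pair fingerprints with Tanimoto scoring; hits require similarity at
#' or above `min_similarity` (inclusive) and, when an anchor SMARTS is
#' given, presence of that substructure.  Hits are sorted by similarity,
#' descending.
#'
#' @param query A [mol_record()] (or single-row molecule table).
#' @param mols Molecule table to search.
#' @param min_similarity Minimum Tanimoto similarity (default 0.40).
#' @param anchor Optional SMARTS string that hits must contain.
#' @return Tibble with `id` and `similarity`.
#' @export
similarity_search <- function(query, mols, min_similarity = 0.40, anchor = NULL) {
  if (nrow(mols) == 0) {
    return(tibble::tibble(id = character(), similarity = double()))
  }
  if (is.data.frame(query)) query <- query$mol[[1]]
  all_tbl <- dplyr::bind_rows(molecule_table(list(query)),
                              mols[mols$id != query$id, , drop = FALSE])
  sdf <- .as_sdfset(all_tbl)
  ap <- ChemmineR::sdf2ap(sdf)
  qi <- match(query$id, ChemmineR::cid(ap))
  sims <- vapply(mols$id, function(id) {
    ChemmineR::cmp.similarity(ap[[qi]], ap[[match(id, ChemmineR::cid(ap))]])
  }, numeric(1))
  out <- tibble::tibble(id = mols$id, similarity = unname(sims))
  out <- out[out$similarity >= min_similarity, , drop = FALSE]
  if (!is.null(anchor) && nrow(out) > 0) {
    hit_tbl <- mols[match(out$id, mols$id), , drop = FALSE]
    counts <- ChemmineR::smartsSearchOB(.as_sdfset(hit_tbl), anchor,
                                        uniqueMatches = FALSE)
    out <- out[counts > 0, , drop = FALSE]
  }
  dplyr::arrange(out, dplyr::desc(.data$similarity))
}

#' Ingest external docking scores
#'
#' Docking is never executed here; scores arrive as a TSV with `id` and
#' `score` columns.  Duplicate ids keep the last row (with a warning).
#'
#' @param path Path to the TSV file.
#' @return Tibble with `id` and `score`.
#' @export
ingest_docking_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed docking score TSV: ",
                                          conditionMessage(e)))
  nm <- tolower(names(df))
  idc <- which(nm == "id")[1]
  sc <- which(nm == "score")[1]
  if (is.na(idc) || is.na(sc)) stop("docking TSV needs 'id' and 'score' columns")
  if (!is.numeric(df[[sc]])) stop("malformed docking TSV: non-numeric scores")
  out <- tibble::tibble(id = as.character(df[[idc]]), score = df[[sc]])
  if (anyDuplicated(out$id)) {
    warning("duplicate ids in docking scores; keeping the last occurrence")
    out <- out[!duplicated(out$id, fromLast = TRUE), , drop = FALSE]
  }
  out
}

#' Apply a docking-score filter to a hit list
#'
#' Hits lacking a score are dropped with a warning; survivors have
#' `score >= min_score` (inclusive).
#'
#' @param hits Character vector of compound ids.
#' @param scores Score table from [ingest_docking_scores()].
#' @param min_score Inclusive minimum score.
#' @return Character vector of surviving ids.
#' @export
apply_score_filter <- function(hits, scores, min_score) {
  sc <- scores$score[match(hits, scores$id)]
  missing <- hits[is.na(sc)]
  if (length(missing) > 0) {
    warning("dropping ", length(missing), " hit(s) without docking scores: ",
            paste(missing, collapse = ", "))
  }
  hits[!is.na(sc) & sc >= min_score]
}

#' Run the full screening cascade
#'
#' Per model arm: pharmacophore mapping with a strict fit threshold, then
#' the drug-likeness stages in `stage_order` (Lipinski, ADMET, optional
#' docking-score filter).  With two models the final hit list is the
#' intersection of the two arms' survivors; attrition is monotone within
#' each arm and the intersection is symmetric in the arms.
#'
#' @param mols A molecule table (the screening database).
#' @param models List of one or two [pharmacophore_model()] objects.
#' @param fit_thresholds Numeric vector, one strict fit threshold per model.
#' @param thresholds A [filter_thresholds()].
#' @param docking_scores Optional score table from
#'   [ingest_docking_scores()]; used when `thresholds$docking_score_min`
#'   is set.
#' @param stage_order Order of the property stages (any permutation of
#'   `"lipinski"`, `"admet"`, `"docking"`).
#' @param rules Feature perception rules.
#' @return Object of class `screen_report`: stage accounting tibble plus
#'   the final hit ids; has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
run_cascade <- function(mols, models, fit_thresholds,
                        thresholds = filter_thresholds(),
                        docking_scores = NULL,
                        stage_order = c("lipinski", "admet", "docking"),
                        rules = .default_rules()) {
  if (nrow(mols) == 0) stop("screening database is empty")
  if (inherits(models, "pharmacophore_model")) models <- list(models)
  stopifnot(length(models) %in% c(1L, 2L),
            length(fit_thresholds) == length(models))
  stage_order <- match.arg(stage_order, c("lipinski", "admet", "docking"),
                           several.ok = TRUE)
  props <- molecular_properties(mols)
  lip <- lipinski_filter(mols, thresholds, properties = props)
  adm <- admet_filter(mols, thresholds, properties = props)

  stages <- list()
  push <- function(arm, stage, ids_in, ids_out) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      arm = arm, stage = stage, n_in = length(ids_in), n_out = length(ids_out),
      survivors = list(ids_out))
  }
  arm_final <- list()
  for (mi in seq_along(models)) {
    arm <- models[[mi]]$name
    fits <- fit_molecules(mols, models[[mi]], rules)
    cur <- mols$id
    hit <- fits$id[fits$fit > fit_thresholds[mi]]
    nxt <- intersect(cur, hit)
    push(arm, sprintf("fit > %g", fit_thresholds[mi]), cur, nxt); cur <- nxt
    for (st in stage_order) {
      if (st == "lipinski") {
        nxt <- intersect(cur, lip$id[lip$pass])
        push(arm, "lipinski", cur, nxt); cur <- nxt
      } else if (st == "admet") {
        nxt <- intersect(cur, adm$id[adm$pass])
        push(arm, "admet", cur, nxt); cur <- nxt
      } else if (st == "docking" && !is.na(thresholds$docking_score_min)) {
        if (is.null(docking_scores)) stop("docking stage requires docking_scores")
        nxt <- suppressWarnings(
          apply_score_filter(cur, docking_scores, thresholds$docking_score_min))
        push(arm, sprintf("docking >= %g", thresholds$docking_score_min),
             cur, nxt); cur <- nxt
      }
    }
    arm_final[[arm]] <- cur
  }
  if (length(models) == 2) {
    final <- intersect(arm_final[[1]], arm_final[[2]])
    stages[[length(stages) + 1L]] <- tibble::tibble(
      arm = "both", stage = "intersection",
      n_in = length(arm_final[[1]]) + length(arm_final[[2]]),
      n_out = length(final), survivors = list(final))
  } else {
    final <- arm_final[[1]]
  }
  structure(list(stages = dplyr::bind_rows(stages), final_hits = final,
                 n_models = length(models),
                 intersection = length(models) == 2),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  df <- x$stages
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  [%s] %-14s %5d -> %5d\n", df$arm[i], df$stage[i],
                df$n_in[i], df$n_out[i]))
  }
  if (!x$intersection) cat("  (single model: intersection stage skipped)\n")
  cat(sprintf("  final hits: %d\n", length(x$final_hits)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.screen_report <- function(x, ...) {
  dplyr::select(x$stages, "arm", "stage", "n_in", "n_out")
}

#' @exportS3Method generics::glance
glance.screen_report <- function(x, ...) {
  tibble::tibble(n_models = x$n_models, n_stages = nrow(x$stages),
                 n_hits = length(x$final_hits),
                 intersection = x$intersection)
}

#' @exportS3Method ggplot2::autoplot
autoplot.screen_report <- function(object, ...) {
  df <- object$stages
  df$label <- factor(paste(df$arm, df$stage, sep = ": "),
                     levels = unique(paste(df$arm, df$stage, sep = ": ")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n_out,
                                   fill = .data$arm)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "compounds surviving",
                  title = "Screening cascade attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
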