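#' Feature perception rules
#'
#' The pharmacophore feature alphabet follows the published Catalyst-style
#' conventions:
#'
#' * **HBA** (hydrogen-bond acceptor): N or O with an available lone pair and
#'   no positive formal charge.  Amide nitrogens (N bonded to a carbonyl
#'   carbon) and trisubstituted aromatic nitrogens are excluded.
#' * **HBD** (hydrogen-bond donor): N or O carrying at least one hydrogen
#'   (explicit or implied by valence).  A hydroxyl oxygen is therefore both
#'   donor and acceptor.
#' * **HY** (hydrophobe): connected components of nonpolar carbons (no N, O,
#'   F, S or P neighbour; not aromatic) of at least `hy_min_size` atoms,
#'   collapsed to one centroid per component.
#' * **AR** (aromatic ring): 5- or 6-membered rings of C/N atoms whose ring
#'   bonds are all marked aromatic (order 4), or 6-rings with alternating
#'   single/double bonds; centroid plus unit plane normal.
#'
#' Rules are data, not code: the defaults ship as an editable YAML file and
#' can be reloaded with [read_feature_rules()].
#'
#' @param hba_elements,hbd_elements Element symbols eligible as acceptor /
#'   donor atoms.
#' @param hba_exclude_amide_n Drop nitrogens bonded to a carbonyl carbon from
#'   the acceptor list.
#' @param hy_min_size Minimum nonpolar-component size collapsed to a
#'   hydrophobe centroid.
#' @param hy_polar_neighbours Elements whose presence as a neighbour makes a
#'   carbon polar (excluded from hydrophobes).
#' @param aromatic_ring_sizes Ring sizes considered for AR features.
#' @param projected_points Reserved flag for the two-sphere projected-point
#'   acceptor/donor representation; the default (and only implemented)
#'   representation is a single sphere on the heavy atom with a direction
#'   vector.
#' @return An object of class `feature_rules`.
#' @export
feature_rules <- function(hba_elements = c("N", "O"),
                          hbd_elements = c("N", "O"),
                          hba_exclude_amide_n = TRUE,
                          hy_min_size = 3L,
                          hy_polar_neighbours = c("N", "O", "F", "S", "P"),
                          aromatic_ring_sizes = c(5L, 6L),
                          projected_points = FALSE) {
  structure(list(
    hba_elements = hba_elements, hbd_elements = hbd_elements,
    hba_exclude_amide_n = isTRUE(hba_exclude_amide_n),
    hy_min_size = as.integer(hy_min_size),
    hy_polar_neighbours = hy_polar_neighbours,
    aromatic_ring_sizes = as.integer(aromatic_ring_sizes),
    projected_points = isTRUE(projected_points),
    version = "1.0"
  ), class = "feature_rules")
}

#' @rdname feature_rules
#' @param path Path to a YAML rules file; defaults to the copy shipped with
#'   the package.
#' @export
read_feature_rules <- function(path = system.file("extdata", "feature_rules.yaml",
                                                  package = "pharmscreen")) {
  y <- yaml::read_yaml(path)
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(feature_rules, y[setdiff(names(y), "version")])
}

.default_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- feature_rules()
    cache
  }
})

.neighbour_list <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# All simple rings of the requested sizes, canonicalized.  Molecules at the
# scales this package handles are small, so a DFS over bonds suffices.
.find_rings <- function(mol, sizes = c(5L, 6L)) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0 || n < min(sizes)) return(list())
  nb <- .neighbour_list(mol)
  maxlen <- max(sizes)
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nx in nb[[last]]) {
      if (nx == path[1] && length(path) >= min(sizes)) {
        if (length(path) %in% sizes) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1L]] <<- path
          }
        }
      } else if (!(nx %in% path) && length(path) < maxlen && nx > path[1]) {
        walk(c(path, nx))
      }
    }
  }
  for (a in seq_len(n)) walk(a)
  rings
}

.bond_order_lookup <- function(mol) {
  if (nrow(mol$bonds) == 0) return(stats::setNames(integer(0), character(0)))
  key <- paste(pmin(mol$bonds$a1, mol$bonds$a2), pmax(mol$bonds$a1, mol$bonds$a2))
  stats::setNames(mol$bonds$order, key)
}

.ring_is_aromatic <- function(ring, mol, orders) {
  elems <- mol$atoms$elem[ring]
  if (!all(elems %in% c("C", "N"))) return(FALSE)
  m <- length(ring)
  ringbonds <- vapply(seq_len(m), function(i) {
    a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
    unname(orders[paste(min(a, b), max(a, b))])
  }, numeric(1))
  if (anyNA(ringbonds)) return(FALSE)
  if (all(ringbonds == 4)) return(TRUE)
  m == 6 && sum(ringbonds) == 9 && all(ringbonds %in% c(1, 2))
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
  v / nv
}

#' Perceive pharmacophore features on a conformer
#'
#' Deterministic: the feature list is sorted by kind and then by source-atom
#' indices, and a rigid motion of the conformer moves every feature center
#' (and direction) by the same transform.
#'
#' @param mol A [mol_record()] with at least one 3D conformer.
#' @param conformer Conformer index (default 1).
#' @param rules A [feature_rules()] object.
#' @return Tibble with columns `kind`, `x`, `y`, `z`, `dx`, `dy`, `dz`
#'   (unit direction or NA), and `atoms` (list of source atom indices).
#' @export
perceive_features <- function(mol, conformer = 1L, rules = .default_rules()) {
  stopifnot(inherits(mol, "mol_record"), inherits(rules, "feature_rules"))
  xyz <- .require_conformer(mol, conformer)
  elem <- mol$atoms$elem
  chg <- mol$atoms$charge
  nb <- .neighbour_list(mol)
  orders <- .bond_order_lookup(mol)
  implh <- implicit_hydrogens(mol)
  heavy <- elem != "H"

  rows <- list()
  add <- function(kind, center, direction, atoms) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, x = center[1], y = center[2], z = center[3],
      dx = direction[1], dy = direction[2], dz = direction[3],
      atoms = list(sort(as.integer(atoms))))
  }
  heavy_nb <- function(a) nb[[a]][heavy[nb[[a]]]]
  lone_pair_dir <- function(a) {
    hn <- nb[[a]]
    if (length(hn) == 0) return(c(NA_real_, NA_real_, NA_real_))
    .unit(xyz[a, ] - colMeans(xyz[hn, , drop = FALSE]))
  }
  is_carbonyl_c <- function(c) {
    elem[c] == "C" && any(vapply(nb[[c]], function(o) {
      elem[o] == "O" && identical(unname(orders[paste(min(c, o), max(c, o))]), 2L)
    }, logical(1)))
  }

  # aromatic rings first; ring membership feeds the hydrophobe rule
  rings <- .find_rings(mol, rules$aromatic_ring_sizes)
  aromatic_atom <- rep(FALSE, length(elem))
  for (ring in rings) {
    if (.ring_is_aromatic(ring, mol, orders)) {
      aromatic_atom[ring] <- TRUE
      pts <- xyz[ring, , drop = FALSE]
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2, ctr))
      normal <- .unit(sv$v[, 3])
      if (!anyNA(normal) && normal[3] < 0) normal <- -normal
      add("AR", ctr, normal, ring)
    }
  }

  for (a in which(heavy)) {
    e <- elem[a]
    has_h <- implh[a] > 0 || any(elem[nb[[a]]] == "H")
    # acceptors
    if (e %in% rules$hba_elements && chg[a] <= 0) {
      excluded <- FALSE
      if (e == "N") {
        if (rules$hba_exclude_amide_n &&
            any(vapply(heavy_nb(a), is_carbonyl_c, logical(1)))) excluded <- TRUE
        if (aromatic_atom[a] && length(heavy_nb(a)) >= 3) excluded <- TRUE
        if (length(nb[[a]]) + implh[a] >= 4) excluded <- TRUE  # quaternary
      }
      if (!excluded) add("HBA", xyz[a, ], lone_pair_dir(a), a)
    }
    # donors
    if (e %in% rules$hbd_elements && has_h && chg[a] >= 0) {
      hat <- nb[[a]][elem[nb[[a]]] == "H"]
      dir <- if (length(hat) > 0) .unit(xyz[hat[1], ] - xyz[a, ]) else lone_pair_dir(a)
      add("HBD", xyz[a, ], dir, a)
    }
  }

  # hydrophobes: connected nonpolar carbon components
  nonpolar <- elem == "C" & !aromatic_atom & chg == 0
  for (a in which(nonpolar)) {
    if (any(elem[nb[[a]]] %in% rules$hy_polar_neighbours)) nonpolar[a] <- FALSE
  }
  if (any(nonpolar)) {
    idx <- which(nonpolar)
    sub <- mol$bonds[nonpolar[mol$bonds$a1] & nonpolar[mol$bonds$a2], , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(sub$a1, idx), to = match(sub$a2, idx)),
      directed = FALSE, vertices = data.frame(name = seq_along(idx)))
    comp <- igraph::components(g)$membership
    for (cm in unique(comp)) {
      members <- idx[comp == cm]
      if (length(members) >= rules$hy_min_size) {
        add("HY", colMeans(xyz[members, , drop = FALSE]),
            c(NA_real_, NA_real_, NA_real_), members)
      }
    }
  }

  if (length(rows) == 0) {
    return(tibble::tibble(kind = character(), x = double(), y = double(),
                          z = double(), dx = double(), dy = double(),
                          dz = double(), atoms = list()))
  }
  out <- dplyr::bind_rows(rows)
  first_atom <- vapply(out$atoms, min, integer(1))
  out[order(out$kind, first_atom), ]
}

#' Perceive features for every molecule in a table
#' @param mols A molecule table.
#' @inheritParams perceive_features
#' @return Tibble of features with an `id` column.
#' @export
perceive_features_all <- function(mols, conformer = 1L, rules = .default_rules()) {
  purrr::map2_dfr(mols$id, mols$mol, function(id, m) {
    dplyr::mutate(perceive_features(m, conformer, rules), id = id, .before = 1)
  })
}
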