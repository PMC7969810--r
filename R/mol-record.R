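#' Atomic masses used for molecular-weight fallbacks
#'
#' Monoisotopic-free average masses for the elements the package's synthetic
#' chemistry and fixtures use.
#' @noRd
.atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

.default_valence <- c(C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1, H = 1)

#' Create a molecule record
#'
#' A `mol_record` bundles a compound identifier with its connection table and
#' one or more 3D conformers.  Coordinates are Angstrom, right-handed, taken
#' as stored in the input; the package never re-centres or otherwise
#' transforms them on ingestion, because pharmacophore fit values depend on
#' the raw geometry.
#'
#' @param id Character identifier, unique within a dataset.
#' @param atoms Data frame with columns `elem` (element symbol) and `charge`
#'   (formal charge, default 0).
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic).
#' @param conformers List of numeric matrices, one row per atom, columns
#'   x/y/z in Angstrom.  May be empty for topology-only work (drug-likeness
#'   filters, fingerprints); geometric operations then refuse the record.
#' @param ic50 Optional experimental IC50 in micromolar (must be positive).
#' @param properties Named list of cached descriptor values.
#' @return An object of class `mol_record`.
#' @examples
#' benzene <- mol_record(
#'   "benzene",
#'   atoms = data.frame(elem = rep("C", 6)),
#'   bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4),
#'   conformers = list(cbind(1.4 * cos(0:5 * pi / 3),
#'                           1.4 * sin(0:5 * pi / 3), 0))
#' )
#' @export
mol_record <- function(id, atoms, bonds, conformers = list(), ic50 = NA_real_,
                       properties = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms <- atoms[, c("elem", "charge")]
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  bonds <- bonds[, c("a1", "a2", "order")]
  bonds$a1 <- as.integer(bonds$a1)
  bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  n <- nrow(atoms)
  if (nrow(bonds) > 0 && (max(bonds$a1, bonds$a2) > n || min(bonds$a1, bonds$a2) < 1)) {
    stop("bond indices out of range for molecule '", id, "'")
  }
  conformers <- lapply(conformers, function(xyz) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != n || ncol(xyz) != 3) {
      stop("each conformer needs one 3-vector per atom (molecule '", id, "')")
    }
    dimnames(xyz) <- NULL
    storage.mode(xyz) <- "double"
    xyz
  })
  if (!is.na(ic50) && ic50 <= 0) stop("activity_ic50 must be positive")
  structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers,
         ic50 = as.numeric(ic50), properties = properties),
    class = "mol_record"
  )
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s: %d atoms, %d bonds, %d conformer(s)%s\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers),
              if (!is.na(x$ic50)) sprintf(", IC50 %g uM", x$ic50) else ""))
  invisible(x)
}

#' Number of implicit hydrogens on each heavy atom
#'
#' Inferred from default valences and the sum of bond orders (aromatic bonds
#' count 1.5).  Explicit hydrogens in the connection table reduce the count.
#' @param mol A `mol_record`.
#' @return Integer vector, one entry per atom (0 for hydrogens themselves).
#' @export
implicit_hydrogens <- function(mol) {
  n <- nrow(mol$atoms)
  bsum <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + ord[k]
      bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + ord[k]
    }
  }
  val <- .default_valence[mol$atoms$elem]
  val[is.na(val)] <- 0
  h <- pmax(0L, as.integer(round(val - bsum)) + as.integer(mol$atoms$charge) * 0L)
  h[mol$atoms$elem == "H"] <- 0L
  h
}

#' Assemble molecule records into a molecule table
#'
#' The molecule table is the package's canonical collection type: a tibble
#' with one row per compound and the full record in the `mol` list-column, so
#' screening stages chain with the pipe while geometry stays available.
#'
#' @param mols List of `mol_record` objects.
#' @return Tibble with columns `id`, `mol`, `n_atoms`, `n_conformers`.
#' @export
molecule_table <- function(mols) {
  if (inherits(mols, "mol_record")) mols <- list(mols)
  stopifnot(all(vapply(mols, inherits, logical(1), "mol_record")))
  ids <- vapply(mols, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tibble::tibble(
    id = ids,
    mol = mols,
    n_atoms = vapply(mols, function(m) nrow(m$atoms), integer(1)),
    n_conformers = vapply(mols, function(m) length(m$conformers), integer(1))
  )
}

#' Apply a rigid transform to every conformer of a record
#' @param mol A `mol_record`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed `mol_record`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  mol$conformers <- lapply(mol$conformers, function(xyz) {
    sweep(xyz %*% t(rotation), 2, translation, "+")
  })
  mol
}

.require_conformer <- function(mol, conformer = 1L) {
  if (length(mol$conformers) < conformer) {
    stop("molecule '", mol$id, "' has no 3D conformer ", conformer,
         "; geometric stages need explicit coordinates")
  }
  mol$conformers[[conformer]]
}
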