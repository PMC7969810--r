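#' Read molecules from disk
#'
#' Reads an SDF (V2000) file, or a SMILES file (one `SMILES id` pair per
#' line, topology only), into a molecule table.  Blocks that fail to parse
#' are skipped and counted rather than aborting the whole read; consecutive
#' SDF blocks sharing an identifier are folded into one record with multiple
#' conformers.
#'
#' @param path Path to the input file.
#' @param format `"sdf"` or `"smiles"`.
#' @return A molecule table (see [molecule_table()]) with attributes
#'   `n_parsed` and `n_skipped`; `n_parsed + n_skipped` equals the number of
#'   input blocks.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") return(.read_smiles(path))

  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("no parsable molecules in ", path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0 ||
      (utils::tail(ends, 1) < length(lines) &&
       any(nzchar(trimws(lines[(utils::tail(ends, 1) + 1):length(lines)]))))) {
    ends <- c(ends, length(lines))
  }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  n_blocks <- length(starts)

  # ChemmineR's V2000 parser does the heavy lifting; corrupt blocks are
  # dropped and counted instead of aborting the read.
  skipped_idx <- integer(0)
  sdf <- withCallingHandlers(
    tryCatch(ChemmineR::read.SDFset(path, skipErrors = TRUE),
             error = function(e) stop("unreadable SDF file ", path, ": ",
                                      conditionMessage(e))),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("removed from the output", msg)) {
        skipped_idx <<- as.integer(unlist(regmatches(msg, gregexpr("[0-9]+", msg))))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(sdf) == 0) stop("zero parsable molecules in ", path)
  block_of <- setdiff(seq_len(n_blocks), skipped_idx)
  ok <- ChemmineR::validSDF(sdf)
  skipped <- length(skipped_idx) + sum(!ok)
  sdf <- sdf[ok]; block_of <- block_of[ok]

  recs <- vector("list", length(sdf))
  for (k in seq_along(recs)) {
    blk <- lines[starts[block_of[k]]:ends[block_of[k]]]
    id <- trimws(blk[1])
    rec <- .sdfset_to_record(sdf[[k]], if (nzchar(id)) id else sprintf("MOL%04d", k))
    for (ln in grep("^M  CHG", blk, value = TRUE)) {
      f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      for (j in seq_len(f[1])) rec$atoms$charge[f[2 * j]] <- f[2 * j + 1]
    }
    db <- ChemmineR::datablock(sdf[[k]])
    if (length(db) > 0) rec$properties <- as.list(db)
    if (!is.null(rec$properties[["IC50_uM"]])) {
      rec$ic50 <- as.numeric(rec$properties[["IC50_uM"]])
    }
    recs[[k]] <- rec
  }
  if (length(recs) == 0) stop("zero parsable molecules in ", path)

  # fold repeated ids into multi-conformer records
  ids <- vapply(recs, `[[`, character(1), "id")
  out <- list()
  for (id in unique(ids)) {
    grp <- recs[ids == id]
    rec <- grp[[1]]
    if (length(grp) > 1) {
      rec$conformers <- do.call(c, lapply(grp, `[[`, "conformers"))
    }
    out[[length(out) + 1L]] <- rec
  }
  tbl <- molecule_table(out)
  attr(tbl, "n_parsed") <- length(recs)
  attr(tbl, "n_skipped") <- skipped
  tbl
}

.read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no parsable molecules in ", path)
  recs <- list(); skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    smi <- f[1]; id <- if (length(f) >= 2) f[2] else sprintf("SMI%04d", i)
    rec <- tryCatch({
      sdf <- ChemmineR::smiles2sdf(stats::setNames(smi, id))
      .sdfset_to_record(sdf[[1]], id, with_conformer = FALSE)
    }, error = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L else recs[[length(recs) + 1L]] <- rec
  }
  if (length(recs) == 0) stop("zero parsable molecules in ", path)
  tbl <- molecule_table(recs)
  attr(tbl, "n_parsed") <- length(recs)
  attr(tbl, "n_skipped") <- skipped
  tbl
}

.sdfset_to_record <- function(sdf, id, with_conformer = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_\\d+$", "", rownames(ab))
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  conf <- if (with_conformer) list(unname(ab[, 1:3, drop = FALSE])) else list()
  mol_record(id, atoms = data.frame(elem = elem, charge = 0),
             bonds = bonds, conformers = conf)
}

#' Write a molecule table to an SDF (V2000) file
#'
#' One block per conformer; multi-conformer records repeat the identifier.
#' Output is byte-deterministic for identical input.
#'
#' @param mols A molecule table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mols))) {
    m <- .kekulize(mols$mol[[i]])
    confs <- if (length(m$conformers) == 0) list(NULL) else m$conformers
    for (xyz in confs) {
      if (is.null(xyz)) xyz <- matrix(0, nrow(m$atoms), 3)
      writeLines(c(m$id, "  pharmscreen", ""), con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(m$atoms), nrow(m$bonds)), con)
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[, 1], xyz[, 2], xyz[, 3], m$atoms$elem), con)
      if (nrow(m$bonds) > 0) {
        writeLines(sprintf("%3d%3d%3d  0", m$bonds$a1, m$bonds$a2, m$bonds$order), con)
      }
      chg <- which(m$atoms$charge != 0)
      for (a in chg) writeLines(sprintf("M  CHG  1 %3d %3d", a, m$atoms$charge[a]), con)
      writeLines("M  END", con)
      if (!is.na(m$ic50)) {
        writeLines(c(">  <IC50_uM>", format(m$ic50, digits = 12), ""), con)
      }
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

# V2000 reserves bond order 4 for queries; isolated aromatic 6-rings are
# written in the alternating Kekule form instead so downstream toolkits
# accept the file.  Perception recognises both encodings.
.kekulize <- function(mol) {
  if (!any(mol$bonds$order == 4)) return(mol)
  orders <- .bond_order_lookup(mol)
  for (ring in .find_rings(mol, sizes = 6L)) {
    ringbonds <- lapply(seq_along(ring), function(i) {
      c(ring[i], ring[if (i == length(ring)) 1L else i + 1L])
    })
    all4 <- all(vapply(ringbonds, function(b) {
      identical(unname(orders[paste(min(b), max(b))]), 4L)
    }, logical(1)))
    if (!all4) next
    for (i in seq_along(ringbonds)) {
      b <- ringbonds[[i]]
      hit <- which((mol$bonds$a1 == b[1] & mol$bonds$a2 == b[2]) |
                   (mol$bonds$a1 == b[2] & mol$bonds$a2 == b[1]))
      mol$bonds$order[hit] <- if (i %% 2 == 1) 2L else 1L
    }
  }
  mol
}

#' Read an activity table
#'
#' CSV with a header naming an id column and an IC50 column (micromolar);
#' the first column matching `id` (case-insensitive) and the first matching
#' `ic50` are used.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `id` (character) and `ic50` (positive numeric).
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty activity table: ", path)
  nm <- tolower(names(df))
  idc <- which(nm %in% c("id", "compound", "compound_id", "compound_no", "no"))[1]
  acc <- grep("ic50", nm)[1]
  if (is.na(idc) || is.na(acc)) stop("activity table needs id and IC50 columns")
  out <- tibble::tibble(id = as.character(df[[idc]]), ic50 = df[[acc]])
  if (!is.numeric(out$ic50)) {
    bad <- which(is.na(suppressWarnings(as.numeric(out$ic50))))[1]
    stop("non-numeric IC50 in row ", bad, " of ", path)
  }
  bad <- which(is.na(out$ic50) | out$ic50 <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing IC50 in row ", bad[1], " (id '",
         out$id[bad[1]], "') of ", path)
  }
  if (anyDuplicated(out$id)) stop("duplicate compound ids in ", path)
  out
}

.MODEL_SCHEMA_VERSION <- "1.0"

#' Write / read a pharmacophore model document
#'
#' JSON serialization with a schema version; `read_model(write_model(m))`
#' returns a model identical field-by-field, including the calibration
#' constant when present.
#'
#' @param model A [pharmacophore_model()].
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  doc <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    name = model$name,
    constraints = lapply(seq_len(nrow(model$constraints)), function(i) {
      ct <- model$constraints[i, ]
      list(kind = ct$kind, center = c(ct$x, ct$y, ct$z),
           tolerance = ct$tolerance, weight = ct$weight)
    }),
    max_omitted = model$max_omitted
  )
  if (!is.null(model$calibration_C) && !is.na(model$calibration_C)) {
    doc$calibration_C <- model$calibration_C
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unreadable model document: ",
                                           conditionMessage(e)))
  if (is.null(doc$schema_version) || doc$schema_version != .MODEL_SCHEMA_VERSION) {
    stop("model schema version mismatch: expected ", .MODEL_SCHEMA_VERSION,
         ", got ", doc$schema_version %||% "<missing>")
  }
  cons <- lapply(doc$constraints, function(ct) {
    sphere_constraint(ct$kind, unlist(ct$center), ct$tolerance, ct$weight)
  })
  pharmacophore_model(doc$name, cons,
                      max_omitted = doc$max_omitted %||% 0L,
                      calibration_C = doc$calibration_C)
}

#' Write a fit report as TSV
#' @param fits Tibble with at least `id` and `fit` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
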