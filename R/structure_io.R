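#' Construct a single RNA structure model
#'
#' A `structure_model` holds the atoms of one 3D model: a data frame with one
#' row per atom and columns `atom` (atom name, prime dialect: `C1'` not
#' `C1*`), `resname`, `resno` (integer), `chain`, and Cartesian coordinates
#' `x`, `y`, `z` in Angstrom.
#'
#' @param model_id Unique string label for the model (conventionally
#'   `filename#model_number`).
#' @param atoms Data frame with columns `atom`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z`. Atom names containing `*` are normalized to `'`.
#' @param source_tag Free-text provenance (predictor name, "MD", ...).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, atoms, source_tag = NA_character_) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id))
  required <- c("atom", "resname", "resno", "chain", "x", "y", "z")
  if (!all(required %in% names(atoms))) {
    stop("atoms must have columns: ", paste(required, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$atom <- normalize_atom_name(atoms$atom)
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain <- as.character(atoms$chain)
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model ", model_id)
  if (anyNA(atoms$resno)) stop("non-integer residue numbers in model ", model_id)
  rownames(atoms) <- NULL
  structure(
    list(model_id = model_id, atoms = atoms, source_tag = source_tag),
    class = "structure_model"
  )
}

# "C1*" and "C1'" are the same atom in the two historical PDB dialects
normalize_atom_name <- function(x) gsub("*", "'", trimws(as.character(x)), fixed = TRUE)

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s: %d atoms, %d residues, chains %s\n",
    x$model_id, nrow(x$atoms),
    nrow(unique(x$atoms[c("chain", "resno")])),
    paste(unique(x$atoms$chain), collapse = ",")
  ))
  invisible(x)
}

#' Construct an ordered collection of structure models
#'
#' @param models List of [structure_model()] objects with unique `model_id`s.
#' @return An object of class `structure_collection`; `length()` gives N.
#' @export
structure_collection <- function(models) {
  stopifnot(is.list(models))
  for (m in models) {
    if (!inherits(m, "structure_model")) stop("all elements must be structure_model")
  }
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate model_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(models) <- ids
  structure(list(models = models), class = "structure_collection")
}

#' @export
length.structure_collection <- function(x) length(x$models)

#' @export
`[.structure_collection` <- function(x, i) structure_collection(x$models[i])

#' @export
print.structure_collection <- function(x, ...) {
  cat(sprintf("<structure_collection> N = %d models\n", length(x)))
  invisible(x)
}

#' Model ids of a collection, in collection order
#' @param collection A [structure_collection()].
#' @return Character vector of model ids.
#' @export
model_ids <- function(collection) {
  unname(vapply(collection$models, function(m) m$model_id, character(1)))
}

#' Read one or more multi-model PDB files into a collection
#'
#' Fixed-column PDB parsing of ATOM/HETATM records, split on MODEL/ENDMDL
#' blocks (a file without MODEL records is one implicit model). Only the
#' first alternate location of an atom is kept; element columns may be
#' absent. Atom names are normalized to the prime dialect, residue numbers
#' are taken verbatim from the file.
#'
#' @param paths Character vector of PDB file paths, read in order.
#' @param model_limit Optional integer: keep only the first `model_limit`
#'   models across all files.
#' @param source_tag Provenance tag stored on every model; defaults to the
#'   file name without extension.
#' @return A [structure_collection()] with one model per MODEL record.
#' @export
read_collection <- function(paths, model_limit = NULL, source_tag = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1L)
  models <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    lines <- readLines(path, warn = FALSE)
    tag <- if (is.null(source_tag)) tools::file_path_sans_ext(basename(path)) else source_tag
    blocks <- split_model_blocks(lines)
    for (b in seq_along(blocks)) {
      atoms <- parse_pdb_atoms(blocks[[b]]$lines, path, blocks[[b]]$offset)
      if (nrow(atoms) == 0L) next
      mid <- sprintf("%s#%d", basename(path), blocks[[b]]$number)
      models[[length(models) + 1L]] <- structure_model(mid, atoms, tag)
      if (!is.null(model_limit) && length(models) >= model_limit) {
        return(structure_collection(models))
      }
    }
  }
  if (length(models) == 0L) stop("no models found in: ", paste(paths, collapse = ", "))
  structure_collection(models)
}

split_model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    return(list(list(lines = lines, offset = 0L, number = 1L)))
  }
  ends <- grep("^ENDMDL", lines)
  blocks <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    end <- ends[ends > starts[k]]
    end <- if (length(end)) end[1L] else length(lines) + 1L
    num <- suppressWarnings(as.integer(substr(lines[starts[k]], 11, 14)))
    if (is.na(num)) num <- k
    blocks[[k]] <- list(
      lines = lines[seq(starts[k] + 1L, end - 1L)],
      offset = starts[k],
      number = num
    )
  }
  blocks
}

parse_pdb_atoms <- function(lines, path, offset) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) {
    return(data.frame(
      atom = character(0), resname = character(0), resno = integer(0),
      chain = character(0), x = numeric(0), y = numeric(0), z = numeric(0)
    ))
  }
  ln <- lines[sel]
  lineno <- which(sel) + offset
  altloc <- substr(ln, 17, 17)
  keep <- altloc %in% c(" ", "", "A", "1")
  ln <- ln[keep]
  lineno <- lineno[keep]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (anyNA(v)) {
      stop(sprintf(
        "unparseable %s field in %s at line %d", what, path, lineno[which(is.na(v))[1L]]
      ))
    }
    v
  }
  resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  if (anyNA(resno)) {
    stop(sprintf(
      "unparseable residue number in %s at line %d", path, lineno[which(is.na(resno))[1L]]
    ))
  }
  data.frame(
    atom = substr(ln, 13, 16),
    resname = substr(ln, 18, 20),
    resno = resno,
    chain = substr(ln, 22, 22),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate")
  )
}

# One ATOM record per row; atom names < 4 chars start in column 14 (PDB v3)
format_pdb_atoms <- function(atoms) {
  name <- ifelse(nchar(atoms$atom) < 4L,
                 sprintf(" %-3s", atoms$atom),
                 sprintf("%-4s", atoms$atom))
  sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(atoms)) %% 100000L, name, atoms$resname,
    substr(atoms$chain, 1, 1), atoms$resno, atoms$x, atoms$y, atoms$z
  )
}

#' Write a collection as a multi-model PDB file
#'
#' @param collection A [structure_collection()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_collection <- function(collection, path) {
  stopifnot(inherits(collection, "structure_collection"))
  con <- file(path, "w")
  on.exit(close(con))
  k <- 0L
  for (m in collection$models) {
    k <- k + 1L
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(format_pdb_atoms(m$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a selected sub-collection with multiplicities
#'
#' Writes a multi-model PDB in which each model appears as many times as its
#' multiplicity (models with multiplicity 0 are absent), plus a tab-separated
#' sidecar table `<path>.tsv` with columns `model_id`, `multiplicity`, `E_DA`.
#'
#' @param collection A [structure_collection()] containing every selected model.
#' @param weights A `selection_weights` object (see [unweighted_selection()],
#'   [weighted_selection()]).
#' @param path Output PDB path; the sidecar is written to `paste0(path, ".tsv")`.
#' @param records Optional efficiency records (data frame with `model_id`,
#'   `E_DA`) used to fill the sidecar `E_DA` column.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(collection, weights, path, records = NULL) {
  stopifnot(inherits(collection, "structure_collection"),
            inherits(weights, "selection_weights"))
  ids <- model_ids(collection)
  unknown <- setdiff(weights$table$model_id, ids)
  if (length(unknown)) {
    stop("weights refer to model_ids absent from collection: ",
         paste(unknown, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  k <- 0L
  for (i in seq_len(nrow(weights$table))) {
    mid <- weights$table$model_id[i]
    mult <- weights$table$multiplicity[i]
    if (mult < 1L) next
    atoms <- collection$models[[mid]]$atoms
    for (r in seq_len(mult)) {
      k <- k + 1L
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(format_pdb_atoms(atoms), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  side <- weights$table
  side$E_DA <- if (is.null(records)) {
    NA_real_
  } else {
    records$E_DA[match(side$model_id, records$model_id)]
  }
  utils::write.table(side, paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# coordinate matrix (n x 3) of a model, optionally restricted
model_xyz <- function(model, atom = NULL, resno = NULL, chain = NULL) {
  a <- model$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(atom)) sel <- sel & a$atom %in% atom
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  as.matrix(a[sel, c("x", "y", "z")])
}

# single named atom of one residue; NULL if absent
find_atom <- function(model, chain, resno, atom) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$atom == atom)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Apply a rigid transform to a model
#'
#' @param model A [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return The transformed model (same id and atom table ordering).
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  out <- model
  out$atoms$x <- xyz[, 1]
  out$atoms$y <- xyz[, 2]
  out$atoms$z <- xyz[, 3]
  out
}
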