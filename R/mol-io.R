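# File I/O: PDB receptors, SDF/MOL2/PDB+CONECT ligands, CSV/JSON result
# tables. Parsing of the standard formats is delegated to bio3d and
# ChemmineR; this file only adapts their output to the internal model.

#' Read a receptor structure from a PDB file
#'
#' HETATM records (ligands, waters, cofactors) are excluded from the
#' residue table. Alternate locations are resolved to the highest-occupancy
#' copy of each atom (first wins on ties).
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @param source_id Identifier; defaults to the file name without extension.
#' @return A [protein()].
#' @export
read_protein <- function(path, format = "pdb", source_id = NULL) {
  format <- match.arg(tolower(format), "pdb")
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("PDB file '", path, "' contains no ATOM records")
  # resolve altLoc: keep highest occupancy per (chain, resno, insert, name)
  occ <- a$o
  occ[is.na(occ)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(a)), key)[unique(key)], function(i) {
    i[which.max(occ[i])]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- .norm_element(substr(trimws(a$elety[bad]), 1, 1))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = a$resno, resid = a$resid,
    atom_name = trimws(a$elety), element = .norm_element(elem),
    x = a$x, y = a$y, z = a$z
  )
  protein(atoms, source_id = source_id)
}

#' Read a ligand from SDF, MOL2 or PDB (with CONECT records)
#'
#' Connectivity must come from the file: SDF and MOL2 carry bonds natively;
#' a PDB ligand is accepted only when CONECT records are present. The
#' pipeline never guesses bonds from interatomic distances, because a wrong
#' bond graph silently corrupts symmetry matching.
#'
#' @param path Path to the ligand file.
#' @param format `"sdf"`, `"mol2"` or `"pdb"`; guessed from the extension
#'   when missing.
#' @param index Record index for multi-record SDF files. An SDF holding
#'   several molecules without an explicit `index` is an error.
#' @param name Molecule identifier; defaults to the file name.
#' @return A [molecule()] with hydrogens retained but flagged.
#' @export
read_ligand <- function(path, format = NULL, index = NULL, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- tolower(sub(".*\\.", "", path))
  }
  format <- match.arg(tolower(format), c("sdf", "mol2", "pdb"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         sdf = .read_sdf(path, index, name),
         mol2 = .read_mol2(path, name),
         pdb = .read_pdb_ligand(path, name))
}

.read_sdf <- function(path, index, name) {
  set <- ChemmineR::read.SDFset(path)
  if (length(set) > 1 && is.null(index)) {
    stop("SDF file '", path, "' holds ", length(set),
         " records; pass `index` to pick one")
  }
  if (is.null(index)) index <- 1L
  sdf <- set[[index]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = elem, name = rownames(ab),
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      is_hydrogen = elem == "H")
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  rownames(atoms) <- NULL
  molecule(atoms, bonds, name = name)
}

.read_mol2 <- function(path, name) {
  m <- bio3d::read.mol2(path)
  a <- m$atom
  elem <- .norm_element(a$elety)
  atoms <- data.frame(element = elem, name = a$elena,
                      x = a$x, y = a$y, z = a$z,
                      is_hydrogen = elem == "H")
  ord <- .mol2_order(m$bond$type)
  bonds <- data.frame(i = as.integer(m$bond$origin),
                      j = as.integer(m$bond$target),
                      order = ord)
  molecule(atoms, bonds, name = name)
}

# SYBYL bond types -> internal order codes; amide bonds are single bonds
# (the amide pattern is recognised structurally by rotatable_bond_count).
.mol2_order <- function(type) {
  type <- as.character(type)
  ord <- rep(1L, length(type))
  ord[type == "2"] <- 2L
  ord[type == "3"] <- 3L
  ord[type == "ar"] <- 4L
  ord
}

# Minimal PDB ligand reader: HETATM/ATOM coordinates plus CONECT topology.
# bio3d does not expose CONECT records, hence the fixed-column parsing here.
.read_pdb_ligand <- function(path, name) {
  lines <- readLines(path)
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  con <- grep("^CONECT", lines, value = TRUE)
  if (!length(at)) stop("PDB file '", path, "' contains no atom records")
  if (!length(con)) {
    stop("PDB file '", path, "' has no CONECT records; ligands need bond ",
         "information - supply SDF or MOL2 instead")
  }
  serial <- as.integer(substr(at, 7, 11))
  elem <- trimws(substr(at, 77, 78))
  nm <- trimws(substr(at, 13, 16))
  elem[elem == ""] <- .norm_element(substr(nm[elem == ""], 1, 1))
  atoms <- data.frame(
    element = .norm_element(elem), name = nm,
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    is_hydrogen = .norm_element(elem) == "H"
  )
  lookup <- stats::setNames(seq_along(serial), serial)
  pairs <- do.call(rbind, lapply(con, function(l) {
    f <- as.integer(substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5)))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  }))
  i <- lookup[as.character(pairs[, 1])]
  j <- lookup[as.character(pairs[, 2])]
  ok <- !is.na(i) & !is.na(j)
  b <- unique(data.frame(i = pmin(i[ok], j[ok]), j = pmax(i[ok], j[ok]),
                         order = 1L))
  molecule(atoms, b, name = name)
}

#' Write a result table to CSV or JSON
#'
#' Written tables round-trip: reading the file back yields the same values
#' (to the usual text precision of the format).
#'
#' @param table Non-empty data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when
#'   missing.
#' @export
write_results <- function(table, path, format = NULL) {
  if (!is.data.frame(table) || !nrow(table)) stop("empty result table")
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  format <- match.arg(tolower(format), c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return Data frame.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  format <- match.arg(tolower(format), c("csv", "json"))
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
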