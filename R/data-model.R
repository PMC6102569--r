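# Internal data model: small ligands, receptors, reference complexes and
# ranked pose ensembles. Plain lists with light S3 classes, in the style of
# bio3d objects; all coordinates in Angstrom.

#' Construct a small-molecule object
#'
#' A molecule is an element-labelled, bonded atom graph with 3D coordinates.
#' Bond orders are integer codes: 1 (single), 2 (double), 3 (triple),
#' 4 (aromatic).
#'
#' @param atoms Data frame with columns `element` (symbol), `name` (atom
#'   label), `x`, `y`, `z` (A) and `is_hydrogen` (logical). `name` and
#'   `is_hydrogen` are filled in when missing.
#' @param bonds Data frame with columns `i`, `j` (atom indices), `order`
#'   (1/2/3/4) and optionally `in_ring` (computed from the graph when
#'   absent).
#' @param name Identifier, e.g. `"h1"`.
#' @return Object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, name = "ligand") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("molecule '", name, "': non-finite coordinates")
  if (sum(!atoms$is_hydrogen) < 1) {
    stop("molecule '", name, "': needs at least one heavy atom")
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        in_ring = logical())
  }
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop("bond with identical endpoints")
    if (any(bonds$i < 1 | bonds$j < 1 |
            bonds$i > nrow(atoms) | bonds$j > nrow(atoms))) {
      stop("bond references a non-existent atom")
    }
    # store as unordered pairs, i < j
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")])) stop("duplicated bond")
    if (is.null(bonds$in_ring)) bonds$in_ring <- .ring_bonds(bonds, nrow(atoms))
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molecule")
}

# A bond is in a ring iff it is not a bridge of the bond graph.
.ring_bonds <- function(bonds, n_atoms) {
  if (!nrow(bonds)) return(logical())
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule '", x$name, "': ", nrow(x$atoms), " atoms (",
      sum(!x$atoms$is_hydrogen), " heavy), ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

#' Atom coordinates of a molecule
#'
#' @param mol A [molecule()].
#' @param heavy_only Drop hydrogens?
#' @return Numeric matrix, one row per atom, columns x/y/z.
#' @export
mol_coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[!a$is_hydrogen, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Indices of heavy atoms
#' @param mol A [molecule()].
#' @return Integer vector.
#' @export
heavy_atoms <- function(mol) which(!mol$atoms$is_hydrogen)

#' Construct a protein structure
#'
#' Receptors are stored as a flat atom table (one row per atom) in file
#' order, with residues identified by `(chain, resno)`; this mirrors how
#' PDB entries are cited. Residue numbering is taken verbatim from the
#' source file.
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer),
#'   `resid` (3-letter code), `atom_name`, `element`, `x`, `y`, `z`.
#' @param source_id Identifier, e.g. a PDB code.
#' @return Object of class `protein`.
#' @export
protein <- function(atoms, source_id = "protein") {
  stopifnot(is.data.frame(atoms))
  if (!nrow(atoms)) stop("protein '", source_id, "': no atoms")
  need <- c("chain", "resno", "resid", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("protein atoms lack column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("protein '", source_id, "': non-finite coordinates")
  }
  key <- paste(atoms$chain, atoms$resno)
  # residues must form contiguous blocks and (chain, resno) must be unique
  blocks <- rle(key)$values
  if (anyDuplicated(blocks)) {
    stop("protein '", source_id,
         "': duplicated residue key(s): ",
         paste(unique(blocks[duplicated(blocks)]), collapse = ", "))
  }
  structure(list(atoms = atoms, source_id = source_id), class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  cat("protein '", x$source_id, "': ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

#' Residue keys of a protein
#' @param prot A [protein()].
#' @return Data frame with `chain`, `resno`, `resid`, one row per residue.
#' @export
residue_keys <- function(prot) {
  a <- prot$atoms
  unique(a[, c("chain", "resno", "resid")])
}

#' Construct a reference protein-ligand complex
#'
#' The reference ligand carries the crystallographic coordinates against
#' which docked poses are judged. The constructor checks that the ligand
#' actually sits on the protein (at least one heavy atom within 10 A of a
#' protein atom).
#'
#' @param protein A [protein()].
#' @param ligand A [molecule()] in the crystallographic frame.
#' @param id Complex identifier.
#' @return Object of class `ref_complex`.
#' @export
ref_complex <- function(protein, ligand, id = ligand$name) {
  stopifnot(inherits(protein, "protein"), inherits(ligand, "molecule"))
  lig <- mol_coords(ligand, heavy_only = TRUE)
  pro <- as.matrix(protein$atoms[, c("x", "y", "z")])
  if (.min_cross_dist(lig, pro) > 10) {
    stop("complex '", id, "': reference ligand has no heavy atom within ",
         "10 A of the protein")
  }
  structure(list(protein = protein, ligand = ligand, id = id),
            class = "ref_complex")
}

# minimum distance between two point sets (chunked to bound memory)
.min_cross_dist <- function(a, b) {
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(m, min(d2))
  }
  sqrt(m)
}

#' Construct a ranked pose ensemble
#'
#' One ensemble holds the scored conformers of one ligand docked into one
#' receptor for one method and replicate. Poses are kept in ascending score
#' order (lower = better, as for Glide and AutoDock energies); ties are
#' broken by input order (stable).
#'
#' @param mol The ligand [molecule()] (supplies the bond graph; pose
#'   coordinates are conformers of this graph).
#' @param poses List of poses; each pose is a list with `coords` (full-atom
#'   coordinate matrix, rows matching `mol$atoms`) and `score` (finite
#'   numeric). `true_rmsd` is optional and usually filled by
#'   [evaluate_ensemble()] or by the synthetic generator.
#' @param ligand_id,receptor_id,method,replicate Grouping labels.
#' @return Object of class `pose_ensemble`; poses carry `rank` 1..n.
#' @export
pose_ensemble <- function(mol, poses, ligand_id = mol$name,
                          receptor_id = ligand_id, method = "method",
                          replicate = 1L) {
  stopifnot(inherits(mol, "molecule"), is.list(poses))
  if (!length(poses)) stop("empty pose list")
  scores <- vapply(poses, function(p) as.numeric(p$score), numeric(1))
  if (!all(is.finite(scores))) stop("non-finite pose score")
  ord <- order(scores)                       # stable for ties
  poses <- poses[ord]
  for (k in seq_along(poses)) {
    poses[[k]]$rank <- k
    if (is.null(poses[[k]]$true_rmsd)) poses[[k]]$true_rmsd <- NA_real_
    cc <- poses[[k]]$coords
    if (!is.null(cc) && nrow(cc) != nrow(mol$atoms)) {
      stop("pose ", k, ": coordinate rows do not match the molecule")
    }
  }
  structure(list(molecule = mol, poses = poses, ligand_id = ligand_id,
                 receptor_id = receptor_id, method = method,
                 replicate = as.integer(replicate)),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat("pose_ensemble: ligand ", x$ligand_id, " in ", x$receptor_id,
      " [", x$method, ", replicate ", x$replicate, "], ",
      length(x$poses), " poses\n", sep = "")
  invisible(x)
}

#' Scores, ranks and RMSDs of an ensemble as a data frame
#' @param x A [pose_ensemble()].
#' @param ... Unused.
#' @return Data frame with one row per pose.
#' @export
as.data.frame.pose_ensemble <- function(x, ...) {
  data.frame(
    ligand_id = x$ligand_id, receptor_id = x$receptor_id,
    method = x$method, replicate = x$replicate,
    rank = vapply(x$poses, `[[`, integer(1), "rank"),
    score = vapply(x$poses, function(p) p$score, numeric(1)),
    true_rmsd = vapply(x$poses, function(p) p$true_rmsd, numeric(1))
  )
}
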