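# Ligand descriptors used alongside the pocket metrics: molecular weight
# from standard average atomic masses and a rotatable-bond count.

#' Molecular weight from standard average atomic masses
#'
#' Sums the masses of all atoms, hydrogens included. Hydrogens must be
#' explicit in the structure; the package refuses to guess implicit
#' hydrogens from valence because silent valence errors would go
#' unnoticed. A molecule carrying no hydrogens at all triggers a warning.
#'
#' @param mol A [molecule()].
#' @return Weight in g/mol.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (!any(mol$atoms$is_hydrogen) && nrow(mol$atoms) > 3) {
    warning("molecule '", mol$name, "' has no explicit hydrogens; ",
            "molecular_weight() sums only the atoms present")
  }
  sum(element_mass(mol$atoms$element))
}

#' Count rotatable bonds
#'
#' A bond rotates freely when it is (i) a non-ring single bond between two
#' heavy atoms, (ii) neither end is terminal (heavy-atom degree 1),
#' (iii) neither end participates in a triple bond (the axis through a
#' C#C or C#N unit adds no conformational freedom), and (iv) the bond is
#' not an amide C-N bond (the C carries a double-bonded O and binds the
#' N), whose partial double-bond character locks it. The amide exclusion
#' can be toggled for comparison with other conventions.
#'
#' @param mol A [molecule()] with bond orders populated.
#' @param exclude_amide Drop amide C-N bonds (default TRUE)?
#' @return Integer count.
#' @export
rotatable_bond_count <- function(mol, exclude_amide = TRUE) {
  stopifnot(inherits(mol, "molecule"))
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  if (anyNA(b$order)) stop("bond orders missing")
  atoms <- mol$atoms
  heavy <- !atoms$is_hydrogen
  hb <- b[heavy[b$i] & heavy[b$j], , drop = FALSE]
  if (!nrow(hb)) return(0L)
  n <- nrow(atoms)
  deg <- tabulate(c(hb$i, hb$j), nbins = n)        # heavy-atom degree
  in_triple <- rep(FALSE, n)
  tr <- hb[hb$order == 3, , drop = FALSE]
  in_triple[c(tr$i, tr$j)] <- TRUE
  is_amide_cn <- function(i, j) {
    # one end carbon double-bonded to oxygen, other end nitrogen
    test <- function(c_at, n_at) {
      if (atoms$element[c_at] != "C" || atoms$element[n_at] != "N") {
        return(FALSE)
      }
      dbl <- hb[(hb$i == c_at | hb$j == c_at) & hb$order == 2, , drop = FALSE]
      if (!nrow(dbl)) return(FALSE)
      other <- ifelse(dbl$i == c_at, dbl$j, dbl$i)
      any(atoms$element[other] == "O")
    }
    test(i, j) || test(j, i)
  }
  count <- 0L
  for (k in seq_len(nrow(hb))) {
    i <- hb$i[k]; j <- hb$j[k]
    if (hb$order[k] != 1L) next
    if (hb$in_ring[k]) next
    if (deg[i] <= 1L || deg[j] <= 1L) next
    if (in_triple[i] || in_triple[j]) next
    if (exclude_amide && is_amide_cn(i, j)) next
    count <- count + 1L
  }
  count
}

#' Descriptor set of a ligand
#' @param mol A [molecule()].
#' @return List with `molecular_weight` and `n_rotatable_bonds`.
#' @export
descriptor_set <- function(mol) {
  list(molecular_weight = molecular_weight(mol),
       n_rotatable_bonds = rotatable_bond_count(mol))
}
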