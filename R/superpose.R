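# Binding-site definition and rigid receptor superposition. Cross-docking
# RMSD is only meaningful after the mobile receptor frame is mapped onto
# the reference frame; the mapping is a least-squares (Kabsch) fit on the
# C-alpha atoms of the binding-site residues. Self-docking uses the
# identity transform, so both paths share one code path downstream.

#' Select the binding site of a reference complex
#'
#' A residue belongs to the binding site iff any of its atoms lies within
#' `cutoff` of any heavy atom of the reference ligand (the most inclusive
#' reading of a distance shell around the ligand).
#'
#' @param complex A [ref_complex()].
#' @param cutoff Shell radius in Angstrom (default 10).
#' @return Object of class `binding_site`: a data frame of residue keys
#'   (`chain`, `resno`, `resid`) with attribute `cutoff`.
#' @export
select_binding_site <- function(complex, cutoff = 10.0) {
  stopifnot(inherits(complex, "ref_complex"), cutoff > 0)
  lig <- mol_coords(complex$ligand, heavy_only = TRUE)
  a <- complex$protein$atoms
  near <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(lig))) {
    d2 <- (a$x - lig[i, 1])^2 + (a$y - lig[i, 2])^2 + (a$z - lig[i, 3])^2
    near <- near | d2 <= cutoff^2
  }
  keys <- unique(a[near, c("chain", "resno", "resid")])
  if (!nrow(keys)) {
    stop("empty binding site: no residue within ", cutoff,
         " A of the reference ligand")
  }
  rownames(keys) <- NULL
  structure(keys, cutoff = cutoff, class = c("binding_site", "data.frame"))
}

#' Pair binding-site C-alpha atoms between two structures of one protein
#'
#' Residues are paired by identical `(chain, resno, resid)`; there is no
#' sequence-alignment fallback because both structures are crystal forms of
#' the same protein. Selected residues missing from either structure,
#' disagreeing in residue name, or lacking a C-alpha are dropped with a
#' warning rather than guessed.
#'
#' @param ref,mobile [protein()] structures of the same protein.
#' @param sel A `binding_site` selection from [select_binding_site()].
#' @return List with matrices `ref_xyz` and `mobile_xyz` (one row per
#'   paired C-alpha) and the data frame `keys` of paired residues.
#' @export
pair_binding_site_residues <- function(ref, mobile, sel) {
  stopifnot(inherits(ref, "protein"), inherits(mobile, "protein"))
  ca <- function(prot, chain, resno) {
    a <- prot$atoms
    hit <- which(a$chain == chain & a$resno == resno & a$atom_name == "CA")
    if (!length(hit)) return(NULL)
    list(xyz = c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]]),
         resid = a$resid[which(a$chain == chain & a$resno == resno)[1]])
  }
  rx <- list(); mx <- list(); kept <- integer(); dropped <- character()
  for (k in seq_len(nrow(sel))) {
    r <- ca(ref, sel$chain[k], sel$resno[k])
    m <- ca(mobile, sel$chain[k], sel$resno[k])
    lab <- paste0(sel$chain[k], sel$resno[k])
    if (is.null(r) || is.null(m)) {
      dropped <- c(dropped, paste0(lab, " (missing CA)"))
    } else if (r$resid != m$resid) {
      dropped <- c(dropped, paste0(lab, " (residue name mismatch: ",
                                   r$resid, " vs ", m$resid, ")"))
    } else {
      rx[[length(rx) + 1]] <- r$xyz
      mx[[length(mx) + 1]] <- m$xyz
      kept <- c(kept, k)
    }
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " binding-site residue pair(s): ",
            paste(dropped, collapse = ", "))
  }
  if (length(kept) < 3) {
    stop("only ", length(kept),
         " C-alpha pair(s); superposition needs at least 3")
  }
  list(ref_xyz = do.call(rbind, rx), mobile_xyz = do.call(rbind, mx),
       keys = sel[kept, , drop = FALSE])
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Returns the proper rotation `R` and translation `t` minimising the RMSD
#' of `R %*% mobile + t` against the reference points. Reflections are
#' excluded by the usual determinant correction of the SVD solution.
#'
#' @param pairs Either the list returned by [pair_binding_site_residues()]
#'   or a list with matrices `ref_xyz` and `mobile_xyz` of equal size
#'   (>= 3 non-collinear rows).
#' @return Object of class `rigid_transform` with fields `rotation` (3x3,
#'   det +1 within 1e-8), `translation` (length 3) and `fit_rmsd` (A).
#' @export
kabsch_superpose <- function(pairs) {
  X <- pairs$mobile_xyz
  Y <- pairs$ref_xyz
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)))
  if (nrow(X) < 3) stop("need at least 3 point pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  # collinear point sets leave the rotation about the line undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) point set; superposition under-determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cy - R %*% cx)
  res <- Yc - Xc %*% t(R)
  fit_rmsd <- sqrt(mean(rowSums(res^2)))
  new_rigid_transform(R, tr, fit_rmsd)
}

new_rigid_transform <- function(rotation, translation, fit_rmsd = NA_real_) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation matrix is not proper (det != +1)")
  }
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthonormal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 fit_rmsd = fit_rmsd),
            class = "rigid_transform")
}

#' The identity rigid transform
#' @return A `rigid_transform` leaving coordinates unchanged.
#' @export
identity_transform <- function() new_rigid_transform(diag(3), c(0, 0, 0), 0)

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  new_rigid_transform(R, -R %*% transform$translation, transform$fit_rmsd)
}

#' Apply a rigid transform to coordinates, a molecule or a protein
#'
#' Maps every coordinate x to `R x + t`; the input object is not modified.
#'
#' @param transform A `rigid_transform`.
#' @param x Coordinate matrix (n x 3), [molecule()] or [protein()].
#' @return Transformed copy of `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  tx <- function(m) {
    sweep(m %*% t(transform$rotation), 2, -transform$translation)
  }
  if (is.matrix(x)) return(tx(x))
  if (inherits(x, "molecule")) {
    xyz <- tx(as.matrix(x$atoms[, c("x", "y", "z")]))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  if (inherits(x, "protein")) {
    xyz <- tx(as.matrix(x$atoms[, c("x", "y", "z")]))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  stop("cannot transform object of class ", paste(class(x), collapse = "/"))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: fit RMSD",
      if (is.na(x$fit_rmsd)) "NA" else sprintf("%.4f A", x$fit_rmsd), "\n")
  invisible(x)
}
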