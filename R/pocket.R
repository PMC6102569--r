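# Grid-based binding-site detection and the pocket metrics BSV (binding
# site volume), VD (summed point depth) and averaged VD. The procedure is
# morphological: a probe sphere explores the solvent from outside the
# structure; empty grid points the probe cannot cover are pocket points,
# and each point's depth is its distance to the probe surface.

#' Configuration of the pocket grid
#'
#' Defaults follow the published POCASA-style settings: 1 A grid, 1 A
#' probe, single point flag 12 and protein depth flag 18. In this package
#' the single point flag is the minimum number of grid points a pocket
#' component must have, and the protein depth flag caps the allowed point
#' depth in grid units; both are interpretations of the original flags and
#' are plain knobs here.
#'
#' @param grid_spacing Grid step (A).
#' @param probe_radius Probe sphere radius (A).
#' @param single_point_flag Minimum component size (points).
#' @param protein_depth_flag Maximum point depth (grid units).
#' @param max_grid_points Memory guard; grids larger than this error out
#'   with a suggestion to coarsen the spacing.
#' @return List of class `pocket_grid_config`.
#' @export
pocket_grid_config <- function(grid_spacing = 1.0, probe_radius = 1.0,
                               single_point_flag = 12,
                               protein_depth_flag = 18,
                               max_grid_points = 2e7) {
  stopifnot(grid_spacing > 0, probe_radius > 0, single_point_flag > 0,
            protein_depth_flag > 0)
  structure(list(grid_spacing = grid_spacing, probe_radius = probe_radius,
                 single_point_flag = single_point_flag,
                 protein_depth_flag = protein_depth_flag,
                 max_grid_points = max_grid_points),
            class = "pocket_grid_config")
}

#' Detect pockets of a protein structure on a 3D grid
#'
#' The algorithm: (i) lay a grid over the structure's bounding box plus a
#' probe margin; (ii) mark protein points (inside the van der Waals
#' surface of any heavy atom); (iii) flood-fill the positions where a
#' probe sphere fits, starting from the box boundary, and dilate them by
#' the probe radius to obtain the probe-covered region; (iv) pocket points
#' are empty points the probe never covers; (v) split into 6-connected
#' components; (vi) drop points deeper than the protein depth flag and
#' components smaller than the single point flag. Components are returned
#' sorted by VD, largest first.
#'
#' @param prot A [protein()] (hydrogens are ignored).
#' @param config A [pocket_grid_config()].
#' @return List of `pocket` objects, each with `points` (n x 3 matrix of
#'   grid-point coordinates, A), `depths` (A, distance to the probe
#'   surface) and `spacing`.
#' @export
detect_pockets <- function(prot, config = pocket_grid_config()) {
  stopifnot(inherits(prot, "protein"), inherits(config, "pocket_grid_config"))
  a <- prot$atoms[prot$atoms$element != "H", , drop = FALSE]
  if (!nrow(a)) stop("protein has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element)
  h <- config$grid_spacing
  rp <- config$probe_radius
  margin <- rp + max(radii) + 2 * h
  lo <- floor((apply(xyz, 2, min) - margin) / h) * h
  hi <- ceiling((apply(xyz, 2, max) + margin) / h) * h
  dim <- as.integer(round((hi - lo) / h)) + 1L
  if (prod(dim) > config$max_grid_points) {
    stop("grid of ", prod(dim), " points exceeds the budget of ",
         config$max_grid_points, "; use a coarser grid_spacing")
  }
  clear <- clearance_field(dim, lo, h, xyz, radii, cap = rp + 2 * h)
  empty <- clear >= 0
  allowed <- clear >= rp
  acc <- flood_from_boundary(allowed, dim)
  d_acc <- h * sqrt(edt_sq(acc, dim))
  covered <- d_acc <= rp + 1e-9
  pocket_mask <- empty & !covered
  depth <- d_acc - rp
  # protein depth flag: cap on point depth, in grid units
  pocket_mask <- pocket_mask & depth <= config$protein_depth_flag * h + 1e-9
  if (!any(pocket_mask)) return(list())
  labs <- label_components(pocket_mask, dim)
  idx <- which(pocket_mask)
  comp <- split(idx, labs[idx])
  comp <- comp[lengths(comp) >= config$single_point_flag]
  if (!length(comp)) return(list())
  pockets <- lapply(comp, function(ii) {
    i0 <- ii - 1L
    ix <- i0 %% dim[1]
    iy <- (i0 %/% dim[1]) %% dim[2]
    iz <- i0 %/% (dim[1] * dim[2])
    pts <- cbind(x = lo[1] + h * ix, y = lo[2] + h * iy, z = lo[3] + h * iz)
    structure(list(points = pts, depths = depth[ii], spacing = h),
              class = "pocket")
  })
  vd <- vapply(pockets, function(p) sum(p$depths), numeric(1))
  pockets <- pockets[order(vd, decreasing = TRUE)]
  names(pockets) <- NULL
  pockets
}

#' @export
print.pocket <- function(x, ...) {
  m <- pocket_metrics(x)
  cat(sprintf("pocket: %d points, BSV %.1f A^3, VD %.1f, averaged VD %.3f\n",
              nrow(x$points), m$bsv, m$vd, m$averaged_vd))
  invisible(x)
}

#' Volume and depth metrics of one pocket
#'
#' BSV is the number of pocket points times the grid cell volume; VD sums
#' the point depths; averaged VD is their mean. These identities hold
#' exactly by construction.
#'
#' @param pocket A `pocket` from [detect_pockets()].
#' @param config Unused placeholder for future weighting schemes.
#' @return List of class `pocket_metrics`: `bsv` (A^3), `vd` (A x points),
#'   `averaged_vd` (A), `n_points`.
#' @export
pocket_metrics <- function(pocket, config = NULL) {
  stopifnot(inherits(pocket, "pocket"))
  n <- nrow(pocket$points)
  if (!n) stop("empty pocket")
  vd <- sum(pocket$depths)
  structure(list(bsv = n * pocket$spacing^3, vd = vd,
                 averaged_vd = vd / n, n_points = n),
            class = "pocket_metrics")
}

#' Pick the pocket hosting a ligand
#'
#' Returns the pocket with the largest number of points within 2 A of any
#' heavy atom of the ligand; overlap, not size, decides.
#'
#' @param pockets List of pockets from [detect_pockets()].
#' @param ligand A [molecule()] in the same frame as the protein.
#' @param contact Distance defining overlap (A, default 2).
#' @return The overlapping `pocket`; error if no pocket overlaps.
#' @export
ligand_pocket <- function(pockets, ligand, contact = 2.0) {
  if (!length(pockets)) stop("no pockets detected")
  lig <- mol_coords(ligand, heavy_only = TRUE)
  ov <- vapply(pockets, function(p) {
    near <- rep(FALSE, nrow(p$points))
    for (i in seq_len(nrow(lig))) {
      d2 <- (p$points[, 1] - lig[i, 1])^2 + (p$points[, 2] - lig[i, 2])^2 +
        (p$points[, 3] - lig[i, 3])^2
      near <- near | d2 <= contact^2
    }
    sum(near)
  }, numeric(1))
  if (max(ov) == 0) {
    stop("ligand does not overlap any detected pocket")
  }
  pockets[[which.max(ov)]]
}
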