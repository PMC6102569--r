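# Best-solution statistics: s2/s3 scoring positions, BS annotation,
# recurrence-per-position tables, cross-docking matrices, and pose
# selection constrained by essential interactions (ECIDALs).

#' Fill in the true RMSD of every pose in an ensemble
#'
#' Each pose is mapped into the reference frame (identity for
#' self-docking, the receptor superposition for cross-docking) and scored
#' with [symmetry_min_rmsd()] against the crystallographic ligand. Pose
#' order is unchanged.
#'
#' @param ensemble A [pose_ensemble()].
#' @param reference A [ref_complex()] or the reference [molecule()] itself.
#' @param transform Receptor-level `rigid_transform`; default identity.
#' @return The ensemble with `true_rmsd` set on every pose.
#' @export
evaluate_ensemble <- function(ensemble, reference,
                              transform = identity_transform()) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  ref_mol <- if (inherits(reference, "ref_complex")) reference$ligand
             else reference
  stopifnot(inherits(ref_mol, "molecule"))
  mol <- ensemble$molecule
  if (nrow(mol$atoms[!mol$atoms$is_hydrogen, ]) !=
      nrow(ref_mol$atoms[!ref_mol$atoms$is_hydrogen, ])) {
    stop("ensemble ", ensemble$ligand_id, "/", ensemble$receptor_id,
         ": pose molecule and reference ligand differ in heavy-atom count")
  }
  auts <- automorphisms(mol)
  hv_ref <- heavy_atoms(ref_mol)
  ref_xyz <- matrix(NA_real_, nrow(mol$atoms), 3)
  ref_xyz[heavy_atoms(mol), ] <- mol_coords(ref_mol, heavy_only = TRUE)
  for (k in seq_along(ensemble$poses)) {
    p <- ensemble$poses[[k]]
    if (is.null(p$coords)) {
      stop("ensemble ", ensemble$ligand_id, "/", ensemble$receptor_id,
           ": pose ", k, " has no coordinates")
    }
    moved <- apply_transform(transform, p$coords)
    r <- tryCatch(
      symmetry_min_rmsd(moved, ref_xyz, mol, auts = auts),
      error = function(e) {
        stop("ensemble ", ensemble$ligand_id, "/", ensemble$receptor_id,
             " [", ensemble$method, ", replicate ", ensemble$replicate,
             "], pose ", k, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    ensemble$poses[[k]]$true_rmsd <- r$rmsd
  }
  ensemble
}

#' Best-solution scoring position under the s2 or s3 criterion
#'
#' s2 takes the best-scored pose of the good class (RMSD within the 2 A
#' threshold); s3 also admits acceptable poses (within 3 A). When no pose
#' in the ensemble complies, the instance is a bad solution (BS) and the
#' position is `NA`.
#'
#' @param ensemble A [pose_ensemble()] with `true_rmsd` filled.
#' @param criterion `"s2"` or `"s3"`.
#' @param tau_good,tau_bad,good_inclusive Passed to [classify_rmsd()].
#' @return Object of class `best_solution`: a one-row data frame with
#'   `ligand_id`, `receptor_id`, `method`, `replicate`, `criterion`,
#'   `position` (integer or `NA`) and `bs` (logical).
#' @export
best_solution_position <- function(ensemble, criterion = c("s2", "s3"),
                                   tau_good = 2.0, tau_bad = 3.0,
                                   good_inclusive = TRUE) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  criterion <- match.arg(criterion)
  rmsd <- vapply(ensemble$poses, function(p) p$true_rmsd, numeric(1))
  if (anyNA(rmsd)) {
    stop("true_rmsd missing; run evaluate_ensemble() first")
  }
  cls <- classify_rmsd(rmsd, tau_good, tau_bad, good_inclusive)
  ok <- if (criterion == "s2") cls == "good" else cls != "bad"
  pos <- if (any(ok)) which(ok)[1] else NA_integer_
  out <- data.frame(ligand_id = ensemble$ligand_id,
                    receptor_id = ensemble$receptor_id,
                    method = ensemble$method,
                    replicate = ensemble$replicate,
                    criterion = criterion,
                    position = as.integer(pos),
                    bs = is.na(pos))
  class(out) <- c("best_solution", "data.frame")
  out
}

#' Stack best-solution results into one table
#' @param results List of `best_solution` rows (or a data frame already).
#' @return Data frame with one row per evaluation instance.
#' @export
best_solution_table <- function(results) {
  if (is.data.frame(results)) return(as.data.frame(results))
  do.call(rbind, lapply(results, as.data.frame))
}

#' Recurrence of the best solution at each scoring position
#'
#' For every group, the percentage of evaluation instances whose best
#' solution sits at scoring position 1..`top_n`, plus the BS percentage.
#' Every replicate counts as one instance. Percentages sum to 100 within
#' numerical noise.
#'
#' @param results `best_solution` rows (list or stacked data frame).
#' @param grouping Character vector of grouping columns, e.g.
#'   `c("method")` or `c("ligand_id", "method")`; empty for one pooled
#'   table.
#' @param top_n Number of scoring positions (default 10).
#' @return Data frame with columns `grouping`..., `position` (factor
#'   `"1"`..`"BS"`), `count`, `percent`, `n_instances`.
#' @export
recurrence_table <- function(results, grouping = character(), top_n = 10) {
  df <- best_solution_table(results)
  if (is.null(df) || !nrow(df)) stop("no results to tabulate")
  if (any(!is.na(df$position) & df$position > top_n)) {
    stop("a result sits beyond position ", top_n,
         "; raise `top_n` to match the ensembles")
  }
  levs <- c(as.character(seq_len(top_n)), "BS")
  df$.pos <- factor(ifelse(df$bs, "BS", as.character(df$position)),
                    levels = levs)
  if (length(grouping)) {
    sp <- split(df, df[grouping], drop = TRUE)
  } else {
    sp <- list(all = df)
  }
  out <- do.call(rbind, lapply(sp, function(g) {
    n <- nrow(g)
    cnt <- table(g$.pos)
    base <- g[rep(1, length(levs)), grouping, drop = FALSE]
    cbind(base,
          data.frame(position = factor(levs, levels = levs),
                     count = as.integer(cnt),
                     percent = 100 * as.integer(cnt) / n,
                     n_instances = n))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-docking matrix of good and bad solutions
#'
#' One cell per (ligand, receptor): `self` on the diagonal pairs,
#' `good_found` when at least one replicate found a solution under the s2
#' criterion, `bs_only` otherwise. Self cells also carry the best
#' (smallest) scoring position over replicates.
#'
#' @param results s2 `best_solution` rows for every (ligand, receptor)
#'   combination, all replicates.
#' @param self_pairs Data frame with columns `ligand_id`, `receptor_id`
#'   naming each ligand's own receptor.
#' @return Data frame with `ligand_id`, `receptor_id`, `category`,
#'   `best_position` (NA unless any replicate found a solution).
#' @export
cross_dock_matrix <- function(results, self_pairs) {
  df <- best_solution_table(results)
  stopifnot(all(c("ligand_id", "receptor_id") %in% names(self_pairs)))
  ligs <- unique(df$ligand_id)
  recs <- unique(df$receptor_id)
  full <- expand.grid(ligand_id = ligs, receptor_id = recs,
                      stringsAsFactors = FALSE)
  have <- unique(df[, c("ligand_id", "receptor_id")])
  missing <- full[!paste(full$ligand_id, full$receptor_id) %in%
                    paste(have$ligand_id, have$receptor_id), ]
  if (nrow(missing)) {
    stop("no evaluated ensemble for cell(s): ",
         paste(paste0(missing$ligand_id, "/", missing$receptor_id),
               collapse = ", "))
  }
  selfkey <- paste(self_pairs$ligand_id, self_pairs$receptor_id)
  out <- do.call(rbind, lapply(seq_len(nrow(full)), function(k) {
    cell <- df[df$ligand_id == full$ligand_id[k] &
                 df$receptor_id == full$receptor_id[k], ]
    found <- any(!cell$bs)
    best <- if (found) min(cell$position, na.rm = TRUE) else NA_integer_
    cat_ <- if (paste(full$ligand_id[k], full$receptor_id[k]) %in% selfkey) {
      "self"
    } else if (found) "good_found" else "bs_only"
    data.frame(ligand_id = full$ligand_id[k],
               receptor_id = full$receptor_id[k],
               category = cat_, best_position = best)
  }))
  rownames(out) <- NULL
  out
}

#' Define an essential-interaction (ECIDAL) distance constraint
#'
#' A constraint names one ligand atom and one protein atom and the maximum
#' distance allowed between them in a compliant pose.
#'
#' @param ligand_atom Ligand atom name (character) or index (integer).
#' @param chain,res_number,atom_name Protein atom selector.
#' @param max_distance Maximum allowed distance (A), > 0.
#' @return Object of class `ecidal_constraint`.
#' @export
ecidal_constraint <- function(ligand_atom, chain, res_number, atom_name,
                              max_distance) {
  stopifnot(max_distance > 0)
  structure(list(ligand_atom = ligand_atom, chain = chain,
                 res_number = res_number, atom_name = atom_name,
                 max_distance = max_distance),
            class = "ecidal_constraint")
}

#' Select the best-scored pose complying with every ECIDAL constraint
#'
#' Implements best-solution selection by the most negative scoring energy
#' that satisfies the essential interactions: poses are visited in score
#' order and the first fully compliant one is returned. With no
#' constraints this reduces to plain top-score selection.
#'
#' @param ensemble A [pose_ensemble()].
#' @param constraints List of [ecidal_constraint()]s (possibly empty).
#' @param protein The receptor [protein()] in the same frame as the poses.
#' @return The selected pose (a list with `coords`, `score`, `rank`). When
#'   no pose complies, an object of class `ecidal_no_match` whose
#'   `violations` element tabulates every pose/constraint distance.
#' @export
select_best_with_ecidals <- function(ensemble, constraints, protein) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  if (length(constraints) == 0) return(ensemble$poses[[1]])
  mol <- ensemble$molecule
  lig_idx <- vapply(constraints, function(con) {
    i <- if (is.character(con$ligand_atom)) {
      which(mol$atoms$name == con$ligand_atom)
    } else as.integer(con$ligand_atom)
    if (length(i) != 1 || is.na(i) || i < 1 || i > nrow(mol$atoms)) {
      stop("ligand atom selector '", con$ligand_atom,
           "' resolves to ", length(i), " atom(s)")
    }
    i
  }, integer(1))
  pro_xyz <- t(vapply(constraints, function(con) {
    a <- protein$atoms
    hit <- which(a$chain == con$chain & a$resno == con$res_number &
                   a$atom_name == con$atom_name)
    if (length(hit) == 0) {
      stop("protein atom selector ", con$chain, con$res_number, ":",
           con$atom_name, " resolves to zero atoms")
    }
    c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
  }, numeric(3)))
  maxd <- vapply(constraints, `[[`, numeric(1), "max_distance")
  viol <- list()
  for (p in ensemble$poses) {
    d <- sqrt(rowSums((p$coords[lig_idx, , drop = FALSE] - pro_xyz)^2))
    if (all(d <= maxd)) return(p)
    viol[[length(viol) + 1]] <- data.frame(rank = p$rank,
                                           constraint = seq_along(d),
                                           distance = d,
                                           max_distance = maxd)
  }
  structure(list(pose = NULL, violations = do.call(rbind, viol)),
            class = "ecidal_no_match")
}

#' Per-residue backbone and side-chain RMSD between two structures
#'
#' After mapping the mobile structure with `transform`, each paired
#' residue is compared atom-by-atom (identity mapping by atom name):
#' backbone over N/CA/C/O, side chain over the remaining shared heavy
#' atoms. Used to quantify how much binding sites differ between crystal
#' forms.
#'
#' @param ref,mobile [protein()] structures of the same protein.
#' @param transform `rigid_transform` for the mobile structure (default
#'   identity).
#' @param selection Optional `binding_site` (or data frame of residue
#'   keys); default all residues shared by both structures.
#' @return Data frame with `chain`, `resno`, `resid`, `backbone_rmsd`,
#'   `side_chain_rmsd`, `n_backbone`, `n_side_chain`; residues with no
#'   shared atoms report `NA`.
#' @export
per_residue_rmsd <- function(ref, mobile, transform = identity_transform(),
                             selection = NULL) {
  stopifnot(inherits(ref, "protein"), inherits(mobile, "protein"))
  mob <- apply_transform(transform, mobile)
  if (is.null(selection)) {
    rk <- residue_keys(ref); mk <- residue_keys(mob)
    selection <- rk[paste(rk$chain, rk$resno) %in%
                      paste(mk$chain, mk$resno), , drop = FALSE]
  }
  bb <- c("N", "CA", "C", "O")
  res <- lapply(seq_len(nrow(selection)), function(k) {
    ra <- ref$atoms[ref$atoms$chain == selection$chain[k] &
                      ref$atoms$resno == selection$resno[k], ]
    ma <- mob$atoms[mob$atoms$chain == selection$chain[k] &
                      mob$atoms$resno == selection$resno[k], ]
    ra <- ra[ra$element != "H", ]; ma <- ma[ma$element != "H", ]
    shared <- intersect(ra$atom_name, ma$atom_name)
    part_rmsd <- function(names_) {
      nm <- intersect(shared, names_)
      if (!length(nm)) return(c(NA_real_, 0))
      i <- match(nm, ra$atom_name); j <- match(nm, ma$atom_name)
      d2 <- (ra$x[i] - ma$x[j])^2 + (ra$y[i] - ma$y[j])^2 +
        (ra$z[i] - ma$z[j])^2
      c(sqrt(mean(d2)), length(nm))
    }
    b <- part_rmsd(bb)
    s <- part_rmsd(setdiff(shared, bb))
    data.frame(chain = selection$chain[k], resno = selection$resno[k],
               resid = selection$resid[k],
               backbone_rmsd = b[1], side_chain_rmsd = s[1],
               n_backbone = as.integer(b[2]), n_side_chain = as.integer(s[2]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
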