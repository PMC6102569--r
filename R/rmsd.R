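# Symmetry-corrected, in-place heavy-atom RMSD. Chemically equivalent
# atoms (ring flips, rotor ends, symmetric substituents) must not inflate
# the deviation between a docked pose and the crystallographic reference,
# so the RMSD is minimised over the automorphisms of the element- and
# bond-order-labelled heavy-atom graph. The pose is never re-fitted onto
# the reference: docking RMSD measures placement in the receptor frame,
# and the only superposition allowed is the receptor-level one.

#' Automorphisms of the heavy-atom bond graph
#'
#' Enumerates all permutations of the heavy atoms that preserve elements,
#' adjacency and bond order (aromatic is its own order). The identity is
#' always included. Enumeration uses colour refinement plus backtracking;
#' a cap guards against pathological molecules.
#'
#' @param mol A [molecule()].
#' @param max_automorphisms Enumeration cap (default 10000); exceeding it
#'   is an error suggesting a higher cap.
#' @return List of integer permutations over the heavy atoms (in the order
#'   given by [heavy_atoms()]); `sigma[i]` is the image of heavy atom `i`.
#' @export
automorphisms <- function(mol, max_automorphisms = 10000) {
  stopifnot(inherits(mol, "molecule"))
  hv <- heavy_atoms(mol)
  n <- length(hv)
  pos <- integer(nrow(mol$atoms)); pos[hv] <- seq_len(n)
  adj <- matrix(0L, n, n)
  b <- mol$bonds
  if (nrow(b)) {
    keep <- b$i %in% hv & b$j %in% hv
    bi <- pos[b$i[keep]]; bj <- pos[b$j[keep]]
    adj[cbind(bi, bj)] <- b$order[keep]
    adj[cbind(bj, bi)] <- b$order[keep]
  }
  elem <- mol$atoms$element[hv]

  # 1-WL colour refinement: start from the element, fold in the multiset
  # of (neighbour colour, bond order) until stable
  col <- as.integer(factor(elem))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- which(adj[i, ] > 0)
      paste(col[i], paste(sort(paste(col[nb], adj[i, nb])), collapse = ";"))
    }, character(1))
    new <- match(sig, sort(unique(sig)))
    # refinement only ever splits classes; a stable class count means the
    # partition is stable
    if (length(unique(new)) == length(unique(col))) break
    col <- new
  }
  col <- new

  # assignment order: breadth-first from the rarest colour class keeps the
  # partial maps connected and prunes early
  tab <- table(col)
  start <- which(col == as.integer(names(tab)[which.min(tab)]))[1]
  ord <- integer(0); seen <- logical(n); queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  ord <- c(ord, which(!seen))  # disconnected fragments

  res <- list()
  cap_hit <- FALSE
  map <- integer(n); used <- logical(n)
  bt <- function(k) {
    if (cap_hit) return()
    if (k > n) {
      if (length(res) >= max_automorphisms) { cap_hit <<- TRUE; return() }
      res[[length(res) + 1]] <<- map
      return()
    }
    v <- ord[k]
    prev <- ord[seq_len(k - 1)]
    for (w in which(col == col[v] & !used)) {
      ok <- TRUE
      for (u in prev) {
        if (adj[v, u] != adj[w, map[u]]) { ok <- FALSE; break }
      }
      if (ok) {
        map[v] <<- w; used[w] <<- TRUE
        bt(k + 1)
        used[w] <<- FALSE; map[v] <<- 0L
        if (cap_hit) return()
      }
    }
  }
  bt(1L)
  if (cap_hit) {
    stop("more than ", max_automorphisms, " graph automorphisms; raise ",
         "`max_automorphisms` if this is intended")
  }
  res
}

#' Symmetry-corrected RMSD between two conformers
#'
#' Computes `min` over automorphisms `sigma` of
#' `sqrt(mean(|pose[sigma(i)] - ref[i]|^2))` over the heavy atoms, with no
#' re-superposition of the ligand. Pose and reference must already share a
#' frame: natively for self-docking, via the receptor transform from
#' [kabsch_superpose()] for cross-docking.
#'
#' @param pose,reference Full-atom coordinate matrices whose rows match
#'   `mol$atoms`, or [molecule()] objects (conformers of `mol`).
#' @param mol The [molecule()] supplying the bond graph.
#' @param auts Optional pre-computed [automorphisms()] list (saves work
#'   when scoring many poses of one ligand).
#' @return List of class `rmsd_result`: `rmsd` (A), `mapping` (the optimal
#'   heavy-atom permutation) and `n_atoms` (heavy atoms compared).
#' @export
symmetry_min_rmsd <- function(pose, reference, mol, auts = NULL) {
  stopifnot(inherits(mol, "molecule"))
  get_xyz <- function(x) {
    if (inherits(x, "molecule")) {
      if (nrow(x$atoms) != nrow(mol$atoms) ||
          !identical(sort(x$atoms$element), sort(mol$atoms$element))) {
        stop("conformer does not match the molecular graph ",
             "(atom count or element multiset differs)")
      }
      return(as.matrix(x$atoms[, c("x", "y", "z")]))
    }
    x <- as.matrix(x)
    if (nrow(x) != nrow(mol$atoms) || ncol(x) != 3) {
      stop("coordinate matrix does not match the molecule (",
           nrow(mol$atoms), " atoms expected)")
    }
    x
  }
  hv <- heavy_atoms(mol)
  P <- get_xyz(pose)[hv, , drop = FALSE]
  Q <- get_xyz(reference)[hv, , drop = FALSE]
  if (is.null(auts)) auts <- automorphisms(mol)
  best <- Inf; best_map <- seq_along(hv)
  for (sg in auts) {
    msd <- mean(rowSums((P[sg, , drop = FALSE] - Q)^2))
    if (msd < best) { best <- msd; best_map <- sg }
  }
  structure(list(rmsd = sqrt(best), mapping = best_map,
                 n_atoms = length(hv)),
            class = "rmsd_result")
}

#' Classify an RMSD value as good / acceptable / bad
#'
#' Default thresholds: good when RMSD <= 2.0 A, acceptable strictly
#' between 2.0 and 3.0 A, bad when RMSD >= 3.0 A. The boundary convention
#' at the good threshold is configurable (`good_inclusive = FALSE` makes
#' 2.0 A itself acceptable rather than good); the labels always partition
#' `[0, Inf)`.
#'
#' @param rmsd Non-negative numeric vector (A).
#' @param tau_good,tau_bad Class thresholds, `tau_good < tau_bad`.
#' @param good_inclusive Is `rmsd == tau_good` good (default) or
#'   acceptable?
#' @return Character vector with levels `"good"`, `"acceptable"`, `"bad"`.
#' @export
classify_rmsd <- function(rmsd, tau_good = 2.0, tau_bad = 3.0,
                          good_inclusive = TRUE) {
  if (any(!is.finite(rmsd)) || any(rmsd < 0)) {
    stop("rmsd must be finite and non-negative")
  }
  stopifnot(tau_good < tau_bad)
  good <- if (good_inclusive) rmsd <= tau_good else rmsd < tau_good
  bad <- rmsd >= tau_bad
  ifelse(good, "good", ifelse(bad, "bad", "acceptable"))
}
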