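# Synthetic docking outputs with known ground truth. The generator
# emulates what a rigid-receptor docking engine hands to the evaluation
# pipeline - ranked, scored pose ensembles in triplicate - while keeping
# the true RMSD of every pose under exact control, plus toy receptors
# with geometrically known cavities for the pocket module.
#
# All randomness flows through R's RNG; every generator takes an explicit
# seed (applied with withr::with_seed, leaving global state untouched) or,
# with seed = NULL, draws from the caller's current stream.

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Random small molecule for simulation
#'
#' Grows a random bonded tree of heavy atoms (bond length 1.5 A, mild
#' clash avoidance). Used as the docked "ligand" in synthetic benchmarks;
#' it has no hydrogens and carries single bonds only.
#'
#' @param n_heavy Number of heavy atoms (>= 2).
#' @param elements Element pool sampled with `probs`.
#' @param probs Sampling weights.
#' @param seed Optional integer seed.
#' @param name Molecule name.
#' @return A [molecule()].
#' @export
synthetic_ligand <- function(n_heavy = 12, elements = c("C", "N", "O"),
                             probs = c(0.7, 0.15, 0.15), seed = NULL,
                             name = "synthetic") {
  stopifnot(n_heavy >= 2)
  .with_seed(seed, {
    xyz <- matrix(0, n_heavy, 3)
    parent <- integer(n_heavy)
    deg <- integer(n_heavy)
    for (k in 2:n_heavy) {
      repeat {
        p <- sample(which(deg[seq_len(k - 1)] < 3), 1)
        for (try in 1:50) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- xyz[p, ] + 1.5 * u
          d2 <- rowSums(sweep(xyz[seq_len(k - 1), , drop = FALSE], 2,
                              cand)^2)
          if (all(d2 > 1.2^2)) break
        }
        break
      }
      xyz[k, ] <- cand
      parent[k] <- p
      deg[p] <- deg[p] + 1L; deg[k] <- deg[k] + 1L
    }
    el <- sample(elements, n_heavy, replace = TRUE, prob = probs)
    atoms <- data.frame(element = el, name = paste0(el, seq_len(n_heavy)),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        is_hydrogen = FALSE)
    bonds <- data.frame(i = parent[-1], j = 2:n_heavy, order = 1L)
    molecule(atoms, bonds, name = name)
  })
}

#' Perturb a reference conformation to a target RMSD
#'
#' Applies a random rigid rotation about the heavy-atom centroid plus a
#' random translation, with the overall amplitude found by bisection so
#' the identity-mapping heavy-atom RMSD hits `target_rmsd` within `tol`.
#' The achieved value is returned as ground truth.
#'
#' @param mol Reference [molecule()].
#' @param target_rmsd Desired RMSD (A, >= 0).
#' @param rotation_only Suppress the translation component (a single-atom
#'   molecule then cannot reach a positive target and errors).
#' @param tol Bisection tolerance (A, default 0.01).
#' @param seed Optional integer seed.
#' @return List with `coords` (full-atom matrix) and `achieved` (A).
#' @export
perturb_pose <- function(mol, target_rmsd, rotation_only = FALSE,
                         tol = 0.01, seed = NULL) {
  stopifnot(inherits(mol, "molecule"), target_rmsd >= 0)
  full <- mol_coords(mol)
  hv <- heavy_atoms(mol)
  if (target_rmsd == 0) {
    return(list(coords = full, achieved = 0))
  }
  if (rotation_only && length(hv) < 2) {
    stop("rotation about the centroid cannot move a single-atom molecule; ",
         "a positive target RMSD is unattainable in rotation-only mode")
  }
  .with_seed(seed, {
    ctr <- colMeans(full[hv, , drop = FALSE])
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
    L <- if (rotation_only) 0 else max(2 * target_rmsd, 1)
    theta_max <- pi
    move <- function(s) {
      R <- .axis_angle(axis, s * theta_max)
      sweep(sweep(full, 2, ctr) %*% t(R), 2, -(ctr + s * L * tdir))
    }
    f <- function(s) {
      m <- move(s)
      sqrt(mean(rowSums((m[hv, , drop = FALSE] -
                           full[hv, , drop = FALSE])^2)))
    }
    if (f(1) < target_rmsd) {
      stop("target RMSD ", target_rmsd, " A unattainable for this molecule",
           if (rotation_only) " in rotation-only mode" else "")
    }
    lo <- 0; hi <- 1
    s <- 0.5
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target_rmsd) < tol / 2) { s <- mid; break }
      if (fm < target_rmsd) lo <- mid else hi <- mid
      s <- (lo + hi) / 2
    }
    list(coords = move(s), achieved = f(s))
  })
}

.axis_angle <- function(u, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
}

#' Specification of one synthetic pose ensemble
#'
#' @param n_poses Poses per ensemble (default 10, matching the top-10
#'   analysis window).
#' @param rmsd_targets Explicit per-pose target RMSDs (A), or `NULL` to
#'   sample from `dist`.
#' @param dist Sampling distribution when `rmsd_targets` is `NULL`:
#'   `list(kind = "uniform", min, max)` or
#'   `list(kind = "lognormal", meanlog, sdlog)`.
#' @param score_slope Score units per Angstrom of true RMSD (> 0; lower
#'   score = better, so scores grow with RMSD).
#' @param score_noise_sd Gaussian score noise (>= 0; 0 makes the score a
#'   perfect oracle of the true RMSD).
#' @param seed Optional integer seed.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_poses = 10, rmsd_targets = NULL,
                          dist = list(kind = "uniform", min = 0.5, max = 6),
                          score_slope = 1, score_noise_sd = 0,
                          seed = NULL) {
  stopifnot(n_poses >= 1, score_slope > 0, score_noise_sd >= 0)
  if (!is.null(rmsd_targets)) {
    stopifnot(all(rmsd_targets >= 0))
    if (length(rmsd_targets) != n_poses) {
      stop("rmsd_targets must have length n_poses")
    }
  }
  structure(list(n_poses = n_poses, rmsd_targets = rmsd_targets,
                 dist = dist, score_slope = score_slope,
                 score_noise_sd = score_noise_sd, seed = seed),
            class = "ensemble_spec")
}

.draw_targets <- function(spec) {
  if (!is.null(spec$rmsd_targets)) return(spec$rmsd_targets)
  d <- spec$dist
  switch(d$kind,
         uniform = stats::runif(spec$n_poses, d$min, d$max),
         lognormal = stats::rlnorm(spec$n_poses, d$meanlog, d$sdlog),
         stop("unknown target distribution: ", d$kind))
}

#' Generate one scored pose ensemble with known true RMSDs
#'
#' Pose i is the reference conformation perturbed to its target RMSD; its
#' score is `score_slope * true_rmsd + N(0, score_noise_sd)`. Poses are
#' ranked by score. Fully reproducible from the spec seed.
#'
#' @param mol Reference [molecule()] (its coordinates are the
#'   crystallographic pose).
#' @param spec An [ensemble_spec()].
#' @param ligand_id,receptor_id,method,replicate Labels for the ensemble.
#' @return A [pose_ensemble()] whose poses carry the generator-truth
#'   `true_rmsd`.
#' @export
generate_ensemble <- function(mol, spec = ensemble_spec(),
                              ligand_id = mol$name,
                              receptor_id = ligand_id,
                              method = "SIM", replicate = 1L) {
  stopifnot(inherits(mol, "molecule"), inherits(spec, "ensemble_spec"))
  .with_seed(spec$seed, {
    targets <- .draw_targets(spec)
    poses <- lapply(targets, function(tg) {
      p <- perturb_pose(mol, tg)
      score <- spec$score_slope * p$achieved +
        stats::rnorm(1, 0, spec$score_noise_sd)
      list(coords = p$coords, score = score, true_rmsd = p$achieved)
    })
    pose_ensemble(mol, poses, ligand_id = ligand_id,
                  receptor_id = receptor_id, method = method,
                  replicate = replicate)
  })
}

#' Specification of a synthetic self-docking benchmark
#'
#' Mirrors the study design: a panel of complexes, each docked in
#' triplicate, the top `n_poses` solutions kept per run.
#'
#' @param n_complexes Number of synthetic complexes (the study used 30).
#' @param replicates Replicates per complex (default 3).
#' @param methods Character vector of method labels.
#' @param good_fraction Fraction of ensembles guaranteed to contain at
#'   least one pose in the good class (target drawn from
#'   `good_rmsd_range`).
#' @param good_rmsd_range RMSD range for the guaranteed good pose (A).
#' @param ensemble An [ensemble_spec()] template (its `seed` is ignored;
#'   the benchmark seed drives everything).
#' @param n_heavy Heavy atoms per synthetic ligand.
#' @param seed Master seed; the whole benchmark is a pure function of the
#'   spec including this seed.
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_complexes = 30, replicates = 3,
                           methods = "SIM", good_fraction = 1,
                           good_rmsd_range = c(0.3, 1.5),
                           ensemble = ensemble_spec(), n_heavy = 12,
                           seed = 1L) {
  stopifnot(n_complexes >= 1, replicates >= 1,
            good_fraction >= 0, good_fraction <= 1)
  structure(list(n_complexes = n_complexes, replicates = replicates,
                 methods = methods, good_fraction = good_fraction,
                 good_rmsd_range = good_rmsd_range, ensemble = ensemble,
                 n_heavy = n_heavy, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a full synthetic benchmark with its truth table
#'
#' Emits every (complex, method, replicate) ensemble plus a machine-
#' readable truth table holding the generator's per-pose target and
#' achieved RMSDs, so downstream recovery tests never re-derive ground
#' truth from the pipeline under test.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `ensembles` (list of [pose_ensemble()]),
#'   `references` (named list of the reference [molecule()]s) and `truth`
#'   (data frame: one row per generated pose, in generation order).
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  withr::with_seed(spec$seed, {
    refs <- list(); ensembles <- list(); truth <- list()
    for (i in seq_len(spec$n_complexes)) {
      id <- sprintf("L%03d", i)
      mol <- synthetic_ligand(spec$n_heavy, name = id)
      refs[[id]] <- mol
      for (m in spec$methods) {
        for (r in seq_len(spec$replicates)) {
          guaranteed <- stats::runif(1) < spec$good_fraction
          targets <- .draw_targets(spec$ensemble)
          if (guaranteed) {
            slot <- sample.int(spec$ensemble$n_poses, 1)
            targets[slot] <- stats::runif(1, spec$good_rmsd_range[1],
                                          spec$good_rmsd_range[2])
          }
          es <- ensemble_spec(n_poses = spec$ensemble$n_poses,
                              rmsd_targets = targets,
                              score_slope = spec$ensemble$score_slope,
                              score_noise_sd = spec$ensemble$score_noise_sd)
          en <- generate_ensemble(mol, es, ligand_id = id,
                                  receptor_id = id, method = m,
                                  replicate = r)
          ensembles[[length(ensembles) + 1]] <- en
          ach <- vapply(en$poses, function(p) p$true_rmsd, numeric(1))
          truth[[length(truth) + 1]] <- data.frame(
            ligand_id = id, receptor_id = id, method = m, replicate = r,
            rank = seq_along(ach), achieved_rmsd = ach,
            guaranteed_good = guaranteed)
        }
      }
    }
    list(ensembles = ensembles, references = refs,
         truth = do.call(rbind, truth))
  })
}

#' Toy receptor slab with a geometrically known cavity
#'
#' Builds a slab of carbon pseudo-atoms on a 1.5 A lattice and carves the
#' requested cavity. Cavity walls are lined with calibrated atom planes
#' placed so that the van der Waals surface straddles the nominal cavity
#' face with zero-mean error; the nominal carved volume (stored in the
#' `analytic_volume` attribute) is then the analytic reference for the
#' detected pocket volume. Slab extents should be multiples of 3 A so the
#' outer faces stay clean on a 1 A grid.
#'
#' Cavity specifications:
#' * `list(type = "none")` - plain convex slab;
#' * `list(type = "box", w, h, d)` - channel open at the top face;
#' * `list(type = "closed_box", w, h, d)` - fully enclosed void;
#' * `list(type = "sphere", r)` - fully enclosed spherical void;
#' * `list(type = "hemisphere", r)` - bowl open at the top face.
#' An optional `center = c(x, y)` places the cavity; default slab centre.
#' A list of such specifications carves several cavities.
#'
#' @param cavity Cavity specification (or list of them).
#' @param slab_dims Slab extents in A (atoms sit on `seq(0, L, 1.5)`).
#' @param seed Reserved for randomised variants; the default construction
#'   is deterministic.
#' @return A [protein()] of carbon pseudo-atoms (one pseudo-residue per
#'   atom) with attributes `analytic_volume` (A^3, `NA` for "none") and
#'   `cavities`.
#' @export
generate_toy_receptor <- function(cavity = list(type = "none"),
                                  slab_dims = c(12, 12, 12), seed = 0L) {
  lattice <- 1.5
  liner_sp <- 0.75                                 # dense liner -> flat walls
  rw <- vdw_radius("C")
  # wall offset calibrated so the union-of-spheres surface of a liner plane
  # straddles the nominal face with near-zero amplitude (~0.04 A at 0.75 A
  # liner spacing)
  r_eff <- (rw + sqrt(rw^2 - liner_sp^2 / 2)) / 2
  if (!is.null(cavity$type)) cavity <- list(cavity)
  L <- slab_dims
  z_top <- L[3] + r_eff                            # nominal slab surface
  grid1 <- function(Lk) seq(0, Lk, by = lattice)
  lat <- as.matrix(expand.grid(x = grid1(L[1]), y = grid1(L[2]),
                               z = grid1(L[3])))
  keep <- rep(TRUE, nrow(lat))
  liners <- list()
  vol <- 0
  plane_grid <- function(u1, u2, pad = lattice) {
    expand.grid(a = seq(u1[1] - pad, u1[2] + pad, by = liner_sp),
                b = seq(u2[1] - pad, u2[2] + pad, by = liner_sp))
  }
  for (cv in cavity) {
    ctr <- if (!is.null(cv$center)) cv$center[1:2] else c(L[1] / 2, L[2] / 2)
    if (cv$type == "none") next
    if (cv$type %in% c("box", "closed_box")) {
      stopifnot(cv$w > 0, cv$h > 0, cv$d > 0)
      if (cv$w > L[1] || cv$h > L[2] || cv$d > L[3]) {
        stop("cavity larger than the slab")
      }
      zhi <- if (cv$type == "box") z_top else L[3] / 2 + cv$d / 2
      zlo <- zhi - cv$d
      box <- rbind(c(ctr[1] - cv$w / 2, ctr[1] + cv$w / 2),
                   c(ctr[2] - cv$h / 2, ctr[2] + cv$h / 2),
                   c(zlo, zhi))
      # drop lattice atoms whose vdW sphere would intrude into the box
      dx <- pmax(box[1, 1] - lat[, 1], lat[, 1] - box[1, 2], 0)
      dy <- pmax(box[2, 1] - lat[, 2], lat[, 2] - box[2, 2], 0)
      dz <- pmax(box[3, 1] - lat[, 3], lat[, 3] - box[3, 2], 0)
      keep <- keep & (dx^2 + dy^2 + dz^2 >= rw^2 - 1e-9)
      # liner planes r_eff outside each face (top face only when closed)
      add_plane <- function(fixed_axis, value, u1, u2, axes) {
        g <- plane_grid(u1, u2)
        m <- matrix(NA_real_, nrow(g), 3)
        m[, fixed_axis] <- value
        m[, axes[1]] <- g$a; m[, axes[2]] <- g$b
        liners[[length(liners) + 1]] <<- m
      }
      add_plane(3, zlo - r_eff, box[1, ], box[2, ], c(1, 2))
      if (cv$type == "closed_box") {
        add_plane(3, zhi + r_eff, box[1, ], box[2, ], c(1, 2))
      }
      add_plane(1, box[1, 1] - r_eff, box[2, ], box[3, ], c(2, 3))
      add_plane(1, box[1, 2] + r_eff, box[2, ], box[3, ], c(2, 3))
      add_plane(2, box[2, 1] - r_eff, box[1, ], box[3, ], c(1, 3))
      add_plane(2, box[2, 2] + r_eff, box[1, ], box[3, ], c(1, 3))
      vol <- vol + cv$w * cv$h * cv$d
    } else if (cv$type == "sphere") {
      stopifnot(cv$r > 0)
      c3 <- c(ctr, if (length(cv$center) == 3) cv$center[3] else L[3] / 2)
      if (2 * (cv$r + rw) > min(L)) stop("cavity larger than the slab")
      d2 <- rowSums(sweep(lat, 2, c3)^2)
      keep <- keep & d2 >= (cv$r + rw)^2 - 1e-9
      shell <- sweep(.calibrated_shell(cv$r, rw, liner_sp), 2, -c3)
      liners[[length(liners) + 1]] <- shell
      vol <- vol + 4 / 3 * pi * cv$r^3
    } else if (cv$type == "hemisphere") {
      stopifnot(cv$r > 0)
      if (2 * cv$r > min(L[1], L[2]) || cv$r > L[3]) {
        stop("cavity larger than the slab")
      }
      c3 <- c(ctr, z_top)
      d2 <- rowSums(sweep(lat, 2, c3)^2)
      keep <- keep & d2 >= (cv$r + rw)^2 - 1e-9
      shell <- .fibonacci_shell(cv$r + r_eff, liner_sp)
      shell <- sweep(shell[shell[, 3] < -1e-6, , drop = FALSE], 2, -c3)
      liners[[length(liners) + 1]] <- shell
      vol <- vol + 2 / 3 * pi * cv$r^3
    } else {
      stop("unknown cavity type: ", cv$type)
    }
  }
  pts <- rbind(lat[keep, , drop = FALSE],
               do.call(rbind, c(liners, list(matrix(0, 0, 3)))))
  # liner atoms must not poke through outer faces or into other cavities;
  # clip them to the slab interior
  inside <- pts[, 1] > -1e-9 & pts[, 1] < L[1] + 1e-9 &
    pts[, 2] > -1e-9 & pts[, 2] < L[2] + 1e-9 &
    pts[, 3] > -1e-9 & pts[, 3] < L[3] + 1e-9
  n_lat <- sum(keep)
  inside[seq_len(n_lat)] <- TRUE
  pts <- pts[inside, , drop = FALSE]
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(pts)),
                      resid = "UNK", atom_name = "CA", element = "C",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3])
  out <- protein(atoms, source_id = "toy_receptor")
  attr(out, "analytic_volume") <- if (vol > 0) vol else NA_real_
  attr(out, "cavities") <- cavity
  out
}

# Shell of liner atoms whose inner vdW envelope averages exactly the
# requested void radius: built at a first-guess radius, the mean envelope
# radius is measured over a deterministic direction sample and the shell
# radius corrected once.
.calibrated_shell <- function(r_void, rw, spacing) {
  build <- function(R) .fibonacci_shell(R, spacing)
  envelope_mean <- function(shell) {
    dirs <- .fibonacci_shell(1, 0.15)
    t_of <- function(u) {
      proj <- shell %*% u
      perp2 <- rowSums(shell^2) - proj^2
      ok <- perp2 < rw^2 & proj > 0
      min(proj[ok] - sqrt(rw^2 - perp2[ok]))
    }
    mean(apply(dirs, 1, t_of))
  }
  R0 <- r_void + rw
  sh <- build(R0)
  R1 <- R0 + (r_void - envelope_mean(sh))
  build(R1)
}

# quasi-uniform points on a sphere of radius r, spacing ~ `spacing`
.fibonacci_shell <- function(r, spacing) {
  n <- max(32, ceiling(4 * pi * r^2 / spacing^2 * 2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta),
        r * cos(phi))
}
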