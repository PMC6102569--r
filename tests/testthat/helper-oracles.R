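# Independent oracles and fixture builders. Everything here recomputes
# quantities by a different route than the package (brute-force
# enumeration, quaternion superposition, direct formulas) so tests compare
# two independent implementations.

# ---- permutation enumeration ------------------------------------------

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# all element-preserving bijections of the heavy atoms of `mol`
element_bijections <- function(mol) {
  hv <- heavy_atoms(mol)
  elem <- mol$atoms$element[hv]
  classes <- split(seq_along(hv), elem)
  per_class <- lapply(classes, all_perms)
  combos <- expand.grid(lapply(per_class, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    sigma <- integer(length(hv))
    for (ci in seq_along(classes)) {
      sigma[classes[[ci]]] <- per_class[[ci]][[combos[r, ci]]]
    }
    sigma
  })
}

heavy_adj <- function(mol) {
  hv <- heavy_atoms(mol)
  pos <- integer(nrow(mol$atoms)); pos[hv] <- seq_along(hv)
  adj <- matrix(0L, length(hv), length(hv))
  b <- mol$bonds
  if (nrow(b)) {
    keep <- b$i %in% hv & b$j %in% hv
    adj[cbind(pos[b$i[keep]], pos[b$j[keep]])] <- b$order[keep]
    adj[cbind(pos[b$j[keep]], pos[b$i[keep]])] <- b$order[keep]
  }
  adj
}

is_graph_preserving <- function(sigma, adj) {
  all(adj[sigma, sigma] == adj)
}

# brute-force automorphism count (element + bond-order preserving)
brute_automorphism_count <- function(mol) {
  adj <- heavy_adj(mol)
  sum(vapply(element_bijections(mol), is_graph_preserving, logical(1),
             adj = adj))
}

# brute-force symmetry-corrected RMSD: minimum over all graph-preserving,
# element-preserving bijections
brute_min_rmsd <- function(pose_xyz, ref_xyz, mol) {
  adj <- heavy_adj(mol)
  hv <- heavy_atoms(mol)
  P <- pose_xyz[hv, , drop = FALSE]
  Q <- ref_xyz[hv, , drop = FALSE]
  best <- Inf
  for (sigma in element_bijections(mol)) {
    if (!is_graph_preserving(sigma, adj)) next
    msd <- mean(rowSums((P[sigma, , drop = FALSE] - Q)^2))
    if (msd < best) best <- msd
  }
  sqrt(best)
}

identity_rmsd <- function(pose_xyz, ref_xyz, mol) {
  hv <- heavy_atoms(mol)
  sqrt(mean(rowSums((pose_xyz[hv, , drop = FALSE] -
                       ref_xyz[hv, , drop = FALSE])^2)))
}

# ---- quaternion (Horn) rigid superposition ----------------------------

quaternion_superpose <- function(mobile, ref) {
  cx <- colMeans(mobile); cy <- colMeans(ref)
  X <- sweep(mobile, 2, cx); Y <- sweep(ref, 2, cy)
  M <- t(X) %*% Y
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  res <- Y - X %*% t(R)
  list(rotation = R, translation = as.numeric(cy - R %*% cx),
       fit_rmsd = sqrt(mean(rowSums(res^2))))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# ---- molecule fixtures -------------------------------------------------

make_mol <- function(elem, xyz, bonds_ij, orders = NULL, name = "fix") {
  if (is.null(orders)) orders <- rep(1L, nrow(bonds_ij))
  molecule(
    data.frame(element = elem, name = paste0(elem, seq_along(elem)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               is_hydrogen = elem == "H"),
    data.frame(i = bonds_ij[, 1], j = bonds_ij[, 2], order = orders),
    name = name)
}

ring6 <- function(elem = rep("C", 6), order = 4L, radius = 1.4) {
  th <- 2 * pi * (0:5) / 6
  make_mol(elem, cbind(radius * cos(th), radius * sin(th), 0),
           cbind(1:6, c(2:6, 1)), rep(order, 6), name = "ring6")
}

# benzene ring with identical single-atom substituents at positions 1, 4
para_disubstituted <- function() {
  th <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  subs <- rbind(2.9 * c(cos(th[1]), sin(th[1]), 0),
                2.9 * c(cos(th[4]), sin(th[4]), 0))
  make_mol(c(rep("C", 6), "Cl", "Cl"), rbind(ring, subs[, 1:3]),
           rbind(cbind(1:6, c(2:6, 1)), c(1, 7), c(4, 8)),
           c(rep(4L, 6), 1L, 1L), name = "para")
}

# random tree-bonded molecule, occasionally closed into a ring
random_test_molecule <- function(n_heavy, ring_prob = 0.3) {
  elem <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
  xyz <- matrix(stats::rnorm(3 * n_heavy, sd = 2), n_heavy, 3)
  parent <- c(0, vapply(2:n_heavy, function(k) {
    sample.int(k - 1, 1)
  }, integer(1)))
  bonds <- cbind(parent[-1], 2:n_heavy)
  orders <- sample(c(1L, 2L), nrow(bonds), replace = TRUE, prob = c(.8, .2))
  if (n_heavy >= 4 && stats::runif(1) < ring_prob) {
    extra <- sort(sample.int(n_heavy, 2))
    if (!any(bonds[, 1] == extra[1] & bonds[, 2] == extra[2]) &&
        extra[1] != extra[2]) {
      bonds <- rbind(bonds, extra)
      orders <- c(orders, 1L)
    }
  }
  make_mol(elem, xyz, bonds, orders, name = "random")
}

# ---- text-format fixture writers --------------------------------------

write_pdb_fixture <- function(path, atoms) {
  # atoms: data.frame(serial, name, altloc, resid, chain, resno, x, y, z,
  #                   occ, elem, type)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, a$serial, a$name, a$altloc, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, 0, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# convert write_pdb_fixture rows to protein() atom columns
as_protein_atoms <- function(raw) {
  data.frame(chain = raw$chain, resno = raw$resno, resid = raw$resid,
             atom_name = raw$name, element = raw$elem,
             x = raw$x, y = raw$y, z = raw$z)
}

std_residue <- function(serial0, chain, resno, resid, origin) {
  # four backbone atoms + one side-chain atom
  data.frame(
    serial = serial0 + 0:4,
    name = c("N", "CA", "C", "O", "CB"), altloc = "",
    resid = resid, chain = chain, resno = resno,
    x = origin[1] + c(0, 1.4, 2.4, 3.3, 1.6),
    y = origin[2] + c(0, 0.6, 0, 0.5, 2.0),
    z = origin[3] + c(0, 0, 0.8, 1.6, 0.3),
    occ = 1, elem = c("N", "C", "C", "O", "C"), type = "ATOM")
}

write_sdf_fixture <- function(path, elem, xyz, bonds_ij, orders,
                              title = "mol") {
  n <- length(elem); m <- nrow(bonds_ij)
  lines <- c(title, "  fixture", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
             vapply(seq_len(n), function(i) {
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[i, 1], xyz[i, 2], xyz[i, 3], elem[i])
             }, character(1)),
             vapply(seq_len(m), function(k) {
               sprintf("%3d%3d%3d  0", bonds_ij[k, 1], bonds_ij[k, 2],
                       orders[k])
             }, character(1)),
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

write_mol2_benzene <- function(path) {
  th <- 2 * pi * (0:5) / 6
  xyz <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  lines <- c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1 0 0", "SMALL",
             "NO_CHARGES", "", "@<TRIPOS>ATOM",
             vapply(1:6, function(i) {
               sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d %-4s %9.4f",
                       i, paste0("C", i), xyz[i, 1], xyz[i, 2], xyz[i, 3],
                       "C.ar", 1, "BNZ", 0)
             }, character(1)),
             "@<TRIPOS>BOND",
             vapply(1:6, function(k) {
               sprintf("%6d %4d %4d %-2s", k, k, ifelse(k == 6, 1, k + 1),
                       "ar")
             }, character(1)))
  writeLines(lines, path)
  path
}

# simple toy complex: protein of single-atom residues around a ligand
toy_complex <- function(n_res = 12, seed = 42) {
  withr::with_seed(seed, {
    lig <- make_mol(c("C", "C", "O"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0)),
                    rbind(c(1, 2), c(2, 3)), name = "toylig")
    ang <- stats::runif(n_res, 0, 2 * pi)
    rr <- stats::runif(n_res, 4, 14)
    zz <- stats::runif(n_res, -6, 6)
    atoms <- data.frame(chain = "A", resno = seq_len(n_res), resid = "GLY",
                        atom_name = "CA", element = "C",
                        x = rr * cos(ang), y = rr * sin(ang), z = zz)
    list(protein = protein(atoms, "toy"), ligand = lig,
         complex = ref_complex(protein(atoms, "toy"), lig, id = "toy"))
  })
}
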