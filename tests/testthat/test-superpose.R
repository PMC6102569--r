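test_that("binding-site selection follows the distance shell exactly", {
  # residues with nearest atoms at 5, 9.9 and 10.1 A from a ligand atom
  lig <- make_mol("C", matrix(0, 1, 3), matrix(0, 0, 2), integer(),
                  name = "pt")
  atoms <- data.frame(chain = "A", resno = 1:3, resid = "GLY",
                      atom_name = "CA", element = "C",
                      x = c(5, 9.9, 10.1), y = 0, z = 0)
  cx <- ref_complex(protein(atoms, "p"), lig, id = "t")
  sel <- select_binding_site(cx, cutoff = 10)
  expect_setequal(sel$resno, c(1, 2))
  expect_error(select_binding_site(cx, cutoff = 0.1), "empty binding site")
})

test_that("binding-site selection matches a brute-force distance scan", {
  tc <- toy_complex(n_res = 30, seed = 11)
  for (cutoff in c(6, 8, 10)) {
    sel <- select_binding_site(tc$complex, cutoff = cutoff)
    # oracle: exhaustive all-pairs scan
    lig <- mol_coords(tc$ligand, heavy_only = TRUE)
    a <- tc$protein$atoms
    want <- sort(unique(a$resno[vapply(seq_len(nrow(a)), function(i) {
      any(sqrt((lig[, 1] - a$x[i])^2 + (lig[, 2] - a$y[i])^2 +
                 (lig[, 3] - a$z[i])^2) <= cutoff)
    }, logical(1))]))
    expect_equal(sort(sel$resno), want, info = paste("cutoff", cutoff))
  }
})

test_that("residue pairing drops what it cannot match, errors below 3 pairs", {
  tc <- toy_complex(n_res = 12, seed = 3)
  sel <- select_binding_site(tc$complex, cutoff = 12)
  pairs <- pair_binding_site_residues(tc$protein, tc$protein, sel)
  expect_equal(nrow(pairs$ref_xyz), nrow(sel))

  # mobile missing one selected residue
  mob <- tc$protein
  drop_res <- sel$resno[1]
  mob$atoms <- mob$atoms[mob$atoms$resno != drop_res, ]
  mob <- protein(mob$atoms, "mob")
  expect_warning(p2 <- pair_binding_site_residues(tc$protein, mob, sel),
                 "missing CA")
  expect_equal(nrow(p2$ref_xyz), nrow(sel) - 1)

  # residue-name mismatch at the same number is dropped, not guessed
  mob2 <- tc$protein
  mob2$atoms$resid[mob2$atoms$resno == sel$resno[2]] <- "ALA"
  mob2 <- protein(mob2$atoms, "mob2")
  expect_warning(p3 <- pair_binding_site_residues(tc$protein, mob2, sel),
                 "mismatch")
  expect_equal(nrow(p3$ref_xyz), nrow(sel) - 1)

  tiny <- sel[1:2, ]
  expect_error(pair_binding_site_residues(tc$protein, tc$protein, tiny),
               "at least 3")
})

test_that("Kabsch recovers known rigid transforms to 1e-8", {
  withr::with_seed(7, {
    X <- matrix(stats::rnorm(30, sd = 4), 10, 3)
    # identity
  })
  tr0 <- kabsch_superpose(list(ref_xyz = X, mobile_xyz = X))
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tr0$fit_rmsd, 0, tolerance = 1e-10)

  withr::with_seed(8, {
    for (rep in 1:10) {
      X <- matrix(stats::rnorm(30, sd = 4), 10, 3)
      R <- random_rotation()
      tvec <- stats::rnorm(3, sd = 5)
      Y <- sweep(X %*% t(R), 2, -tvec)
      tr <- kabsch_superpose(list(ref_xyz = Y, mobile_xyz = X))
      expect_equal(tr$rotation, R, tolerance = 1e-8)
      expect_equal(tr$translation, tvec, tolerance = 1e-8)
      expect_lt(tr$fit_rmsd, 1e-8)
      # recovered transform composed with the inverse is the identity
      inv <- invert_transform(tr)
      back <- apply_transform(inv, apply_transform(tr, X))
      expect_equal(back, X, tolerance = 1e-9)
    }
  })
})

test_that("noisy fits agree with an independent quaternion oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      X <- matrix(stats::rnorm(30, sd = 4), 10, 3)
      Y <- sweep(X %*% t(random_rotation()), 2, -stats::rnorm(3)) +
        matrix(stats::rnorm(30, sd = 0.2), 10, 3)
      a <- kabsch_superpose(list(ref_xyz = Y, mobile_xyz = X))
      b <- quaternion_superpose(X, Y)
      expect_equal(a$fit_rmsd, b$fit_rmsd, tolerance = 1e-6)
      expect_equal(a$rotation, b$rotation, tolerance = 1e-5)
    }
  })
})

test_that("transforms are rigid and never worse than doing nothing", {
  withr::with_seed(31, {
    X <- matrix(stats::rnorm(24, sd = 3), 8, 3)
    Y <- X + matrix(stats::rnorm(24, sd = 1), 8, 3)
    tr <- kabsch_superpose(list(ref_xyz = Y, mobile_xyz = X))
    # optimality: fitted RMSD <= untransformed RMSD
    expect_lte(tr$fit_rmsd, sqrt(mean(rowSums((Y - X)^2))))
    # rigidity: pairwise distances preserved to 1e-9
    Xt <- apply_transform(tr, X)
    expect_equal(as.matrix(dist(Xt)), as.matrix(dist(X)), tolerance = 1e-9)
  })
  # identity transform leaves coordinates unchanged
  expect_equal(apply_transform(identity_transform(), diag(3)), diag(3))
  # collinear input is rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(list(ref_xyz = line, mobile_xyz = line)),
               "collinear")
})
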