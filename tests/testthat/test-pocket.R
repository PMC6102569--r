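test_that("metric identities are exact by construction", {
  pk <- structure(list(points = matrix(stats::runif(30), 10, 3),
                       depths = rep(2, 10), spacing = 1),
                  class = "pocket")
  m <- pocket_metrics(pk)
  expect_identical(m$bsv, 10 * 1^3)
  expect_identical(m$vd, 20)
  expect_identical(m$averaged_vd, 2)

  single <- structure(list(points = matrix(0, 1, 3), depths = 3.7,
                           spacing = 0.5), class = "pocket")
  ms <- pocket_metrics(single)
  expect_identical(ms$averaged_vd, 3.7)
  expect_identical(ms$bsv, 0.5^3)

  # VD equals an independent summation on a random synthetic pocket
  withr::with_seed(4, {
    d <- stats::runif(200, 0, 5)
    pk2 <- structure(list(points = matrix(stats::runif(600), 200, 3),
                          depths = d, spacing = 0.25), class = "pocket")
    expect_equal(pocket_metrics(pk2)$vd, sum(d), tolerance = 1e-9)
  })
  expect_error(pocket_metrics(structure(list(points = matrix(0, 0, 3),
                                             depths = numeric(),
                                             spacing = 1),
                                        class = "pocket")), "empty")
})

test_that("a convex slab yields no pockets", {
  slab <- generate_toy_receptor(list(type = "none"))
  expect_length(detect_pockets(slab, pocket_grid_config()), 0)
})

test_that("carved cavities are found, separated and measured", {
  # enclosed 5x5x5 box: pocket volume equals the carved volume at 1 A
  bx <- generate_toy_receptor(list(type = "closed_box", w = 5, h = 5,
                                   d = 5))
  ps <- detect_pockets(bx, pocket_grid_config(protein_depth_flag = 1000))
  expect_length(ps, 1)
  expect_equal(pocket_metrics(ps[[1]])$bsv, 125, tolerance = 0.15)

  # channel open to the top face, sealed by a large probe
  ch <- generate_toy_receptor(list(type = "box", w = 5, h = 5, d = 7))
  ps_ch <- detect_pockets(ch, pocket_grid_config(probe_radius = 6,
                                                 protein_depth_flag = 1000))
  expect_length(ps_ch, 1)
  expect_equal(pocket_metrics(ps_ch[[1]])$bsv,
               attr(ch, "analytic_volume"), tolerance = 0.15)

  # two disjoint voids come back as two components
  two <- generate_toy_receptor(list(
    list(type = "closed_box", w = 4.5, h = 4.5, d = 4.5, center = c(4, 4)),
    list(type = "closed_box", w = 3.5, h = 3.5, d = 3.5,
         center = c(13, 13))), slab_dims = c(18, 18, 12))
  ps2 <- detect_pockets(two, pocket_grid_config(protein_depth_flag = 1000))
  expect_length(ps2, 2)
  sizes <- sort(vapply(ps2, function(p) nrow(p$points), numeric(1)))
  expect_true(sizes[1] < sizes[2])
})

test_that("the ligand picks its pocket by overlap, not size", {
  two <- generate_toy_receptor(list(
    list(type = "closed_box", w = 4.5, h = 4.5, d = 4.5, center = c(4, 4)),
    list(type = "closed_box", w = 3.5, h = 3.5, d = 3.5,
         center = c(13, 13))), slab_dims = c(18, 18, 12))
  ps <- detect_pockets(two, pocket_grid_config(protein_depth_flag = 1000))
  # ligand sitting inside the smaller void
  lig <- make_mol("C", matrix(c(13, 13, 6), 1, 3), matrix(0, 0, 2),
                  integer())
  pk <- ligand_pocket(ps, lig)
  expect_equal(nrow(pk$points),
               min(vapply(ps, function(p) nrow(p$points), numeric(1))))
  # ligand far from both voids
  far <- make_mol("C", matrix(c(-30, -30, -30), 1, 3), matrix(0, 0, 2),
                  integer())
  expect_error(ligand_pocket(ps, far), "overlap")
})

test_that("shrinking the probe cannot grow the pocket", {
  ch <- generate_toy_receptor(list(type = "box", w = 5, h = 5, d = 7))
  vol_of <- function(rp) {
    ps <- detect_pockets(ch, pocket_grid_config(probe_radius = rp,
                                                protein_depth_flag = 1000))
    if (!length(ps)) 0 else max(vapply(ps, function(p)
      pocket_metrics(p)$bsv, numeric(1)))
  }
  v6 <- vol_of(6); v4 <- vol_of(4); v3 <- vol_of(3)
  expect_lte(v4, v6)
  expect_lte(v3, v4)
})

test_that("the grid memory guard triggers with a helpful message", {
  slab <- generate_toy_receptor(list(type = "none"))
  cfg <- pocket_grid_config(grid_spacing = 0.1, max_grid_points = 1e5)
  expect_error(detect_pockets(slab, cfg), "coarser")
})

test_that("deeper hemispherical bowls have larger averaged depth", {
  avg_vd <- function(r) {
    hs <- generate_toy_receptor(list(type = "hemisphere", r = r),
                                slab_dims = c(18, 18, 12))
    ps <- detect_pockets(hs, pocket_grid_config(probe_radius = 6,
                                                protein_depth_flag = 1000))
    pocket_metrics(ps[[1]])$averaged_vd
  }
  a3 <- avg_vd(3); a4 <- avg_vd(4)
  expect_gt(a3, 0)
  expect_gt(a4, a3)
})
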