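# build a minimal evaluated ensemble from an RMSD vector (rank order =
# input order; scores equal the position index so ordering is stable)
ensemble_from_rmsd <- function(rmsd, ligand_id = "L", receptor_id = "R",
                               method = "M", replicate = 1L) {
  mol <- make_mol(c("C", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                  rbind(c(1, 2)), name = ligand_id)
  poses <- lapply(seq_along(rmsd), function(k) {
    list(coords = NULL, score = k, true_rmsd = rmsd[k])
  })
  pose_ensemble(mol, poses, ligand_id = ligand_id,
                receptor_id = receptor_id, method = method,
                replicate = replicate)
}

test_that("best-solution positions follow the s2/s3 rules", {
  e1 <- ensemble_from_rmsd(c(3.5, 1.2, 0.8))
  expect_equal(best_solution_position(e1, "s2")$position, 2L)
  expect_equal(best_solution_position(e1, "s3")$position, 2L)

  e2 <- ensemble_from_rmsd(c(2.5, 2.4, 2.6))
  r2 <- best_solution_position(e2, "s2")
  expect_true(r2$bs)
  expect_true(is.na(r2$position))
  expect_equal(best_solution_position(e2, "s3")$position, 1L)

  e3 <- ensemble_from_rmsd(rep(1, 5))
  expect_equal(best_solution_position(e3, "s2")$position, 1L)
  expect_equal(best_solution_position(e3, "s3")$position, 1L)

  miss <- ensemble_from_rmsd(c(1, NA, 2))
  expect_error(best_solution_position(miss, "s2"), "true_rmsd")
})

test_that("recurrence tables count instances and sum to 100", {
  res <- list(
    best_solution_position(ensemble_from_rmsd(c(1, 5, 5), replicate = 1), "s2"),
    best_solution_position(ensemble_from_rmsd(c(0.5, 5, 5), replicate = 2), "s2"),
    best_solution_position(ensemble_from_rmsd(c(5, 1, 5), replicate = 3), "s2"),
    best_solution_position(ensemble_from_rmsd(c(5, 5, 5), replicate = 4), "s2"))
  tab <- recurrence_table(res, top_n = 10)
  expect_equal(tab$percent[tab$position == "1"], 50)
  expect_equal(tab$percent[tab$position == "2"], 25)
  expect_equal(tab$percent[tab$position == "BS"], 25)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_equal(unique(tab$n_instances), 4L)

  all_bs <- recurrence_table(list(
    best_solution_position(ensemble_from_rmsd(c(4, 4)), "s2")), top_n = 10)
  expect_equal(all_bs$percent[all_bs$position == "BS"], 100)
  expect_error(recurrence_table(list()), "no results")
})

test_that("cross-docking matrix categorises cells from replicates", {
  mk <- function(lig, rec, rmsds_by_rep) {
    lapply(seq_along(rmsds_by_rep), function(r) {
      best_solution_position(
        ensemble_from_rmsd(rmsds_by_rep[[r]], ligand_id = lig,
                           receptor_id = rec, replicate = r), "s2")
    })
  }
  res <- c(
    mk("a", "a", list(c(1, 5), c(5, 1), c(1, 5))),          # self
    mk("a", "b", list(c(5, 5), c(5, 1), c(5, 5))),          # good at rep 2
    mk("b", "a", list(c(5, 5), c(5, 5), c(5, 5))),          # all BS
    mk("b", "b", list(c(5, 1), c(5, 5), c(5, 5))))          # self, pos 2
  m <- cross_dock_matrix(res, data.frame(ligand_id = c("a", "b"),
                                         receptor_id = c("a", "b")))
  get <- function(l, r) m[m$ligand_id == l & m$receptor_id == r, ]
  expect_equal(get("a", "a")$category, "self")
  expect_equal(get("a", "a")$best_position, 1L)
  expect_equal(get("a", "b")$category, "good_found")
  expect_equal(get("b", "a")$category, "bs_only")
  expect_equal(get("b", "b")$best_position, 2L)

  # a missing cell is an error naming the gap
  expect_error(cross_dock_matrix(res[1:9], data.frame(
    ligand_id = c("a", "b"), receptor_id = c("a", "b"))), "b/b")
})

test_that("s3 is never later than s2 and BS propagates (10k ensembles)", {
  withr::with_seed(2024, {
    pos_of <- function(x) ifelse(is.na(x), Inf, x)
    n_bad <- 0
    for (i in 1:10000) {
      rmsd <- stats::runif(10, 0, 6)
      en <- ensemble_from_rmsd(rmsd)
      s2 <- best_solution_position(en, "s2")
      s3 <- best_solution_position(en, "s3")
      if (!(pos_of(s3$position) <= pos_of(s2$position))) n_bad <- n_bad + 1
      if (s3$bs && !s2$bs) n_bad <- n_bad + 1
    }
    expect_equal(n_bad, 0)
  })
})

test_that("raising top_n never turns a solution into BS", {
  withr::with_seed(77, {
    for (i in 1:50) {
      rmsd <- stats::runif(10, 0, 6)
      short <- best_solution_position(ensemble_from_rmsd(rmsd[1:5]), "s2")
      long <- best_solution_position(ensemble_from_rmsd(rmsd), "s2")
      if (!short$bs) {
        expect_false(long$bs)
        expect_equal(long$position, short$position)
      }
    }
  })
})

test_that("ECIDAL selection prefers compliant poses over better scores", {
  mol <- make_mol(c("C", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                  rbind(c(1, 2)), name = "lig")
  # rank-1/2 poses far from the anchor residue, rank-3 close to it
  mk_pose <- function(offset, score) {
    list(coords = sweep(mol_coords(mol), 2, -c(offset, 0, 0)),
         score = score)
  }
  en <- pose_ensemble(mol, list(mk_pose(20, -10), mk_pose(15, -9),
                                mk_pose(0, -8)))
  anchor <- protein(data.frame(chain = "A", resno = 57, resid = "HIS",
                               atom_name = "NE2", element = "N",
                               x = 0, y = 2, z = 0), "rec")
  con <- ecidal_constraint("N2", "A", 57, "NE2", max_distance = 3.5)
  sel <- select_best_with_ecidals(en, list(con), anchor)
  expect_equal(sel$rank, 3L)

  # no constraints: plain top-score selection
  expect_equal(select_best_with_ecidals(en, list(), anchor)$rank, 1L)

  # impossible constraint: no pose, with a violation report
  hard <- ecidal_constraint("N2", "A", 57, "NE2", max_distance = 0.1)
  out <- select_best_with_ecidals(en, list(hard), anchor)
  expect_s3_class(out, "ecidal_no_match")
  expect_equal(nrow(out$violations), 3)

  # a selector resolving to zero atoms errors
  bad <- ecidal_constraint("N2", "A", 999, "NE2", max_distance = 3)
  expect_error(select_best_with_ecidals(en, list(bad), anchor),
               "zero atoms")
})

test_that("per-residue RMSD separates backbone and side-chain motion", {
  raw <- rbind(std_residue(1, "A", 10, "ALA", c(0, 0, 0)),
               std_residue(6, "A", 11, "SER", c(5, 0, 0)))
  at <- as_protein_atoms(raw)
  ref <- protein(at, "ref")
  same <- per_residue_rmsd(ref, ref)
  expect_true(all(same$backbone_rmsd == 0))
  expect_true(all(same$side_chain_rmsd == 0))

  # displace one side chain by exactly 2 A, backbone untouched
  mob_at <- at
  i <- mob_at$resno == 11 & mob_at$atom_name == "CB"
  mob_at$x[i] <- mob_at$x[i] + 2
  mob <- protein(mob_at, "mob")
  tab <- per_residue_rmsd(ref, mob)
  expect_equal(tab$backbone_rmsd, c(0, 0))
  expect_equal(tab$side_chain_rmsd[tab$resno == 11], 2.0)
  expect_equal(tab$side_chain_rmsd[tab$resno == 10], 0)
})
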