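test_that("PDB receptors parse to residues with altLoc and HETATM handling", {
  f <- withr::local_tempfile(fileext = ".pdb")
  at <- rbind(std_residue(1, "A", 10, "ALA", c(0, 0, 0)),
              std_residue(6, "A", 11, "GLY", c(4, 0, 0)))
  # a HETATM ligand record that must not become a residue
  at <- rbind(at, data.frame(serial = 11, name = "C1", altloc = "",
                             resid = "LIG", chain = "A", resno = 200,
                             x = 1, y = 1, z = 1, occ = 1, elem = "C",
                             type = "HETATM"))
  write_pdb_fixture(f, at)
  p <- read_protein(f)
  keys <- residue_keys(p)
  expect_equal(nrow(keys), 2)
  expect_setequal(keys$resno, c(10, 11))
  expect_equal(sum(p$atoms$atom_name == "CA"), 2)

  # altLoc A/B on one atom: the higher-occupancy copy survives
  f2 <- withr::local_tempfile(fileext = ".pdb")
  r <- std_residue(1, "A", 10, "ALA", c(0, 0, 0))
  dup <- r[r$name == "CB", ]
  r$altloc[r$name == "CB"] <- "A"; r$occ[r$name == "CB"] <- 0.3
  dup$altloc <- "B"; dup$occ <- 0.7; dup$x <- dup$x + 1; dup$serial <- 6
  write_pdb_fixture(f2, rbind(r, dup))
  p2 <- read_protein(f2)
  cb <- p2$atoms[p2$atoms$atom_name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, dup$x)   # the 0.7-occupancy B copy

  # no ATOM records at all
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK empty", "END"), f3)
  expect_error(read_protein(f3), "no ATOM")
})

test_that("ligand readers populate bonds from SDF and MOL2", {
  f <- withr::local_tempfile(fileext = ".sdf")
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7),
                 c(2, 8))
  write_sdf_fixture(f, c("C", "C", "H", "H", "H", "H", "H", "H"),
                    rbind(c(0, 0, 0), c(1.54, 0, 0), c(-0.5, 0.9, 0),
                          c(-0.5, -0.9, 0.1), c(-0.4, 0, -1),
                          c(2, 0.9, 0), c(2, -0.9, 0.1), c(1.9, 0, -1)),
                    bonds, rep(1L, 7), title = "ethane")
  m <- read_ligand(f)
  expect_equal(sum(!m$atoms$is_hydrogen), 2)
  hb <- m$bonds[!m$atoms$is_hydrogen[m$bonds$i] &
                  !m$atoms$is_hydrogen[m$bonds$j], ]
  expect_equal(nrow(hb), 1)          # one C-C bond
  expect_equal(hb$order, 1L)

  f2 <- withr::local_tempfile(fileext = ".mol2")
  write_mol2_benzene(f2)
  bz <- read_ligand(f2)
  expect_equal(nrow(bz$atoms), 6)
  expect_true(all(bz$bonds$order == 4L))   # aromatic
  expect_true(all(bz$bonds$in_ring))

  # two records without an index is ambiguous
  f3 <- withr::local_tempfile(fileext = ".sdf")
  one <- readLines(f)
  writeLines(c(one, one), f3)
  expect_error(read_ligand(f3), "index")
  expect_equal(read_ligand(f3, index = 2)$atoms$element[1], "C")

  # bare PDB ligand without CONECT is refused
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       "HETATM", 1, "C1", "", "LIG", "A", 1, 0, 0, 0, 1, 0,
                       "C"), "END"), f4)
  expect_error(read_ligand(f4, format = "pdb"), "CONECT")
})

test_that("result tables round-trip through CSV and JSON", {
  tab <- data.frame(position = c("1", "2", "BS"),
                    percent = c(50, 25, 25), n_instances = 4L)
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_results(tab, fc)
  write_results(tab, fj)
  back_c <- read_results(fc)
  back_j <- read_results(fj)
  expect_equal(back_c$percent, tab$percent)
  expect_equal(back_j$percent, tab$percent)
  expect_equal(back_c$position, tab$position)
  expect_error(write_results(tab[0, ], fc), "empty")
})

test_that("structure invariants hold after parsing and construction", {
  # read -> write -> read round trip preserves atoms and bonds
  f <- withr::local_tempfile(fileext = ".sdf")
  th <- 2 * pi * (0:5) / 6
  write_sdf_fixture(f, rep("C", 6), cbind(1.4 * cos(th), 1.4 * sin(th), 0),
                    cbind(1:6, c(2:6, 1)), rep(4L, 6), title = "ring")
  m1 <- read_ligand(f)
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_fixture(f2, m1$atoms$element, mol_coords(m1),
                    as.matrix(m1$bonds[, c("i", "j")]), m1$bonds$order)
  m2 <- read_ligand(f2)
  expect_equal(nrow(m2$atoms), nrow(m1$atoms))
  expect_equal(mol_coords(m2), mol_coords(m1), tolerance = 1e-4)
  expect_equal(m2$bonds[order(m2$bonds$i, m2$bonds$j), ],
               m1$bonds[order(m1$bonds$i, m1$bonds$j), ])

  # duplicated residue keys are rejected
  raw <- rbind(std_residue(1, "A", 10, "ALA", c(0, 0, 0)),
               std_residue(6, "A", 11, "GLY", c(4, 0, 0)),
               std_residue(11, "A", 10, "ALA", c(8, 0, 0)))
  expect_error(protein(as_protein_atoms(raw), "dup"), "duplicated residue")
})
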