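test_that("read_structure parses PDB, classifies kinds and drops hetero groups", {
  pdb <- c(
    "HEADER    test",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   2       4.000   1.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   3       7.000   2.000   0.000  1.00  0.00           C",
    "ATOM      5  H   ALA A   3       7.500   2.000   0.000  1.00  0.00           H",
    "ATOM      6  P     U R   1       3.000   4.000   0.000  1.00  0.00           P",
    "HETATM    7  O   HOH A  90      20.000  20.000  20.000  1.00  0.00           O",
    "HETATM    8 MG    MG A  91      21.000  21.000  21.000  1.00  0.00          MG",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- read_structure(f, "pdb")
  expect_s3_class(s, "complex_structure")
  expect_equal(sum(s$residues$kind == "protein"), 3)
  expect_equal(sum(s$residues$kind == "rna"), 1)
  expect_false(any(s$atoms$element == "H"))   # hydrogens dropped
  expect_false("HOH" %in% s$atoms$res_name)   # waters/ions dropped
  expect_equal(s$residues$res_id[s$residues$chain == "A"], 0:2)
})

test_that("waters-only file raises an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f, "pdb"), "empty structure")
})

test_that("altloc duplicates resolve to the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  P     U R   1       9.000   3.000   0.000  1.00  0.00           P",
    "END"), f)
  s <- read_structure(f, "pdb")
  prot <- s$atoms[s$atoms$kind == "protein", ]
  expect_equal(nrow(prot), 1)
  expect_equal(prot$x, 9.0)
})

test_that("mmCIF atom_site parsing matches the PDB path", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "ATOM 1 C CA ALA A 1 0.000 0.000 0.000 1.00",
    "ATOM 2 C CA ALA A 2 3.800 0.000 0.000 1.00",
    "ATOM 3 P P U R 1 3.800 4.200 0.000 1.00",
    "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  s <- read_structure(f)   # auto-detected by extension
  expect_equal(sum(s$residues$kind == "protein"), 2)
  expect_equal(sum(s$residues$kind == "rna"), 1)
  lab <- label_interface_residues(s)
  expect_equal(lab$label, c(0L, 1L))  # 4.2 < 5 for residue 2 only
})

test_that("synthetic write/read round-trip preserves counts, names, coords", {
  sp <- fixture_spec(n_residues = 12, rna_patch = c(4, 6), seed = 3)
  s <- make_complex(sp)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_structure(f, "pdb")
  expect_equal(nrow(s2$residues), nrow(s$residues))
  expect_equal(s2$residues$res_name, s$residues$res_name)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("min_heavy_atom_distance: 3-4-5 triangle, identity, brute force", {
  a <- list(coords = matrix(c(0, 0, 0), 1))
  b <- list(coords = matrix(c(3, 4, 0), 1))
  expect_equal(min_heavy_atom_distance(a, b), 5.0)
  expect_equal(min_heavy_atom_distance(a, a), 0.0)
  set.seed(11)
  A <- matrix(runif(15, 0, 10), 5, 3)
  B <- matrix(runif(12, 0, 10), 4, 3)
  brute <- Inf
  for (i in 1:5) for (j in 1:4)
    brute <- min(brute, sqrt(sum((A[i, ] - B[j, ])^2)))
  expect_equal(min_heavy_atom_distance(list(coords = A), list(coords = B)),
               brute)
  expect_equal(min_heavy_atom_distance(list(coords = A), list(coords = B)),
               min_heavy_atom_distance(list(coords = B), list(coords = A)))
  expect_error(min_heavy_atom_distance(list(coords = A[0, , drop = FALSE]),
                                       list(coords = B)), "missing atoms")
})

test_that("interface labeling: cutoff strictness and brute-force agreement", {
  mk <- function(d) make_structure(list(
    list(chain = "A", res_id = 0L, res_name = "ALA", kind = "protein",
         coords = c(0, 0, 0)),
    list(chain = "R", res_id = 0L, res_name = "U", kind = "rna",
         coords = c(d, 0, 0))))
  expect_equal(label_interface_residues(mk(4.2))$label, 1L)
  expect_equal(label_interface_residues(mk(5.0))$label, 0L)  # strict <
  expect_equal(label_interface_residues(mk(4.9999))$label, 1L)

  # no RNA -> all-zero labels
  s <- make_structure(list(
    list(chain = "A", res_id = 0L, res_name = "ALA", kind = "protein",
         coords = c(0, 0, 0)),
    list(chain = "A", res_id = 1L, res_name = "GLY", kind = "protein",
         coords = c(3, 0, 0))))
  expect_equal(label_interface_residues(s)$label, c(0L, 0L))

  # synthetic helix with RNA near residues 3-5 matches the per-atom oracle
  sp <- fixture_spec(n_residues = 10, rna_patch = c(3, 5), rna_offset = 4)
  sx <- make_complex(sp)
  expect_equal(label_interface_residues(sx)$label, oracle_labels(sx))
  expect_equal(which(label_interface_residues(sx)$label == 1L) - 1L, 3:5)
})

test_that("labeling is monotone in the cutoff", {
  set.seed(5)
  for (rep in 1:10) {
    s <- random_complex(8, 3)
    prev <- rep(0L, 8)
    for (cutoff in c(2, 4, 6, 9, 14)) {
      lab <- label_interface_residues(s, cutoff)$label
      expect_true(all(lab >= prev))
      prev <- lab
    }
  }
})

test_that("residue_distance metrics are symmetric, zero on the diagonal", {
  sp <- fixture_spec(n_residues = 8, rna_patch = c(2, 3))
  s <- make_complex(sp)
  for (metric in c("ca", "min_heavy", "centroid")) {
    expect_equal(residue_distance(s, 2, 5, metric),
                 residue_distance(s, 5, 2, metric))
  }
  expect_equal(residue_distance(s, 3, 3, "ca"), 0)
  expect_equal(residue_distance(s, 3, 3, "centroid"), 0)
  # cross-operation oracle: min_heavy equals min_heavy_atom_distance
  res <- s$residues[s$residues$kind == "protein", ]
  ra <- get_residue(s, res$chain[1], res$res_id[1])
  rb <- get_residue(s, res$chain[6], res$res_id[6])
  expect_equal(residue_distance(s, 1, 6, "min_heavy"),
               min_heavy_atom_distance(ra, rb))
  # ca distance on explicit coordinates
  s2 <- make_structure(list(
    list(chain = "A", res_id = 0L, res_name = "ALA", kind = "protein",
         coords = c(0, 0, 0), atoms = "CA"),
    list(chain = "A", res_id = 1L, res_name = "ALA", kind = "protein",
         coords = c(0, 0, 1.5), atoms = "CA"),
    list(chain = "R", res_id = 0L, res_name = "U", kind = "rna",
         coords = c(9, 9, 9))))
  expect_equal(residue_distance(s2, 1, 2, "ca"), 1.5)
})

test_that("residues lacking CA fall back to centroid with a warning", {
  s <- make_structure(list(
    list(chain = "A", res_id = 0L, res_name = "ALA", kind = "protein",
         coords = c(0, 0, 0), atoms = "CA"),
    list(chain = "A", res_id = 1L, res_name = "ALA", kind = "protein",
         coords = rbind(c(2, 0, 0), c(4, 0, 0)), atoms = c("CB", "CG")),
    list(chain = "R", res_id = 0L, res_name = "U", kind = "rna",
         coords = c(9, 9, 9))))
  expect_warning(d <- residue_distance(s, 1, 2, "ca"), "centroid")
  expect_equal(d, 3)  # centroid of (2,0,0),(4,0,0)
})
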