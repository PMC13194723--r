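random_structure <- function(n = 10, seed = 1) {
  set.seed(seed)
  structure_model(data.frame(
    chain = "A", resno = 1:n, resname = "GLY", name = "CA", element = "C",
    entity = "protein", x = stats::rnorm(n, sd = 5),
    y = stats::rnorm(n, sd = 5), z = stats::rnorm(n, sd = 5)))
}

test_that("C-alpha RMSD is zero for self and rigid copies, and symmetric", {
  s <- random_structure(12, seed = 31)
  self <- ca_rmsd_pair(s, s)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$n_matched, 12)

  moved <- s
  rot <- random_rotation()
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(9, -3, 4), "+")
  expect_equal(ca_rmsd_pair(s, moved)$rmsd, 0, tolerance = 1e-9)

  perturbed <- s
  set.seed(8)
  perturbed$atoms[, c("x", "y", "z")] <-
    perturbed$atoms[, c("x", "y", "z")] + stats::rnorm(36, sd = 0.5)
  expect_equal(ca_rmsd_pair(s, perturbed)$rmsd,
               ca_rmsd_pair(perturbed, s)$rmsd, tolerance = 1e-9)
})

test_that("shell residues respect and are monotone in the cutoff", {
  atoms <- data.frame(
    chain = c("A", "A", "L"), resno = c(1L, 2L, 9L),
    resname = c("GLY", "GLY", "LIG"), name = c("CA", "CA", "C1"),
    element = "C", entity = c("protein", "protein", "ligand"),
    x = c(4, 12, 0), y = 0, z = 0)
  s <- structure_model(atoms)
  lig <- select_structure(s, entity = "ligand")
  expect_equal(shell_residues(s, lig, 6)$resno, 1L)
  expect_equal(nrow(shell_residues(s, lig, 3)), 0)
  expect_equal(nrow(shell_residues(s, lig, 0)), 0)
  expect_equal(shell_residues(s, lig, 20)$resno, c(1L, 2L))
  small <- shell_residues(s, lig, 5)$resno
  big <- shell_residues(s, lig, 13)$resno
  expect_true(all(small %in% big))
  expect_error(shell_residues(s, integer(), 6), "centre")
})

test_that("contact distance is the minimum heavy-atom separation", {
  atoms <- data.frame(
    chain = c("A", "A", "L", "L"), resno = c(1L, 1L, 9L, 9L),
    resname = c("ASP", "ASP", "LIG", "LIG"),
    name = c("OD1", "HD", "NE", "H1"),
    element = c("O", "H", "N", "H"),
    entity = c("protein", "protein", "ligand", "ligand"),
    x = c(0, 0.5, 3.2, 3.0), y = 0, z = 0)
  s <- structure_model(atoms)
  a <- select_structure(s, entity = "ligand", heavy = FALSE)
  b <- select_structure(s, entity = "protein", heavy = FALSE)
  expect_equal(contact_distance(s, a, b), 3.2)  # hydrogens ignored
  expect_error(contact_distance(s, a[s$atoms$element[a] == "H"], b),
               "zero heavy atoms")
})

test_that("state displacement isolates the moved atom after superposition", {
  s1 <- random_structure(10, seed = 77)
  s2 <- s1
  s2$atoms$z[5] <- s2$atoms$z[5] + 2.8
  rot <- random_rotation()
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% t(rot)
  s2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(3, 3, -6), "+")
  rep_tab <- data.frame(resno = c(5L, 8L), name = "CA")
  d <- state_displacement(s1, s2, superpose_resno = c(1:4, 6:10), rep_tab)
  expect_equal(d$displacement[1], 2.8, tolerance = 1e-6)
  expect_lt(d$displacement[2], 1e-6)

  d0 <- state_displacement(s1, s1, superpose_resno = 1:10, rep_tab)
  expect_true(all(d0$displacement < 1e-9))
  expect_error(state_displacement(s1, s2, 1:10,
                                  data.frame(resno = 99L, name = "CA")),
               "missing")
})

test_that("identity and similarity follow the alignment-column convention", {
  same <- pairwise_identity_similarity("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(same$percent_identity, 100)
  expect_equal(same$percent_similarity, 100)

  three <- pairwise_identity_similarity("AAAA", "AAAG")
  expect_equal(three$percent_identity, 75)

  # conservative substitution scores positive: similar but not identical
  cons <- pairwise_identity_similarity("ILLI", "ILLV")  # V/I positive in BLOSUM62
  expect_equal(cons$percent_identity, 75)
  expect_equal(cons$percent_similarity, 100)

  set.seed(14)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    s1 <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 25, replace = TRUE), collapse = "")
    r <- pairwise_identity_similarity(s1, s2)
    expect_lte(r$percent_identity, r$percent_similarity)
    expect_gte(r$percent_identity, 0)
    expect_lte(r$percent_similarity, 100)
  }
  expect_error(pairwise_identity_similarity("AC1D", "ACD"), "invalid")
  expect_error(pairwise_identity_similarity("", "ACD"), "empty")
})

test_that("PDB files round-trip through read_structure with altloc policy", {
  pdb_lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   1.000   0.000  0.60  0.00           C",
    "ATOM      4  CB BALA A   1       2.100   1.100   0.000  0.40  0.00           C",
    "HETATM    5  C1  LIG A   9       5.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  expect_warning(s <- read_structure(f), "altloc")
  expect_equal(nrow(s$atoms), 4)
  expect_equal(sum(s$atoms$entity == "ligand"), 1)
  expect_equal(s$atoms$x[2], 1.458)
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})
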