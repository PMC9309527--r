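test_that("a toy PDB parses into atoms, chains, and an id", {
  s <- read_structure(toy_pdb())
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$atoms), 4)
  expect_equal(s$chains, "A")
  expect_equal(s$atoms$x[2], 1.5)
})

test_that("chain filtering keeps the selected chain's ATOMs but all HETATMs", {
  path <- write_pdb_fixture(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_line("ATOM", 3, "CA", "SER", "A", 3, 6, 0, 0),
    pdb_line("ATOM", 4, "CA", "LEU", "B", 1, 20, 0, 0),
    pdb_line("ATOM", 5, "CA", "VAL", "B", 2, 23, 0, 0),
    pdb_line("HETATM", 6, "C1", "ATP", "B", 90, 30, 0, 0)
  ))
  s <- read_structure(path, chain_filter = "A")
  expect_equal(sum(s$atoms$record == "ATOM"), 3)
  expect_equal(sum(s$atoms$record == "HETATM"), 1)
  strict <- read_structure(path, chain_filter = "A", strict_chain = TRUE)
  expect_equal(sum(strict$atoms$record == "HETATM"), 0)
})

test_that("parse errors are structured: missing file, no ATOMs, bad coordinates", {
  expect_error(read_structure(tempfile()), "not found")
  no_atoms <- write_pdb_fixture(pdb_line("HETATM", 1, "C1", "ATP", "A", 1, 0, 0, 0))
  expect_error(read_structure(no_atoms), "No ATOM records")
  bad <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0))
  bad <- c(bad, sub("   0\\.000", "   abc.x", pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 0, 1, 0)))
  path <- write_pdb_fixture(bad)
  expect_error(read_structure(path), "line 2")
})

test_that("altlocs resolve to highest occupancy, ties to 'A'", {
  path <- write_pdb_fixture(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 1, 0, 0, alt = "A", occ = 0.4),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 2, 0, 0, alt = "B", occ = 0.6),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 3, 0, 0, alt = "A", occ = 0.5),
    pdb_line("ATOM", 4, "CB", "ALA", "A", 1, 4, 0, 0, alt = "B", occ = 0.5)
  ))
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$elety == "CA"], 2) # occupancy 0.6 wins
  expect_equal(s$atoms$x[s$atoms$elety == "CB"], 3) # tie -> altloc A
})

test_that("write-then-read preserves atom count, residues, and coordinates", {
  g <- generate_geometric_protein(4, 2, seed = 7, out_dir = tempfile())
  s <- read_structure(g$pdb_path)
  path2 <- tempfile(fileext = ".pdb")
  write_structure(s, path2)
  s2 <- read_structure(path2)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(s2$atoms$resid, s$atoms$resid)
  expect_equal(s2$atoms[, c("x", "y", "z")], s$atoms[, c("x", "y", "z")],
               tolerance = 1e-3)
})

test_that("modulator extraction excludes solvent, drops hydrogens, orders groups", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    vapply(1:30, function(i)
      pdb_line("HETATM", 100 + i, "O", "HOH", "W", i, i, 50, 0, elesy = "O"),
      character(1)),
    pdb_line("HETATM", 200, "C1", "ATP", "B", 401, 10, 0, 0),
    pdb_line("HETATM", 201, "H1", "ATP", "B", 401, 10.5, 0, 0, elesy = "H"),
    pdb_line("HETATM", 202, "C1", "FAD", "A", 300, 20, 0, 0)
  )
  s <- read_structure(write_pdb_fixture(lines))
  mods <- extract_modulators(s)
  expect_length(mods, 2)
  # ordered by (chain, resno): FAD on A before ATP on B
  expect_equal(vapply(mods, function(m) m$resid, ""), c("FAD", "ATP"))
  expect_equal(nrow(mods[[2]]$xyz), 1) # hydrogen dropped
  # record order within a group does not matter
  s_rev <- s
  s_rev$atoms <- s$atoms[rev(seq_len(nrow(s$atoms))), ]
  mods_rev <- extract_modulators(s_rev)
  expect_equal(lapply(mods_rev, function(m) m$resid),
               lapply(mods, function(m) m$resid))
})

test_that("apo structures give an empty modulator list", {
  s <- read_structure(toy_pdb())
  expect_length(extract_modulators(s), 0)
})

test_that("centroid is the coordinate-wise mean and is translation-equivariant", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(centroid(rbind(c(1, 1, 1))), c(1, 1, 1))
  expect_error(centroid(matrix(numeric(), ncol = 3)), "empty")
  set.seed(42)
  pts <- matrix(rnorm(300), ncol = 3)
  # independent summation oracle
  manual <- c(sum(pts[, 1]), sum(pts[, 2]), sum(pts[, 3])) / nrow(pts)
  expect_equal(centroid(pts), manual)
  t_off <- c(5, -3, 2)
  expect_equal(centroid(sweep(pts, 2, t_off, "+")), centroid(pts) + t_off)
})
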