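# Contact scheme: positive iff a pocket residue has a heavy atom within the
# cutoff of a modulator heavy atom. Centroid scheme: unique positive at the
# argmin centroid distance.

make_modulator <- function(xyz, resid = "LIG", chain = "A", resno = 900) {
  structure(list(resid = resid, chain = chain, resno = resno,
                 xyz = rbind(xyz)), class = "modulator")
}

test_that("contact labels follow the heavy-atom distance cutoff", {
  atoms <- rbind(
    atom_row("ATOM", 1, "CB", "ALA", "A", 42, 3, 0, 0),
    atom_row("ATOM", 2, "CB", "GLY", "A", 50, 50, 0, 0)
  )
  s <- make_structure("T", atoms)
  pockets <- list(
    make_pocket("T", 1, 1, residues = data.frame(chain = "A", resno = 42L,
                                                 resid = "ALA")),
    make_pocket("T", 2, 2, residues = data.frame(chain = "A", resno = 50L,
                                                 resid = "GLY"))
  )
  mod <- make_modulator(c(0, 0, 0))
  labeled <- label_by_contact(pockets, list(mod), s, contact_cutoff = 4.5)
  expect_equal(set_labels(labeled), c(1L, 0L)) # 3.0 A in, 50 A out
  expect_error(label_by_contact(pockets, list(), s), "No modulators")
})

test_that("contact labels are monotone in the cutoff", {
  g <- generate_geometric_protein(6, 2, seed = 31, out_dir = tempfile())
  s <- read_structure(g$pdb_path)
  mods <- extract_modulators(s)
  recs <- parse_fpocket_dir(g$fpocket_dir)
  pos4 <- which(set_labels(label_by_contact(recs, mods, s, 4.0)) == 1L)
  pos5 <- which(set_labels(label_by_contact(recs, mods, s, 5.0)) == 1L)
  expect_true(all(pos4 %in% pos5))
})

test_that("contact labels match a brute-force all-pairs distance scan", {
  g <- generate_geometric_protein(6, 2, seed = 17, out_dir = tempfile())
  s <- read_structure(g$pdb_path)
  mods <- extract_modulators(s)
  recs <- parse_fpocket_dir(g$fpocket_dir)
  labeled <- label_by_contact(recs, mods, s, contact_cutoff = 4.5)
  expect_equal(which(set_labels(labeled) == 1L), 2L)
  # O(n^2) oracle straight off the parsed coordinates
  mod_xyz <- mods[[1]]$xyz
  oracle <- vapply(recs, function(rec) {
    hit <- FALSE
    for (r in seq_len(nrow(rec$residues))) {
      sel <- s$atoms$record == "ATOM" &
        s$atoms$chain == rec$residues$chain[r] &
        s$atoms$resno == rec$residues$resno[r]
      for (i in which(sel)) {
        for (j in seq_len(nrow(mod_xyz))) {
          d <- sqrt(sum((c(s$atoms$x[i], s$atoms$y[i], s$atoms$z[i]) -
                           mod_xyz[j, ])^2))
          if (d <= 4.5) hit <- TRUE
        }
      }
    }
    as.integer(hit)
  }, 0L)
  expect_equal(set_labels(labeled), oracle)
})

test_that("centroid labeling picks the nearest pocket, uniquely", {
  pockets <- list(
    make_pocket("T", 1, 1, centers = rbind(c(0, 0, 0))),
    make_pocket("T", 2, 2, centers = rbind(c(10, 0, 0)))
  )
  mod <- make_modulator(c(1, 1, 1))
  labeled <- label_by_centroid(pockets, list(mod))
  expect_equal(set_labels(labeled), c(1L, 0L))
  expect_equal(sum(set_labels(labeled)), 1L)
  # degenerate single pocket
  one <- label_by_centroid(pockets[1], list(mod))
  expect_equal(set_labels(one), 1L)
})

test_that("centroid labeling agrees with an exhaustive argmin oracle", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 25
    cents <- matrix(runif(n * 3, -40, 40), ncol = 3)
    pockets <- lapply(seq_len(n), function(i)
      make_pocket("T", i, i, centers = rbind(cents[i, ])))
    mxyz <- matrix(runif(9, -40, 40), ncol = 3)
    mod <- make_modulator(mxyz)
    labeled <- label_by_centroid(pockets, list(mod))
    mc <- colMeans(mxyz)
    d <- apply(cents, 1, function(p) sqrt(sum((p - mc)^2)))
    expect_equal(which(set_labels(labeled) == 1L), which.min(d))
  }
})

test_that("exact centroid ties break toward the better rank, with a warning", {
  pockets <- list(
    make_pocket("T", 1, 2, centers = rbind(c(5, 0, 0))),
    make_pocket("T", 2, 1, centers = rbind(c(-5, 0, 0)))
  )
  mod <- make_modulator(c(0, 0, 0))
  expect_warning(labeled <- label_by_centroid(pockets, list(mod)), "tie")
  expect_equal(set_labels(labeled), c(0L, 1L)) # rank 1 wins
})

test_that("both schemes are invariant under rigid translation", {
  g <- generate_geometric_protein(5, 4, seed = 23, out_dir = tempfile())
  s <- read_structure(g$pdb_path)
  mods <- extract_modulators(s)
  recs <- parse_fpocket_dir(g$fpocket_dir)
  lc <- set_labels(label_by_contact(recs, mods, s))
  lz <- set_labels(label_by_centroid(recs, mods, s))
  t_off <- c(13.5, -7.25, 101)
  s$atoms$x <- s$atoms$x + t_off[1]
  s$atoms$y <- s$atoms$y + t_off[2]
  s$atoms$z <- s$atoms$z + t_off[3]
  mods_t <- lapply(mods, function(m) {
    m$xyz <- sweep(m$xyz, 2, t_off, "+"); m
  })
  recs_t <- lapply(recs, function(r) {
    r$centers <- sweep(r$centers, 2, t_off, "+"); r
  })
  expect_equal(set_labels(label_by_contact(recs_t, mods_t, s)), lc)
  expect_equal(set_labels(label_by_centroid(recs_t, mods_t, s)), lz)
})

test_that("labeling reports serialize one row per pocket", {
  g <- generate_geometric_protein(3, 1, seed = 5, out_dir = tempfile())
  s <- read_structure(g$pdb_path)
  labeled <- label_by_centroid(parse_fpocket_dir(g$fpocket_dir),
                               extract_modulators(s), s)
  path <- tempfile(fileext = ".tsv")
  write_labeling_report(list(labeled), path)
  rep_tab <- utils::read.delim(path)
  expect_equal(nrow(rep_tab), 3)
  expect_equal(sum(rep_tab$label), 1)
  expect_true(all(rep_tab$scheme == "centroid"))
})
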