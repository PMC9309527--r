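# Builders for small in-code fixtures: fixed-column PDB text and FPocket
# info files written to tempdir.

# One PDB line from explicit fields (fixed columns, incl. altloc + occupancy).
pdb_line <- function(record, eleno, name, resid, chain, resno, x, y, z,
                     alt = " ", occ = 1, elesy = "C", insert = " ") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, nm, alt, resid, chain, resno, insert,
          x, y, z, occ, 0, elesy)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A 4-atom, single-chain toy structure.
toy_pdb <- function() {
  write_pdb_fixture(c(
    pdb_line("ATOM", 1, "N",  "ALA", "A", 1, 0, 0, 0, elesy = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line("ATOM", 3, "C",  "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_line("ATOM", 4, "O",  "ALA", "A", 1, 1.8, 2.6, 0, elesy = "O")
  ))
}

# FPocket-style info file with the given scores; all 19 descriptors per
# pocket unless `drop` names keys to omit from every block.
write_info_fixture <- function(scores, drop = character(),
                               path = tempfile(fileext = ".txt")) {
  schema <- descriptor_schema()
  lines <- character()
  for (p in seq_along(scores)) {
    lines <- c(lines, sprintf("Pocket %d :", p))
    for (key in schema) {
      if (key %in% drop) next
      val <- if (key == "score") scores[p] else p + which(schema == key) / 10
      lines <- c(lines, sprintf("\t%s :\t%.4f",
                                allopocket:::INFO_DISPLAY_NAMES[[key]], val))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

# Minimal pocket_record for labeling tests (no file round trip needed).
make_pocket <- function(protein_id, pocket_index, rank, score = NULL,
                        residues = NULL, centers = NULL) {
  schema <- descriptor_schema()
  desc <- stats::setNames(rep(0, length(schema)), schema)
  desc["score"] <- if (is.null(score)) -rank else score
  rec <- structure(
    list(protein_id = protein_id, pocket_index = as.integer(pocket_index),
         rank = as.integer(rank), score = unname(desc[["score"]]),
         descriptors = desc, imputed = character(),
         residues = residues, centers = centers, label = NA_integer_),
    class = "pocket_record"
  )
  rec
}

# Minimal protein_structure from an atom data.frame.
make_structure <- function(id, atoms) {
  structure(list(id = id, chains = sort(unique(atoms$chain[atoms$record == "ATOM"])),
                 atoms = atoms),
            class = "protein_structure")
}

atom_row <- function(record, eleno, elety, resid, chain, resno, x, y, z,
                     elesy = "C") {
  data.frame(record = record, eleno = eleno, elety = elety, resid = resid,
             chain = chain, resno = resno, insert = "", x = x, y = y, z = z,
             elesy = elesy, stringsAsFactors = FALSE)
}
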