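# Residue names never treated as allosteric modulators: waters, common
# crystallographic ions, cryoprotectants. User-overridable in
# extract_modulators().
DEFAULT_MODULATOR_EXCLUSIONS <- c(
  "HOH", "WAT", "DOD",
  "NA", "K", "CL", "MG", "ZN", "CA", "MN", "SO4", "PO4",
  "GOL", "EDO", "PEG"
)

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HETATM records (via bio3d) into a flat atom table.
#' Alternate locations are resolved by keeping, per atom, the altloc with
#' the highest occupancy (ties broken alphabetically, so 'A' wins).
#'
#' @param path Path to a PDB file.
#' @param chain_filter Optional single chain identifier. When given, only
#'   that chain's ATOM records are retained. HETATM records from *all*
#'   chains are kept by default, because bound modulators are frequently
#'   assigned their own chain; set `strict_chain = TRUE` to restrict
#'   HETATMs to the selected chain as well.
#' @param strict_chain Logical; see `chain_filter`.
#' @return An object of class `protein_structure`: a list with `id`,
#'   `chains`, and `atoms` (a data.frame with columns `record`, `eleno`,
#'   `elety`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `elesy`).
#' @export
read_structure <- function(path, chain_filter = NULL, strict_chain = FALSE) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  validate_pdb_lines(readLines(path, warn = FALSE), path)
  # rm.alt = FALSE: altloc resolution is done here (highest occupancy,
  # ties to 'A'), not by dropping everything but 'A'
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  atoms <- pdb$atom
  if (!any(atoms$type == "ATOM")) {
    stop("No ATOM records in ", path, call. = FALSE)
  }
  atoms <- resolve_altlocs(atoms)
  if (!is.null(chain_filter)) {
    stopifnot(length(chain_filter) == 1L)
    keep_atom <- atoms$type != "ATOM" | (!is.na(atoms$chain) & atoms$chain == chain_filter)
    if (strict_chain) {
      keep_atom <- !is.na(atoms$chain) & atoms$chain == chain_filter
    }
    atoms <- atoms[keep_atom, , drop = FALSE]
    if (!any(atoms$type == "ATOM")) {
      stop("Chain filter '", chain_filter, "' leaves no ATOM records in ", path,
           call. = FALSE)
    }
  }
  out <- data.frame(
    record = atoms$type,
    eleno = atoms$eleno,
    elety = atoms$elety,
    resid = atoms$resid,
    chain = ifelse(is.na(atoms$chain), "", atoms$chain),
    resno = atoms$resno,
    insert = ifelse(is.na(atoms$insert), "", atoms$insert),
    x = atoms$x, y = atoms$y, z = atoms$z,
    elesy = ifelse(is.na(atoms$elesy), "", atoms$elesy),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("Non-finite coordinates in ", path, call. = FALSE)
  }
  structure(
    list(
      id = tools::file_path_sans_ext(basename(path)),
      chains = sort(unique(out$chain[out$record == "ATOM"])),
      atoms = out
    ),
    class = "protein_structure"
  )
}

# Fail early, with a line number, on coordinate fields that are not numeric.
validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    stop("No ATOM records in ", path, call. = FALSE)
  }
  idx <- which(is_atom)
  coords <- cbind(
    substr(lines[idx], 31, 38),
    substr(lines[idx], 39, 46),
    substr(lines[idx], 47, 54)
  )
  bad <- which(apply(coords, 1, function(v) any(is.na(suppressWarnings(as.numeric(v))))))
  if (length(bad) > 0) {
    stop("Unparseable coordinate field at line ", idx[bad[1]], " of ", path,
         call. = FALSE)
  }
  invisible(TRUE)
}

# Keep one altloc per (chain, resno, insert, atom name): highest occupancy,
# ties broken by altloc letter ('A' before 'B').
resolve_altlocs <- function(atoms) {
  alt <- atoms$alt
  if (is.null(alt) || all(is.na(alt) | alt == "")) {
    return(atoms)
  }
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  alt_chr <- ifelse(is.na(alt) | alt == "", "", alt)
  key <- paste(atoms$type, atoms$chain, atoms$resno, atoms$insert,
               atoms$resid, atoms$elety, sep = "\r")
  ord <- order(key, -occ, alt_chr)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

#' Write a structure back to PDB format
#'
#' Fixed-column ATOM/HETATM serialization; coordinates at PDB precision
#' (3 decimals). Used for round-trip checks and synthetic fixtures.
#'
#' @param struct A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "protein_structure"))
  a <- struct$atoms
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$eleno,
    format_atom_name(a$elety), a$resid,
    ifelse(a$chain == "", " ", a$chain), a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, 1, 0, a$elesy
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# PDB atom-name column convention: names of <4 chars start in column 14.
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Extract modulator (HETATM) groups from a structure
#'
#' Every HETATM residue group whose residue name is not on the exclusion
#' list is treated as a candidate allosteric modulator. Hydrogens are
#' dropped; groups are returned in (chain, residue number) order.
#'
#' @param struct A `protein_structure`.
#' @param exclusions Character vector of residue names to ignore
#'   (default: waters, common ions, cryoprotectants).
#' @return A list of `modulator` objects (fields `resid`, `chain`, `resno`,
#'   `xyz` — an n x 3 matrix of heavy-atom coordinates in Angstrom). Empty
#'   list when the structure is apo.
#' @export
extract_modulators <- function(struct, exclusions = DEFAULT_MODULATOR_EXCLUSIONS) {
  stopifnot(inherits(struct, "protein_structure"))
  het <- struct$atoms[struct$atoms$record == "HETATM", , drop = FALSE]
  het <- het[!(toupper(het$resid) %in% toupper(exclusions)), , drop = FALSE]
  het <- het[!is_hydrogen(het$elety, het$elesy), , drop = FALSE]
  if (nrow(het) == 0) {
    return(list())
  }
  key <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  groups <- split(seq_len(nrow(het)), key)
  mods <- lapply(groups, function(ix) {
    g <- het[ix, , drop = FALSE]
    structure(
      list(
        resid = g$resid[1],
        chain = g$chain[1],
        resno = g$resno[1],
        xyz = as.matrix(g[, c("x", "y", "z")])
      ),
      class = "modulator"
    )
  })
  ord <- order(
    vapply(mods, function(m) m$chain, ""),
    vapply(mods, function(m) m$resno, 0)
  )
  unname(mods[ord])
}

is_hydrogen <- function(elety, elesy) {
  sym <- toupper(trimws(elesy))
  by_sym <- sym %in% c("H", "D")
  # fall back to the atom-name heuristic when the element column is blank
  nm <- toupper(trimws(elety))
  by_name <- grepl("^[0-9]*[HD]", nm) & !grepl("^H[EFGO]$", nm)
  ifelse(sym != "", by_sym, by_name)
}

#' Centroid of a point set
#'
#' Arithmetic mean per coordinate, in the structure's native Angstrom frame.
#'
#' @param points An n x 3 numeric matrix (rows are points).
#' @return A length-3 numeric vector.
#' @export
centroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) {
    stop("centroid of an empty point set is undefined", call. = FALSE)
  }
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  colMeans(points)
}
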