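# FPocket output parsing: per-pocket descriptor blocks from <name>_info.txt,
# pocket residues from pockets/pocketN_atm.pdb, alpha-sphere centers from
# pockets/pocketN_vert.pqr. FPocket itself is never run here; its
# descriptors and scores are consumed as-is.

#' The 19 pocket descriptors used as model features
#'
#' Normalized (lowercase, underscore) names of FPocket's per-pocket
#' descriptors, in canonical column order. The first entry, `score`, is
#' FPocket's pocket score and drives the rank used by the baseline
#' predictor and the training cutoff.
#'
#' @return Character vector of length 19.
#' @export
descriptor_schema <- function() {
  c(
    "score",
    "druggability_score",
    "number_of_alpha_spheres",
    "total_sasa",
    "polar_sasa",
    "apolar_sasa",
    "volume",
    "mean_local_hydrophobic_density",
    "mean_alpha_sphere_radius",
    "mean_alpha_sphere_solvent_access",
    "apolar_alpha_sphere_proportion",
    "hydrophobicity_score",
    "volume_score",
    "polarity_score",
    "charge_score",
    "proportion_of_polar_atoms",
    "alpha_sphere_density",
    "cent_pock_max_dist",
    "flexibility"
  )
}

# Field-name variants across FPocket versions, mapped onto the schema.
DESCRIPTOR_SYNONYMS <- c(
  "pocket_score"                          = "score",
  "real_volume"                           = "volume",
  "real_volume_monte_carlo"               = "volume",
  "apolar_asa"                            = "apolar_sasa",
  "polar_asa"                             = "polar_sasa",
  "total_asa"                             = "total_sasa",
  "number_of_v._vertices"                 = "number_of_alpha_spheres",
  "mean_alp._sph._solvent_access"         = "mean_alpha_sphere_solvent_access",
  "mean_alp_sph_solvent_access"           = "mean_alpha_sphere_solvent_access",
  "apolar_alpha_sphere_prop."             = "apolar_alpha_sphere_proportion",
  "apolar_alpha_sphere_prop"              = "apolar_alpha_sphere_proportion",
  "proportion_of_polar_atoms_2"           = "proportion_of_polar_atoms",
  "cent._of_mass_-_alpha_sphere_max_dist" = "cent_pock_max_dist",
  "center_of_mass_max_dist"               = "cent_pock_max_dist"
)

normalize_descriptor_key <- function(key) {
  k <- tolower(trimws(key))
  k <- gsub("[[:space:]]+", "_", k)
  k <- gsub(":$", "", k)
  unname(ifelse(k %in% names(DESCRIPTOR_SYNONYMS), DESCRIPTOR_SYNONYMS[k], k))
}

#' Parse an FPocket info file into pocket records
#'
#' Reads blocks of the form `Pocket N :` followed by `key : value` lines.
#' Descriptor keys are normalized and matched against [descriptor_schema()];
#' unknown keys produce a warning and are ignored, missing keys are imputed
#' (see `impute`) and flagged. Records are returned in pocket-index order,
#' with `rank` assigned by descending pocket score (ties broken by ascending
#' pocket index, FPocket's own output order).
#'
#' @param path Path to a `<name>_info.txt` file.
#' @param protein_id Identifier stored on every record.
#' @param impute Named numeric vector of fallback values for missing
#'   descriptors (e.g. persisted training medians). Descriptors absent from
#'   both the file and `impute` default to 0.
#' @return A list of `pocket_record` objects: fields `protein_id`,
#'   `pocket_index`, `rank`, `score`, `descriptors` (named numeric, length
#'   19), `imputed` (character vector of imputed keys), and empty `residues`
#'   / `centers` slots to be filled by [parse_pocket_atoms()].
#' @export
parse_info_file <- function(path, protein_id, impute = NULL) {
  if (!file.exists(path)) {
    stop("FPocket info file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  head_ix <- grep("^Pocket[[:space:]]+[0-9]+", lines)
  if (length(head_ix) == 0) {
    stop("No 'Pocket N :' blocks in ", path, call. = FALSE)
  }
  bounds <- c(head_ix, length(lines) + 1L)
  schema <- descriptor_schema()
  records <- vector("list", length(head_ix))
  for (i in seq_along(head_ix)) {
    idx <- as.integer(sub("^Pocket[[:space:]]+([0-9]+).*$", "\\1", lines[head_ix[i]]))
    block <- lines[seq(head_ix[i] + 1L, bounds[i + 1L] - 1L)]
    kv <- grep(":", block, fixed = TRUE, value = FALSE)
    desc <- stats::setNames(rep(NA_real_, length(schema)), schema)
    for (j in kv) {
      line <- block[j]
      pos <- regexpr(":", line, fixed = TRUE)
      key <- normalize_descriptor_key(substr(line, 1, pos - 1))
      val_str <- trimws(substr(line, pos + 1, nchar(line)))
      if (!key %in% schema) {
        warning("Unknown descriptor key '", key, "' in ", path, call. = FALSE)
        next
      }
      val <- suppressWarnings(as.numeric(val_str))
      if (is.na(val)) {
        stop("Malformed numeric for '", key, "' at line ",
             head_ix[i] + j, " of ", path, call. = FALSE)
      }
      desc[key] <- val
    }
    missing <- names(desc)[is.na(desc)]
    for (key in missing) {
      desc[key] <- if (!is.null(impute) && key %in% names(impute)) impute[[key]] else 0
    }
    records[[i]] <- new_pocket_record(
      protein_id = protein_id, pocket_index = idx,
      descriptors = desc, imputed = missing
    )
  }
  records <- records[order(vapply(records, function(r) r$pocket_index, 0L))]
  assign_ranks(records)
}

new_pocket_record <- function(protein_id, pocket_index, descriptors,
                              imputed = character(), residues = NULL,
                              centers = NULL, label = NA_integer_) {
  structure(
    list(
      protein_id = protein_id,
      pocket_index = as.integer(pocket_index),
      rank = NA_integer_,
      score = unname(descriptors[["score"]]),
      descriptors = descriptors,
      imputed = imputed,
      residues = residues,
      centers = centers,
      label = label
    ),
    class = "pocket_record"
  )
}

# Rank 1..n by descending pocket score; ties by ascending pocket index.
assign_ranks <- function(records) {
  scores <- vapply(records, function(r) r$score, 0)
  idx <- vapply(records, function(r) r$pocket_index, 0L)
  ord <- order(-scores, idx)
  for (pos in seq_along(ord)) {
    records[[ord[pos]]]$rank <- pos
  }
  records
}

#' Parse one pocket's atom and vertex files
#'
#' Residues come from `pocketN_atm.pdb` (deduplicated ATOM records); alpha-
#' sphere centers come from `pocketN_vert.pqr`. If one of the two files is
#' missing a partial result is returned with a warning; if both are missing,
#' an error.
#'
#' @param pockets_dir The FPocket `pockets/` directory.
#' @param pocket_index FPocket pocket number.
#' @return List with `residues` (data.frame: `chain`, `resno`, `resid`) and
#'   `centers` (n x 3 matrix, possibly 0-row).
#' @export
parse_pocket_atoms <- function(pockets_dir, pocket_index) {
  atm <- file.path(pockets_dir, sprintf("pocket%d_atm.pdb", pocket_index))
  vert <- file.path(pockets_dir, sprintf("pocket%d_vert.pqr", pocket_index))
  has_atm <- file.exists(atm)
  has_vert <- file.exists(vert)
  if (!has_atm && !has_vert) {
    stop("Neither ", atm, " nor ", vert, " exists", call. = FALSE)
  }
  residues <- data.frame(chain = character(), resno = integer(),
                         resid = character(), stringsAsFactors = FALSE)
  centers <- matrix(numeric(), ncol = 3)
  if (has_atm) {
    pdb <- bio3d::read.pdb(atm, verbose = FALSE)
    a <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    key <- paste(a$chain, a$resno, a$resid, sep = "\r")
    a <- a[!duplicated(key), , drop = FALSE]
    residues <- data.frame(
      chain = ifelse(is.na(a$chain), "", a$chain),
      resno = a$resno, resid = a$resid, stringsAsFactors = FALSE
    )
    residues <- residues[order(residues$chain, residues$resno), , drop = FALSE]
    rownames(residues) <- NULL
  } else {
    warning("Missing ", atm, "; residues unavailable for pocket ",
            pocket_index, call. = FALSE)
  }
  if (has_vert) {
    centers <- parse_vertex_file(vert)
  } else {
    warning("Missing ", vert, "; sphere centers unavailable for pocket ",
            pocket_index, call. = FALSE)
  }
  list(residues = residues, centers = centers)
}

# FPocket vertex PQR: ATOM/HETATM records whose xyz are the alpha-sphere
# centers (fixed PDB-like coordinate columns).
parse_vertex_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  if (length(rec) == 0) {
    return(matrix(numeric(), ncol = 3))
  }
  xyz <- t(vapply(rec, function(l) {
    v <- suppressWarnings(as.numeric(c(
      substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)
    )))
    if (any(is.na(v))) {
      # whitespace-delimited dialect: fields 6-8 after record/serial/name/res/num
      tok <- strsplit(trimws(l), "[[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(tok[6:8]))
    }
    v
  }, numeric(3)))
  if (any(is.na(xyz))) {
    stop("Unparseable vertex coordinates in ", path, call. = FALSE)
  }
  unname(xyz)
}

#' Parse a full FPocket output directory
#'
#' Convenience wrapper: reads `<name>_info.txt` and, for every pocket,
#' its atom/vertex files.
#'
#' @param out_dir An FPocket `<name>_out` directory.
#' @param protein_id Identifier; defaults to the directory stem minus
#'   `_out`.
#' @param impute Passed to [parse_info_file()].
#' @return List of `pocket_record`s with `residues` and `centers` filled.
#' @export
parse_fpocket_dir <- function(out_dir, protein_id = NULL, impute = NULL) {
  if (!dir.exists(out_dir)) {
    stop("FPocket output directory not found: ", out_dir, call. = FALSE)
  }
  info <- list.files(out_dir, pattern = "_info\\.txt$", full.names = TRUE)
  if (length(info) != 1) {
    stop("Expected exactly one *_info.txt in ", out_dir, call. = FALSE)
  }
  if (is.null(protein_id)) {
    protein_id <- sub("_out$", "", basename(out_dir))
  }
  records <- parse_info_file(info[1], protein_id, impute = impute)
  pockets_dir <- file.path(out_dir, "pockets")
  for (i in seq_along(records)) {
    geom <- parse_pocket_atoms(pockets_dir, records[[i]]$pocket_index)
    records[[i]]$residues <- geom$residues
    records[[i]]$centers <- geom$centers
  }
  records
}

#' Flatten pocket records into a feature table
#'
#' @param records List of `pocket_record`s (possibly across proteins).
#' @return Data.frame with columns `protein_id`, `pocket_index`, `rank`,
#'   the 19 descriptors in schema order, and `label` (NA when unset).
#' @export
feature_table <- function(records) {
  schema <- descriptor_schema()
  if (length(records) == 0) {
    tab <- data.frame(
      protein_id = character(), pocket_index = integer(), rank = integer(),
      stringsAsFactors = FALSE
    )
    for (col in schema) tab[[col]] <- numeric()
    tab$label <- integer()
    return(tab)
  }
  desc <- t(vapply(records, function(r) r$descriptors[schema], numeric(length(schema))))
  tab <- data.frame(
    protein_id = vapply(records, function(r) r$protein_id, ""),
    pocket_index = vapply(records, function(r) r$pocket_index, 0L),
    rank = vapply(records, function(r) r$rank, 0L),
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(desc))
  tab$label <- vapply(records, function(r) as.integer(r$label), 0L)
  key <- paste(tab$protein_id, tab$pocket_index)
  if (anyDuplicated(key)) {
    stop("Duplicate (protein_id, pocket_index) pairs in records", call. = FALSE)
  }
  tab <- tab[order(tab$protein_id, tab$pocket_index), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

feature_table_columns <- function() {
  c("protein_id", "pocket_index", "rank", descriptor_schema(), "label")
}

#' Write / read a feature table as CSV
#'
#' Lossless round trip of identifiers, rank, the 19 descriptors, and label;
#' pocket geometry (residues, sphere centers) is not carried. The header
#' is fixed; a schema mismatch on read is an error naming the missing and
#' extra columns.
#'
#' @param tab Feature table data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the feature table (read).
#' @export
write_feature_table <- function(tab, path) {
  stopifnot(identical(names(tab), feature_table_columns()))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(protein_id = "character"))
  expected <- feature_table_columns()
  if (!identical(names(tab), expected)) {
    stop("Feature table schema mismatch. Missing: ",
         paste(setdiff(expected, names(tab)), collapse = ", "),
         "; extra: ", paste(setdiff(names(tab), expected), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(tab$label) & !tab$label %in% c(0L, 1L)
  if (any(bad)) {
    stop("Labels must be 0/1 or NA", call. = FALSE)
  }
  tab
}
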