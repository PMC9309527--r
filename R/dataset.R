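# Protein-level splitting and rank-cutoff under-sampling.
#
# Pocket data are heavily imbalanced (roughly 1 positive in 20 pockets);
# because positives concentrate at good FPocket ranks, keeping only each
# training protein's top-k pockets raises the positive rate seen by the
# learner without fabricating samples. The cutoff applies to the training
# split only — validation and test are always evaluated on all pockets.

#' Randomly split proteins into train / validation / test
#'
#' Uniform partition at the protein level (never by pocket, so no
#' leakage), reproducible under `seed`.
#'
#' @param protein_ids Character vector of unique protein ids.
#' @param counts Integer vector `c(n_train, n_val, n_test)`; must sum to
#'   `length(protein_ids)`.
#' @param seed Integer RNG seed.
#' @return A `split_spec`: list with `train`, `validation`, `test` id
#'   vectors and the `seed` and `counts` used.
#' @export
split_proteins <- function(protein_ids, counts, seed) {
  protein_ids <- as.character(protein_ids)
  stopifnot(!anyDuplicated(protein_ids), length(counts) == 3)
  counts <- as.integer(counts)
  if (sum(counts) != length(protein_ids)) {
    stop("counts (", paste(counts, collapse = "/"), ") must sum to ",
         length(protein_ids), " proteins", call. = FALSE)
  }
  perm <- with_seed_local(seed, sample(protein_ids))
  structure(
    list(
      train = sort(perm[seq_len(counts[1])]),
      validation = sort(perm[counts[1] + seq_len(counts[2])]),
      test = sort(perm[counts[1] + counts[2] + seq_len(counts[3])]),
      counts = counts,
      seed = as.integer(seed)
    ),
    class = "split_spec"
  )
}

# evaluate expr under a fixed seed, then restore the caller's RNG state
with_seed_local <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Save / load a split manifest
#'
#' JSON manifest (seed, counts, id lists) sufficient for an exact rerun.
#'
#' @param split A `split_spec`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `split_spec` (read).
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, counts = split$counts,
         train = split$train, validation = split$validation,
         test = split$test),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(train = sort(m$train), validation = sort(m$validation),
         test = sort(m$test), counts = as.integer(m$counts),
         seed = as.integer(m$seed)),
    class = "split_spec"
  )
}

#' Keep only a protein's top-k pockets (rank-cutoff under-sampling)
#'
#' Retains pockets with FPocket rank at most `k`; a protein with fewer
#' than `k` pockets keeps all of them. Labels and descriptors are never
#' modified, only membership — a positive pocket ranked worse than `k` is
#' dropped (the count of dropped positives is attached as an attribute so
#' callers can log it).
#'
#' @param labeled_set A `labeled_pocket_set`.
#' @param k Cutoff position, an integer >= 1.
#' @return The filtered `labeled_pocket_set`, with attribute
#'   `dropped_positives`.
#' @export
apply_cutoff <- function(labeled_set, k) {
  if (!is.numeric(k) || k < 1) {
    stop("Cutoff position k must be >= 1", call. = FALSE)
  }
  ranks <- vapply(labeled_set$pockets, function(p) p$rank, 0L)
  keep <- ranks <= k
  dropped_pos <- sum(set_labels(labeled_set)[!keep])
  labeled_set$pockets <- labeled_set$pockets[keep]
  attr(labeled_set, "dropped_positives") <- dropped_pos
  labeled_set
}

#' Assemble a training matrix from labeled pocket sets
#'
#' Rows ordered by (protein id, pocket index); feature columns in
#' [descriptor_schema()] order; label vector aligned.
#'
#' @param labeled_sets List of `labeled_pocket_set`s.
#' @return List with `features` (data.frame incl. identifiers and rank),
#'   `x` (numeric matrix of the 19 descriptors), and `y` (integer labels).
#' @export
assemble_matrix <- function(labeled_sets) {
  records <- unlist(lapply(labeled_sets, function(s) s$pockets),
                    recursive = FALSE)
  if (length(records) > 0 &&
      anyNA(vapply(records, function(p) as.integer(p$label), 0L))) {
    stop("All pockets must be labeled before matrix assembly", call. = FALSE)
  }
  tab <- feature_table(records)
  x <- as.matrix(tab[, descriptor_schema(), drop = FALSE])
  list(features = tab, x = x, y = tab$label)
}
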