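# Binary allosteric labels for detected pockets, under two schemes:
#  * contact  — a pocket is positive iff it contains at least one residue
#               with a heavy atom within `contact_cutoff` Angstrom of any
#               modulator heavy atom; several pockets may be positive.
#  * centroid — exactly one pocket is positive: the one whose centroid
#               (mean alpha-sphere center) is closest to the modulator's
#               heavy-atom centroid.

#' Label pockets by modulator contact
#'
#' A residue "binds" a modulator iff any heavy-atom pair distance is at
#' most `contact_cutoff` (default 4.5 Angstrom, the conventional
#' heavy-atom ligand-contact threshold). A pocket is positive iff it
#' contains at least one binding residue; a protein may therefore carry
#' more than one positive pocket.
#'
#' @param pockets List of `pocket_record`s with `residues` filled.
#' @param modulators Non-empty list of `modulator` objects.
#' @param struct The `protein_structure` the pockets belong to (supplies
#'   residue atom coordinates).
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @return A `labeled_pocket_set`: list with `protein_id`, `pockets`
#'   (records with `label` set), `scheme = "contact"`, `modulator_ref`.
#' @export
label_by_contact <- function(pockets, modulators, struct, contact_cutoff = 4.5) {
  stopifnot(length(pockets) > 0)
  if (length(modulators) == 0) {
    stop("No modulators found; supply a modulator override or skip this ",
         "structure for contact labeling", call. = FALSE)
  }
  mod_xyz <- do.call(rbind, lapply(modulators, function(m) m$xyz))
  atoms <- struct$atoms[struct$atoms$record == "ATOM", , drop = FALSE]
  # residues with any heavy atom within cutoff of any modulator atom
  heavy <- atoms[!is_hydrogen(atoms$elety, atoms$elesy), , drop = FALSE]
  d2min <- min_dist2_per_row(as.matrix(heavy[, c("x", "y", "z")]), mod_xyz)
  binding <- d2min <= contact_cutoff^2
  binding_res <- unique(paste(heavy$chain[binding], heavy$resno[binding], sep = "\r"))
  for (i in seq_along(pockets)) {
    res <- pockets[[i]]$residues
    if (is.null(res) || nrow(res) == 0) {
      pockets[[i]]$label <- 0L
      next
    }
    keys <- paste(res$chain, res$resno, sep = "\r")
    pockets[[i]]$label <- as.integer(any(keys %in% binding_res))
  }
  new_labeled_set(struct$id, pockets, "contact",
                  modulator_ref = modulator_ref(modulators))
}

# squared distance from each row of a to its nearest row of b
min_dist2_per_row <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  cross <- a %*% t(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * cross
  pmax(apply(d2, 1, min), 0)
}

#' Label pockets by closest centroid
#'
#' Exactly one pocket per modulator is labeled positive: the argmin of the
#' Euclidean distance between the pocket centroid and the modulator's
#' heavy-atom centroid. The pocket centroid is the mean of its alpha-sphere
#' vertex centers; when a pocket has no vertices, the mean of its residue
#' atom coordinates in `struct` is used instead (logged). With several
#' modulators, one positive is chosen per modulator and the labels are
#' OR-ed. Exact distance ties break toward the better (lower) FPocket
#' rank, with a warning.
#'
#' @inheritParams label_by_contact
#' @return A `labeled_pocket_set` with `scheme = "centroid"` and a
#'   `distances` matrix (pockets x modulators) recording the decision.
#' @export
label_by_centroid <- function(pockets, modulators, struct = NULL) {
  stopifnot(length(pockets) > 0)
  if (length(modulators) == 0) {
    stop("No modulators found; centroid labeling needs at least one",
         call. = FALSE)
  }
  cents <- t(vapply(pockets, function(p) pocket_centroid(p, struct), numeric(3)))
  labels <- integer(length(pockets))
  dists <- matrix(NA_real_, nrow = length(pockets), ncol = length(modulators))
  ranks <- vapply(pockets, function(p) p$rank, 0L)
  for (j in seq_along(modulators)) {
    mc <- centroid(modulators[[j]]$xyz)
    d <- sqrt(rowSums(sweep(cents, 2, mc)^2))
    dists[, j] <- d
    winners <- which(d == min(d))
    if (length(winners) > 1) {
      warning("Centroid distance tie among pockets ",
              paste(vapply(pockets[winners], function(p) p$pocket_index, 0L),
                    collapse = ", "),
              "; breaking by FPocket rank", call. = FALSE)
      winners <- winners[which.min(ranks[winners])]
    }
    labels[winners] <- 1L
  }
  for (i in seq_along(pockets)) pockets[[i]]$label <- labels[i]
  out <- new_labeled_set(
    if (!is.null(struct)) struct$id else pockets[[1]]$protein_id,
    pockets, "centroid", modulator_ref = modulator_ref(modulators)
  )
  out$distances <- dists
  out
}

pocket_centroid <- function(pocket, struct = NULL) {
  if (!is.null(pocket$centers) && nrow(pocket$centers) > 0) {
    return(centroid(pocket$centers))
  }
  if (!is.null(struct) && !is.null(pocket$residues) && nrow(pocket$residues) > 0) {
    atoms <- struct$atoms
    keys <- paste(atoms$chain, atoms$resno, sep = "\r")
    want <- paste(pocket$residues$chain, pocket$residues$resno, sep = "\r")
    sel <- atoms$record == "ATOM" & keys %in% want
    if (any(sel)) {
      message("Pocket ", pocket$pocket_index,
              ": no alpha-sphere vertices; falling back to residue-atom centroid")
      return(centroid(as.matrix(atoms[sel, c("x", "y", "z")])))
    }
  }
  stop("Pocket ", pocket$pocket_index,
       " has neither sphere centers nor resolvable residues", call. = FALSE)
}

modulator_ref <- function(modulators) {
  paste(vapply(modulators, function(m)
    sprintf("%s/%s%d", m$resid, m$chain, m$resno), ""), collapse = "+")
}

new_labeled_set <- function(protein_id, pockets, scheme, modulator_ref = "") {
  labels <- vapply(pockets, function(p) as.integer(p$label), 0L)
  stopifnot(!anyNA(labels), all(labels %in% c(0L, 1L)))
  if (scheme == "centroid" && sum(labels) < 1) {
    stop("Centroid scheme must yield at least one positive", call. = FALSE)
  }
  structure(
    list(protein_id = protein_id, pockets = pockets, scheme = scheme,
         modulator_ref = modulator_ref),
    class = "labeled_pocket_set"
  )
}

#' Labels of a labeled pocket set
#' @param set A `labeled_pocket_set`.
#' @return Integer 0/1 vector aligned with `set$pockets`.
#' @export
set_labels <- function(set) {
  vapply(set$pockets, function(p) as.integer(p$label), 0L)
}

#' Write a labeling report
#'
#' TSV with one row per pocket: protein, pocket index, rank, label, scheme,
#' and (centroid scheme) the decision distance.
#'
#' @param sets List of `labeled_pocket_set`s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labeling_report <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    d <- if (!is.null(s$distances)) apply(s$distances, 1, min) else NA_real_
    data.frame(
      protein_id = s$protein_id,
      pocket_index = vapply(s$pockets, function(p) p$pocket_index, 0L),
      rank = vapply(s$pockets, function(p) p$rank, 0L),
      label = set_labels(s),
      scheme = s$scheme,
      decision_distance = round(d, 3),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
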