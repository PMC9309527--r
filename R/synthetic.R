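# Synthetic benchmark generator.
#
# Emulates the statistical structure of curated allosteric-protein pocket
# data at two fidelities: (a) feature-table level — per-protein pocket
# counts from a truncated negative binomial (min 4, max 91, mean 25),
# ~4.87% positive pockets overall, the positive pocket at score rank 1
# with probability 0.706, and class-conditional Gaussian descriptors whose
# separation is a tunable signal strength; (b) geometric level — toy PDB
# structures plus FPocket-style output directories where one modulator
# sits adjacent to a designated pocket, so contact and centroid labeling
# agree by construction.

#' Synthetic dataset configuration
#'
#' @param n_proteins Number of proteins.
#' @param pocket_min,pocket_max,pocket_mean Truncated-negative-binomial
#'   summaries of pockets per protein.
#' @param positive_rate Target overall fraction of positive pockets.
#'   Every protein gets one guaranteed positive; extra positives are added
#'   with the per-pocket probability that makes the expected overall rate
#'   equal the target.
#' @param top1_enrichment Probability that a protein's (primary) positive
#'   pocket has score rank 1; remaining mass is uniform over the other
#'   ranks. `NA` means chance placement (uniform over all ranks), which
#'   removes any score-label association — use together with
#'   `signal_strength = 0` for a full null dataset.
#' @param signal_strength In [0, 1]: scales the class-conditional mean
#'   shift of the descriptors. 0 = labels independent of the descriptors;
#'   1 = effectively linearly separable classes.
#' @param seed Integer master seed; every protein draws from a derived
#'   substream, so single proteins are reproducible in isolation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_proteins = 204L, pocket_min = 4L,
                             pocket_max = 91L, pocket_mean = 25,
                             positive_rate = 0.0487,
                             top1_enrichment = 0.706,
                             signal_strength = 0.35, seed = 1L) {
  stopifnot(n_proteins >= 1, pocket_min >= 1, pocket_max >= pocket_min,
            positive_rate > 0, positive_rate < 1,
            signal_strength >= 0, signal_strength <= 1)
  if (pocket_mean <= pocket_min || pocket_mean >= pocket_max) {
    stop("pocket_mean must lie strictly between pocket_min and pocket_max",
         call. = FALSE)
  }
  if (!is.na(top1_enrichment) &&
      (top1_enrichment < 0 || top1_enrichment > 1)) {
    stop("top1_enrichment must be in [0,1] or NA for chance placement",
         call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         pocket_min = as.integer(pocket_min),
         pocket_max = as.integer(pocket_max),
         pocket_mean = pocket_mean,
         positive_rate = positive_rate,
         top1_enrichment = top1_enrichment,
         signal_strength = signal_strength,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Truncated negative binomial on [min, max]: dispersion fixed at size = 2
# (long right tail); mu solved so the truncated mean hits the target.
pocket_count_pmf <- function(config) {
  support <- config$pocket_min:config$pocket_max
  trunc_mean <- function(mu) {
    w <- stats::dnbinom(support, size = 2, mu = mu)
    sum(support * w) / sum(w)
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - config$pocket_mean,
                       lower = 1, upper = 200)$root
  w <- stats::dnbinom(support, size = 2, mu = mu)
  list(support = support, prob = w / sum(w))
}

# Plausible location/scale per descriptor (order = descriptor_schema()).
# The score column is handled separately: it encodes the rank ordering.
descriptor_prior <- function() {
  schema <- descriptor_schema()
  mean <- c(score = 0, druggability_score = 0.3,
            number_of_alpha_spheres = 40, total_sasa = 150,
            polar_sasa = 60, apolar_sasa = 90, volume = 450,
            mean_local_hydrophobic_density = 15,
            mean_alpha_sphere_radius = 3.8,
            mean_alpha_sphere_solvent_access = 0.45,
            apolar_alpha_sphere_proportion = 0.5,
            hydrophobicity_score = 20, volume_score = 4,
            polarity_score = 8, charge_score = 1,
            proportion_of_polar_atoms = 40, alpha_sphere_density = 5,
            cent_pock_max_dist = 12, flexibility = 0.4)
  sd <- c(score = 1, druggability_score = 0.15,
          number_of_alpha_spheres = 20, total_sasa = 60, polar_sasa = 25,
          apolar_sasa = 45, volume = 180,
          mean_local_hydrophobic_density = 8,
          mean_alpha_sphere_radius = 0.3,
          mean_alpha_sphere_solvent_access = 0.1,
          apolar_alpha_sphere_proportion = 0.15,
          hydrophobicity_score = 12, volume_score = 1.2,
          polarity_score = 3, charge_score = 1.5,
          proportion_of_polar_atoms = 8, alpha_sphere_density = 2,
          cent_pock_max_dist = 4, flexibility = 0.15)
  list(mean = mean[schema], sd = sd[schema])
}

# Descriptors carrying the class signal; the mean shift is spread over
# them so the total Mahalanobis separation is 12 * signal_strength
# (separation 12 makes the Bayes error negligible — "separable").
SIGNAL_DESCRIPTORS <- c(
  "druggability_score", "volume", "apolar_sasa",
  "mean_local_hydrophobic_density", "hydrophobicity_score",
  "alpha_sphere_density"
)

protein_substream_seed <- function(master_seed, i) {
  (as.numeric(master_seed) * 7919 + i * 104729) %% 2147483647
}

#' Generate a synthetic pocket feature dataset
#'
#' @param config A [generator_config()].
#' @return List with `table` (a feature table, labels set), `truth`
#'   (per-protein manifest: pocket count, positive pocket indices, rank of
#'   the primary positive), and the echoed `config`.
#' @export
generate_feature_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  pmf <- pocket_count_pmf(config)
  prior <- descriptor_prior()
  schema <- descriptor_schema()
  shift <- stats::setNames(rep(0, length(schema)), schema)
  sep <- 12 * config$signal_strength
  shift[SIGNAL_DESCRIPTORS] <-
    sep / sqrt(length(SIGNAL_DESCRIPTORS)) * prior$sd[SIGNAL_DESCRIPTORS]
  p_extra <- max(0, (config$positive_rate * config$pocket_mean - 1) /
                    (config$pocket_mean - 1))
  rows <- vector("list", config$n_proteins)
  truth <- vector("list", config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    res <- with_seed_local(protein_substream_seed(config$seed, i), {
      n <- sample(pmf$support, 1, prob = pmf$prob)
      labels <- integer(n)
      # primary positive: rank 1 with the enrichment probability
      primary <- if (is.na(config$top1_enrichment)) {
        sample.int(n, 1)
      } else if (n == 1 || stats::runif(1) < config$top1_enrichment) {
        1L
      } else {
        1L + sample.int(n - 1L, 1)
      }
      labels[primary] <- 1L
      extra <- which(stats::runif(n) < p_extra & labels == 0L)
      labels[extra] <- 1L
      # scores descending in rank; pocket index = rank (FPocket numbering)
      scores <- sort(stats::runif(n, 0, 60), decreasing = TRUE)
      desc <- matrix(stats::rnorm(n * length(schema)), nrow = n) *
        rep(prior$sd, each = n) + rep(prior$mean, each = n)
      colnames(desc) <- schema
      desc <- desc + outer(labels, shift)
      desc[, "score"] <- scores
      list(n = n, labels = labels, primary = primary, desc = desc)
    })
    pid <- sprintf("SYN%04d", i)
    tab <- data.frame(protein_id = pid, pocket_index = seq_len(res$n),
                      rank = seq_len(res$n), stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(res$desc))
    tab$label <- res$labels
    rows[[i]] <- tab
    truth[[i]] <- data.frame(
      protein_id = pid, n_pockets = res$n,
      primary_rank = res$primary, n_positive = sum(res$labels),
      positive_indices = paste(which(res$labels == 1L), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth),
       config = config)
}

#' Convert a feature table into labeled pocket sets
#'
#' Rebuilds per-protein `labeled_pocket_set`s (descriptors, ranks, labels;
#' no geometry) from a flat feature table, e.g. one produced by
#' [generate_feature_dataset()] or [read_feature_table()].
#'
#' @param tab A feature table with labels set.
#' @param scheme Labeling provenance string to record.
#' @return Named list of `labeled_pocket_set`s, one per protein.
#' @export
table_to_sets <- function(tab, scheme = "contact") {
  schema <- descriptor_schema()
  out <- lapply(split(tab, tab$protein_id), function(sub) {
    pockets <- lapply(seq_len(nrow(sub)), function(r) {
      rec <- new_pocket_record(
        protein_id = sub$protein_id[r],
        pocket_index = sub$pocket_index[r],
        descriptors = stats::setNames(as.numeric(sub[r, schema]), schema),
        label = as.integer(sub$label[r])
      )
      rec$rank <- as.integer(sub$rank[r])
      rec
    })
    new_labeled_set(sub$protein_id[1], pockets, scheme)
  })
  out[order(names(out))]
}

#' Generate a geometric toy protein with FPocket-style output
#'
#' Builds `n_pockets` spatially separated residue clusters along a line
#' (18 Angstrom spacing), places 5 alpha-sphere vertices at each cluster
#' center, and puts a 3-atom HETATM modulator (residue `LIG`) at the
#' center of the designated cluster — within 3.5 Angstrom of that
#' cluster's residues and more than 8 Angstrom from every other cluster.
#' Both labeling schemes therefore mark exactly the designated pocket
#' positive. Emits a PDB file and an FPocket-style `<id>_out` directory
#' (info file + per-pocket atom/vertex files).
#'
#' @param n_pockets Number of pocket clusters (>= 1).
#' @param modulator_pocket_index Designated positive pocket (1-based).
#' @param seed Integer seed (cluster jitter, descriptor values).
#' @param out_dir Directory to write into (created if needed).
#' @param id Protein identifier (file stem).
#' @return List with `pdb_path`, `fpocket_dir`, and `truth`
#'   (the designated pocket index and per-pocket residue assignments).
#' @export
generate_geometric_protein <- function(n_pockets, modulator_pocket_index,
                                       seed, out_dir,
                                       id = sprintf("GEO%03d", seed %% 1000)) {
  stopifnot(n_pockets >= 1,
            modulator_pocket_index >= 1,
            modulator_pocket_index <= n_pockets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spacing <- 18
  res_per_pocket <- 4L
  with_seed_local(seed, {
    atoms <- list()
    eleno <- 0L
    resno <- 0L
    pocket_residues <- vector("list", n_pockets)
    centers_by_pocket <- vector("list", n_pockets)
    for (p in seq_len(n_pockets)) {
      ctr <- c(spacing * (p - 1), 0, 0)
      res_ids <- integer(res_per_pocket)
      for (r in seq_len(res_per_pocket)) {
        resno <- resno + 1L
        res_ids[r] <- resno
        ang <- 2 * pi * (r - 1) / res_per_pocket
        base <- ctr + c(3 * cos(ang), 3 * sin(ang), 0)
        for (nm in c("CA", "CB")) {
          eleno <- eleno + 1L
          off <- if (nm == "CB") stats::runif(3, -0.4, 0.4) else c(0, 0, 0)
          atoms[[length(atoms) + 1L]] <- data.frame(
            record = "ATOM", eleno = eleno, elety = nm, resid = "ALA",
            chain = "A", resno = resno, insert = "",
            x = base[1] + off[1], y = base[2] + off[2], z = base[3] + off[3],
            elesy = "C", stringsAsFactors = FALSE
          )
        }
      }
      pocket_residues[[p]] <- res_ids
      jitter <- matrix(stats::runif(15, -0.8, 0.8), ncol = 3)
      centers_by_pocket[[p]] <- sweep(jitter, 2, ctr, "+")
    }
    # modulator: 3 heavy atoms hugging the designated cluster center
    mod_ctr <- c(spacing * (modulator_pocket_index - 1), 0, 0)
    for (k in 1:3) {
      eleno <- eleno + 1L
      off <- c(0.6 * (k - 2), 0.4 * (k %% 2), 0)
      atoms[[length(atoms) + 1L]] <- data.frame(
        record = "HETATM", eleno = eleno, elety = paste0("C", k),
        resid = "LIG", chain = "A", resno = 900L, insert = "",
        x = mod_ctr[1] + off[1], y = mod_ctr[2] + off[2], z = mod_ctr[3] + off[3],
        elesy = "C", stringsAsFactors = FALSE
      )
    }
    struct <- structure(
      list(id = id, chains = "A", atoms = do.call(rbind, atoms)),
      class = "protein_structure"
    )
    pdb_path <- file.path(out_dir, paste0(id, ".pdb"))
    write_structure(struct, pdb_path)
    fdir <- file.path(out_dir, paste0(id, "_out"))
    write_fpocket_fixture(fdir, id, struct, pocket_residues,
                          centers_by_pocket)
    list(
      pdb_path = pdb_path,
      fpocket_dir = fdir,
      truth = list(id = id, modulator_pocket_index = modulator_pocket_index,
                   pocket_residues = pocket_residues)
    )
  })
}

# FPocket display names for the info file (exercises the synonym map).
INFO_DISPLAY_NAMES <- c(
  score = "Score",
  druggability_score = "Druggability Score",
  number_of_alpha_spheres = "Number of Alpha Spheres",
  total_sasa = "Total SASA",
  polar_sasa = "Polar SASA",
  apolar_sasa = "Apolar SASA",
  volume = "Volume",
  mean_local_hydrophobic_density = "Mean local hydrophobic density",
  mean_alpha_sphere_radius = "Mean alpha sphere radius",
  mean_alpha_sphere_solvent_access = "Mean alp. sph. solvent access",
  apolar_alpha_sphere_proportion = "Apolar alpha sphere prop.",
  hydrophobicity_score = "Hydrophobicity score",
  volume_score = "Volume score",
  polarity_score = "Polarity score",
  charge_score = "Charge score",
  proportion_of_polar_atoms = "Proportion of polar atoms",
  alpha_sphere_density = "Alpha sphere density",
  cent_pock_max_dist = "Cent. of mass - Alpha Sphere max dist",
  flexibility = "Flexibility"
)

write_fpocket_fixture <- function(fdir, id, struct, pocket_residues,
                                  centers_by_pocket) {
  n <- length(pocket_residues)
  dir.create(file.path(fdir, "pockets"), recursive = TRUE,
             showWarnings = FALSE)
  prior <- descriptor_prior()
  schema <- descriptor_schema()
  scores <- sort(stats::runif(n, 0, 40), decreasing = TRUE)
  info <- character()
  for (p in seq_len(n)) {
    desc <- stats::rnorm(length(schema), prior$mean, prior$sd)
    names(desc) <- schema
    desc["score"] <- scores[p]
    info <- c(info, sprintf("Pocket %d :", p),
              sprintf("\t%s :\t%.4f", INFO_DISPLAY_NAMES[schema], desc),
              "")
    res <- struct$atoms[struct$atoms$record == "ATOM" &
                          struct$atoms$resno %in% pocket_residues[[p]], ,
                        drop = FALSE]
    atm <- struct
    atm$atoms <- res
    write_structure(atm, file.path(fdir, "pockets",
                                   sprintf("pocket%d_atm.pdb", p)))
    ctr <- centers_by_pocket[[p]]
    vert <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      "ATOM", seq_len(nrow(ctr)), "APOL", "STP", "C", p, " ",
      ctr[, 1], ctr[, 2], ctr[, 3], 0, 3.5
    )
    writeLines(c(vert, "TER", "END"),
               file.path(fdir, "pockets", sprintf("pocket%d_vert.pqr", p)))
  }
  writeLines(info, file.path(fdir, paste0(id, "_info.txt")))
  invisible(fdir)
}
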