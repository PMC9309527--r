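# Bagged, greedily weighted ensemble of tabular classifiers.
#
# Each base learner is trained with k-fold bagging: k models per learner,
# each fitted on k-1 folds, with out-of-fold (OOF) probabilities collected
# on the held-out fold. The final predictor is a weighted average of the
# bagged learners; weights come from greedy forward selection (with
# replacement) maximizing OOF F1 at the decision threshold. Because the
# first greedy pick is the single best learner and later additions are
# kept only when they improve, the ensemble's OOF F1 never falls below the
# best single learner's.

#' Ensemble configuration
#'
#' @param portfolio Character vector of base-learner names; see
#'   [learner_portfolio()] for the available set.
#' @param k_folds Bagging folds (>= 2; capped at the minority-class count).
#' @param threshold Decision threshold on the predicted probability; a
#'   pocket is called allosteric iff probability > threshold (strict).
#' @param seed Integer seed controlling fold assignment and every
#'   learner's internal randomness.
#' @param max_greedy_iter Greedy-selection iteration cap.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(portfolio = names(learner_portfolio()),
                            k_folds = 5L, threshold = 0.5, seed = 1L,
                            max_greedy_iter = 25L) {
  stopifnot(length(portfolio) >= 1, k_folds >= 2,
            threshold > 0, threshold < 1)
  unknown <- setdiff(portfolio, names(learner_portfolio()))
  if (length(unknown) > 0) {
    stop("Unknown learners: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(portfolio = portfolio, k_folds = as.integer(k_folds),
         threshold = threshold, seed = as.integer(seed),
         max_greedy_iter = as.integer(max_greedy_iter)),
    class = "ensemble_config"
  )
}

#' Available base learners
#'
#' Gradient-boosted trees (xgboost), random forest and extremely
#' randomized trees (ranger), elastic-net logistic regression (glmnet),
#' k-nearest neighbours, and a shallow feed-forward network (nnet). Each
#' entry provides `fit(x, y, seed)` and `predict(fit, x)` returning
#' probabilities of the positive class.
#'
#' @return Named list of learner definitions.
#' @export
learner_portfolio <- function() {
  list(
    gbm = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        dm <- xgboost::xgb.DMatrix(x, label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 4,
                        eta = 0.1, subsample = 0.9, nthread = 1,
                        seed = seed),
          dm, nrounds = 80, verbose = 0
        )
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x)))
      }
    ),
    rf = list(
      fit = function(x, y, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 300,
                       seed = seed, num.threads = 1)
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, data = x,
                                  num.threads = 1)$predictions[, "1"])
      }
    ),
    extra_trees = list(
      fit = function(x, y, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 300,
                       splitrule = "extratrees", num.random.splits = 1,
                       seed = seed, num.threads = 1)
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, data = x,
                                  num.threads = 1)$predictions[, "1"])
      }
    ),
    glmnet = list(
      fit = function(x, y, seed) {
        foldid <- with_seed_local(seed, sample(rep_len(1:5, length(y))))
        # small inner folds routinely trip glmnet's low-count warning
        suppressWarnings(
          glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            alpha = 0.5)
        )
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, x, s = "lambda.min",
                                  type = "response"))
      }
    ),
    knn = list(
      fit = function(x, y, seed) {
        ctr <- colMeans(x)
        scl <- pmax(apply(x, 2, stats::sd), 1e-8)
        list(x = scale(x, ctr, scl), y = factor(y, levels = c(0, 1)),
             center = ctr, scale = scl, k = min(7L, nrow(x) - 1L),
             seed = seed)
      },
      predict = function(fit, x) {
        xs <- scale(x, fit$center, fit$scale)
        pred <- with_seed_local(fit$seed,
          class::knn(fit$x, xs, cl = fit$y, k = fit$k, prob = TRUE))
        pr <- attr(pred, "prob")
        as.numeric(ifelse(pred == "1", pr, 1 - pr))
      }
    ),
    mlp = list(
      fit = function(x, y, seed) {
        ctr <- colMeans(x)
        scl <- pmax(apply(x, 2, stats::sd), 1e-8)
        net <- with_seed_local(seed,
          nnet::nnet(x = scale(x, ctr, scl), y = y, size = 8,
                     decay = 0.01, maxit = 300, entropy = TRUE,
                     trace = FALSE, MaxNWts = 2000))
        list(net = net, center = ctr, scale = scl)
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit$net, scale(x, fit$center, fit$scale)))
      }
    )
  )
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin, so every fold sees both classes whenever k <= minority count.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed_local(seed, {
    for (cls in unique(y)) {
      ix <- which(y == cls)
      folds[ix] <- rep_len(seq_len(k), length(ix))[sample.int(length(ix))]
    }
  })
  folds
}

#' Train the bagged weighted ensemble
#'
#' @param x Numeric feature matrix (columns must match
#'   [descriptor_schema()], or at least be consistent with later
#'   prediction calls); NAs are imputed with per-column training medians,
#'   which are persisted in the model.
#' @param y Integer 0/1 label vector.
#' @param config An [ensemble_config()].
#' @return A `trained_ensemble`: fold models per learner, ensemble
#'   `weights` (non-negative, summing to 1), `oof` probabilities, OOF F1,
#'   persisted `medians` and `schema`, `folds`, and the `config`.
#' @export
train_ensemble <- function(x, y, config = ensemble_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) {
    stop("Training labels contain a single class", call. = FALSE)
  }
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- impute_columns(x, medians)
  k <- min(config$k_folds, min(table(y)))
  if (k < 2) {
    stop("Need at least 2 examples of each class for bagging", call. = FALSE)
  }
  folds <- stratified_folds(y, k, config$seed)
  portfolio <- learner_portfolio()[config$portfolio]
  learners <- list()
  oof <- matrix(NA_real_, nrow = length(y), ncol = 0)
  for (name in names(portfolio)) {
    lr <- portfolio[[name]]
    fold_models <- vector("list", k)
    col <- rep(NA_real_, length(y))
    ok <- TRUE
    for (f in seq_len(k)) {
      hold <- folds == f
      fit <- tryCatch(
        lr$fit(x[!hold, , drop = FALSE], y[!hold],
               seed = config$seed * 1000L + f),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        warning("Learner '", name, "' failed (", conditionMessage(fit),
                "); dropped from the portfolio", call. = FALSE)
        ok <- FALSE
        break
      }
      fold_models[[f]] <- fit
      col[hold] <- lr$predict(fit, x[hold, , drop = FALSE])
    }
    if (!ok) next
    learners[[name]] <- fold_models
    oof <- cbind(oof, col)
    colnames(oof)[ncol(oof)] <- name
  }
  if (length(learners) == 0) {
    stop("Every learner in the portfolio failed", call. = FALSE)
  }
  sel <- greedy_select(oof, y, config$threshold, config$max_greedy_iter)
  structure(
    list(
      learners = learners,
      weights = sel$weights,
      oof = oof,
      oof_prob = sel$prob,
      oof_f1 = sel$f1,
      folds = folds,
      medians = medians,
      schema = colnames(x),
      config = config,
      version = ENSEMBLE_BUNDLE_VERSION
    ),
    class = "trained_ensemble"
  )
}

ENSEMBLE_BUNDLE_VERSION <- "1"

impute_columns <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  if (any(!is.finite(x))) {
    stop("Non-finite feature values remain after imputation", call. = FALSE)
  }
  x
}

# Greedy forward selection with replacement (Caruana-style): repeatedly add
# the learner whose inclusion in the running average maximizes OOF F1 at the
# threshold; stop when no addition improves. Weights = selection counts.
greedy_select <- function(oof, y, threshold, max_iter) {
  f1_of <- function(prob) {
    metrics(confusion(y, classify(prob, threshold)))$f1
  }
  single <- apply(oof, 2, f1_of)
  counts <- stats::setNames(rep(0L, ncol(oof)), colnames(oof))
  best_name <- colnames(oof)[which.max(single)]
  counts[best_name] <- 1L
  run_sum <- oof[, best_name]
  best_f1 <- f1_of(run_sum)
  n_sel <- 1L
  while (n_sel < max_iter) {
    cand_f1 <- apply(oof, 2, function(col) f1_of((run_sum + col) / (n_sel + 1)))
    j <- which.max(cand_f1)
    if (cand_f1[j] <= best_f1 + 1e-12) break
    run_sum <- run_sum + oof[, j]
    counts[j] <- counts[j] + 1L
    n_sel <- n_sel + 1L
    best_f1 <- cand_f1[j]
  }
  weights <- counts / sum(counts)
  list(weights = weights, prob = run_sum / n_sel, f1 = best_f1)
}

#' Predict allosteric probabilities
#'
#' Each base learner's probability is the mean over its k fold models
#' (bagging); the ensemble output is the weighted average over learners.
#' Deterministic given the model.
#'
#' @param model A `trained_ensemble`.
#' @param x Feature matrix or data.frame; columns must cover the model's
#'   schema (extra columns are dropped, a missing column is an error).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "trained_ensemble"))
  x <- as.matrix(as.data.frame(x)[, , drop = FALSE])
  missing <- setdiff(model$schema, colnames(x))
  if (length(missing) > 0) {
    stop("Feature schema mismatch; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$schema, drop = FALSE]
  storage.mode(x) <- "double"
  x <- impute_columns(x, model$medians)
  portfolio <- learner_portfolio()
  prob <- rep(0, nrow(x))
  for (name in names(model$learners)) {
    w <- model$weights[[name]]
    if (w == 0) next
    preds <- vapply(model$learners[[name]], function(fit)
      portfolio[[name]]$predict(fit, x), numeric(nrow(x)))
    preds <- if (nrow(x) == 1) matrix(preds, nrow = 1) else preds
    prob <- prob + w * rowMeans(preds)
  }
  pmin(pmax(prob, 0), 1)
}

#' Threshold probabilities into 0/1 calls
#'
#' A pocket is called allosteric iff its probability is strictly above the
#' threshold; a probability exactly equal to the threshold is negative.
#'
#' @param prob Numeric probabilities in [0, 1].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 vector.
#' @export
classify <- function(prob, threshold = 0.5) {
  stopifnot(all(prob >= 0 & prob <= 1))
  as.integer(prob > threshold)
}

#' Save / load a trained ensemble bundle
#'
#' The bundle (single RDS archive) carries the fold models, ensemble
#' weights, feature schema, imputation medians, config, and a content
#' hash; `load_model` verifies both the bundle version and the hash, so a
#' corrupted or incompatible file fails loudly. Round trips preserve
#' predictions bit-for-bit.
#'
#' @param model A `trained_ensemble`.
#' @param path Bundle path.
#' @return `path` invisibly (save); the `trained_ensemble` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_ensemble"))
  model$hash <- model_hash(model)
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("Cannot read model bundle ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(model, "trained_ensemble")) {
    stop("File ", path, " is not a trained_ensemble bundle", call. = FALSE)
  }
  if (!identical(model$version, ENSEMBLE_BUNDLE_VERSION)) {
    stop("Bundle version ", model$version, " does not match supported ",
         "version ", ENSEMBLE_BUNDLE_VERSION, call. = FALSE)
  }
  stored <- model$hash
  model$hash <- NULL
  if (!identical(stored, model_hash(model))) {
    stop("Bundle hash mismatch; file is corrupted", call. = FALSE)
  }
  model$hash <- stored
  model
}

# md5 over the model's deterministic numeric content (weights, schema,
# medians, folds, OOF probabilities, config). Fitted learner internals are
# excluded: some backends do not re-serialize byte-identically, and readRDS
# already detects file corruption.
model_hash <- function(model) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(
    list(weights = model$weights, schema = model$schema,
         medians = model$medians, folds = model$folds, oof = model$oof,
         oof_f1 = model$oof_f1, config = unclass(model$config),
         version = model$version),
    tmp, version = 3
  )
  unname(tools::md5sum(tmp))
}
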