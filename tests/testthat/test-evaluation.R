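test_that("confusion matrices tally the four cells", {
  cm <- confusion(c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), c(tp = 1, fp = 1, fn = 1, tn = 1))
  ident <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(ident$fp + ident$fn, 0)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  set.seed(1)
  truth <- rbinom(1000, 1, 0.3); pred <- rbinom(1000, 1, 0.5)
  cm <- confusion(truth, pred)
  tally <- c(0, 0, 0, 0) # brute-force four-way tally
  for (i in 1:1000) {
    if (truth[i] == 1 && pred[i] == 1) tally[1] <- tally[1] + 1
    if (truth[i] == 0 && pred[i] == 1) tally[2] <- tally[2] + 1
    if (truth[i] == 1 && pred[i] == 0) tally[3] <- tally[3] + 1
    if (truth[i] == 0 && pred[i] == 0) tally[4] <- tally[4] + 1
  }
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")], use.names = FALSE), tally)
})

test_that("metrics handle symmetric and degenerate confusion matrices", {
  m <- metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")],
                      use.names = FALSE), rep(0.5, 4))
  z <- metrics(confusion_counts(0, 0, 5, 5))
  expect_equal(z$precision, 0)
  expect_equal(z$recall, 0)
  expect_equal(z$f1, 0)
  expect_equal(z$accuracy, 0.5)
  expect_true("precision" %in% z$degenerate)
})

test_that("F1 is the harmonic mean and lies between precision and recall", {
  set.seed(2)
  for (i in 1:20) {
    cm <- confusion_counts(sample(1:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(1:200, 1))
    m <- metrics(cm)
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("ranking power counts proteins whose positive is in the top k", {
  # single protein, positive pocket has the highest probability
  r1 <- ranking_power(list(list(prob = c(0.9, 0.2), truth = c(1L, 0L))))
  expect_equal(unname(r1$topk), c(1, 1, 1))
  # positives at sorted positions 1 and 3
  r2 <- ranking_power(list(
    list(prob = c(0.9, 0.2, 0.1), truth = c(1L, 0L, 0L)),
    list(prob = c(0.1, 0.5, 0.9), truth = c(1L, 0L, 0L))
  ))
  expect_equal(unname(r2$topk), c(0.5, 0.5, 1))
  # monotone in k, histogram sums to the denominator
  expect_true(all(diff(r2$topk) >= 0))
  expect_equal(sum(r2$rank_histogram), r2$n_proteins)
})

test_that("probability ties in ranking break by FPocket rank", {
  pr <- list(prob = c(0.5, 0.5), truth = c(0L, 1L), rank = c(2L, 1L))
  expect_equal(unname(ranking_power(list(pr))$topk[1]), 1)
  pr2 <- list(prob = c(0.5, 0.5), truth = c(0L, 1L), rank = c(1L, 2L))
  expect_equal(unname(ranking_power(list(pr2))$topk[1]), 0)
})

test_that("proteins without a positive pocket leave the denominator", {
  profiles <- list(
    list(prob = c(0.9, 0.1), truth = c(1L, 0L)),
    list(prob = c(0.9, 0.1), truth = c(0L, 0L))
  )
  r <- ranking_power(profiles)
  expect_equal(r$n_proteins, 1)
  expect_equal(r$n_excluded, 1)
})

test_that("ranking power equals exhaustive recomputation on random profiles", {
  set.seed(3)
  profiles <- lapply(1:50, function(i) {
    n <- sample(4:30, 1)
    truth <- integer(n); truth[sample.int(n, sample(1:2, 1))] <- 1L
    list(prob = runif(n), truth = truth, rank = sample.int(n))
  })
  r <- ranking_power(profiles, ks = 1:3)
  for (k in 1:3) {
    hits <- 0
    for (pr in profiles) {
      ord <- order(-pr$prob, pr$rank)
      if (any(which(pr$truth[ord] == 1L) <= k)) hits <- hits + 1
    }
    expect_equal(unname(r$topk[k]), hits / length(profiles))
  }
})

test_that("multi-run aggregation uses sample mean and n-1 standard deviation", {
  one <- metrics(confusion_counts(10, 5, 5, 80))
  agg <- aggregate_runs(rep(list(one), 10))
  expect_equal(unname(agg$sd), rep(0, 4))
  two <- list(metrics(confusion_counts(6, 4, 4, 0)),   # f1 = 0.6
              metrics(confusion_counts(8, 2, 2, 0)))   # f1 = 0.8
  agg2 <- aggregate_runs(two)
  expect_equal(unname(agg2$mean["f1"]), 0.7)
  expect_equal(unname(agg2$sd["f1"]), 0.14142136, tolerance = 1e-6)
  # independent summation oracle
  set.seed(4)
  reports <- lapply(1:10, function(i)
    metrics(confusion_counts(sample(1:20, 1), sample(0:20, 1),
                             sample(0:20, 1), sample(1:100, 1))))
  agg3 <- aggregate_runs(reports)
  f1s <- vapply(reports, function(r) r$f1, 0)
  expect_equal(unname(agg3$mean["f1"]), sum(f1s) / 10)
  expect_equal(unname(agg3$sd["f1"]),
               sqrt(sum((f1s - mean(f1s))^2) / 9))
  expect_error(aggregate_runs(list()), "at least one")
})
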