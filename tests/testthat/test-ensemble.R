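# hand-built member whose vote equals feature `slot` of the input: the
# positive unit sees sigmoid(2*x[slot] - 1), the negative unit sigmoid(0)
vote_member <- function(slot, n_features = 5L) {
  W1 <- matrix(0, n_features, 1)
  W1[slot, 1] <- 1
  structure(list(W1 = W1, b1 = 0,
                 W2 = matrix(c(2, 0), 1, 2), b2 = c(-1, 0)),
            class = "glyco_params")
}

vote_ensemble <- function(n_members = 5L, n_features = 5L) {
  structure(list(members = lapply(seq_len(n_members), vote_member,
                                  n_features = n_features),
                 traces = NULL, hyper = nn_hyperparams(),
                 n_features = n_features, vocab_hash = "fixture"),
            class = "glyco_ensemble")
}

test_that("vote aggregation reproduces the closed-form binomial intervals", {
  ens <- vote_ensemble()
  x <- rbind(c(1, 1, 1, 1, 1),
             c(1, 1, 1, 0, 0),
             c(1, 1, 1, 1, 0),
             c(0, 0, 0, 0, 0))
  agg <- predict(ens, x)
  expect_equal(agg$p_hat, c(1.0, 0.6, 0.8, 0.0))
  expect_equal(agg$width[1], 0)
  expect_equal(agg$width[4], 0)
  expect_equal(agg$width[2], 2 * 1.96 * sqrt(0.6 * 0.4 / 5), tolerance = 1e-12)
  expect_equal(agg$width[2], 0.8589, tolerance = 1e-4)
  # p_hat = 0.8: displayed upper limit truncates at 1, but the decision
  # width is the distance between the untruncated limits
  half3 <- 1.96 * sqrt(0.8 * 0.2 / 5)
  expect_equal(agg$ci_high[3], 1.0)
  expect_equal(agg$ci_low[3], 0.8 - half3, tolerance = 1e-12)
  expect_equal(agg$width[3], 2 * half3, tolerance = 1e-12)
  expect_equal(agg$width[3], 0.7013, tolerance = 1e-4)
  # interval always brackets p_hat inside [0, 1]
  expect_true(all(agg$ci_low <= agg$p_hat & agg$p_hat <= agg$ci_high))
})

test_that("prediction is invariant to ensemble member order", {
  ens <- vote_ensemble()
  x <- rbind(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 0))
  agg1 <- predict(ens, x)
  ens2 <- ens
  ens2$members <- rev(ens2$members)
  agg2 <- predict(ens2, x)
  expect_equal(agg1$p_hat, agg2$p_hat)
  expect_equal(agg1$width, agg2$width)
})

test_that("decide applies the rounding rule, ambiguity override and outcome rule", {
  ens <- vote_ensemble()
  x <- rbind(c(1, 1, 1, 1, 1),  # unanimous positive
             c(1, 1, 1, 0, 0),  # 3/5 -> wide interval
             c(0, 0, 0, 0, 0))  # unanimous negative
  agg <- predict(ens, x)
  d0 <- decide(agg)
  expect_equal(d0$call, c("positive", "ambiguous", "negative"))
  # the call is ambiguous whatever the truth
  expect_equal(decide(agg, truth = c("positive", "positive", "positive"))$call[2],
               "ambiguous")
  expect_equal(decide(agg, truth = c("negative", "negative", "negative"))$call[2],
               "ambiguous")
  # outcomes: correct rounding wins even under a wide interval; a unanimous
  # wrong vote is wrong; a wrongly-rounded wide interval is rescued as ambiguous
  d1 <- decide(agg, truth = c("positive", "positive", "positive"))
  expect_equal(d1$outcome, c("correct", "correct", "wrong"))
  d2 <- decide(agg, truth = c("negative", "negative", "negative"))
  expect_equal(d2$outcome, c("wrong", "ambiguous", "correct"))
  # exact p_hat = 0.5 rounds to negative (conservative); width > 0.5 -> ambiguous call
  agg5 <- predict(vote_ensemble(4, 5), rbind(c(1, 1, 0, 0, 0)))
  expect_equal(agg5$p_hat, 0.5)
  expect_equal(decide(agg5, truth = "negative")$outcome, "correct")
})

test_that("evaluation metrics count correct, ambiguous and decisive calls", {
  ens <- vote_ensemble()
  # 6 correct (unanimous, matching), 2 wrong (unanimous, mismatched),
  # 2 ambiguous (2/5 votes, truth positive: wrong rounding, wide interval)
  x <- rbind(matrix(1, 3, 5), matrix(0, 3, 5),
             matrix(0, 2, 5),
             matrix(c(1, 1, 0, 0, 0), 2, 5, byrow = TRUE))
  truth <- c(rep("positive", 3), rep("negative", 3),
             rep("positive", 2), rep("positive", 2))
  m <- evaluate_ensemble(ens, x, truth)
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$accuracy_with_ambiguous, 0.8)
  expect_equal(m$ambiguous_fraction, 0.2)
  # decisive calls: 3 TP, 0 FP, 2 FN -> precision 1, recall 3/5
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 0.6)

  # all-correct evaluation
  m2 <- evaluate_ensemble(ens, rbind(matrix(1, 2, 5), matrix(0, 2, 5)),
                          c("positive", "positive", "negative", "negative"))
  expect_equal(unlist(m2[c("accuracy", "accuracy_with_ambiguous",
                           "precision", "recall")]),
               c(accuracy = 1, accuracy_with_ambiguous = 1,
                 precision = 1, recall = 1))
  # no decisive positive calls: precision is absent, not zero
  m3 <- evaluate_ensemble(ens, matrix(0, 2, 5), c("negative", "negative"))
  expect_true(is.na(m3$precision))
})

test_that("accuracy_with_ambiguous never falls below accuracy", {
  ens <- vote_ensemble()
  set.seed(31)
  for (i in 1:20) {
    x <- matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), 8, 5)
    truth <- sample(c("positive", "negative"), 8, replace = TRUE)
    m <- evaluate_ensemble(ens, x, truth)
    expect_gte(m$accuracy_with_ambiguous, m$accuracy)
  }
})

test_that("the binomial interval attains nominal coverage in the normal regime", {
  set.seed(52)
  n_voters <- 100L
  for (p in seq(0.2, 0.8, by = 0.1)) {
    draws <- rbinom(1e4, n_voters, p) / n_voters
    half <- 1.96 * sqrt(draws * (1 - draws) / n_voters)
    covered <- (pmax(draws - half, 0) <= p) & (p <= pmin(draws + half, 1))
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
  }
})

test_that("trained ensembles have the requested size and reproducible votes", {
  set.seed(8)
  n <- 60
  x <- matrix(rbinom(n * 10, 1, 0.5), n, 10)
  y_pos <- x[, 3] == 1
  y <- cbind(as.integer(y_pos), as.integer(!y_pos))
  h <- nn_hyperparams(n_cycles = 1, c = 60, hidden_units = 6, seed = NULL)
  ens <- train_ensemble(x, y, x, y, h, n_models = 5, seed = 19)
  expect_length(ens$members, 5L)
  # single-member ensemble: zero-width intervals everywhere
  ens1 <- train_ensemble(x, y, x, y, h, n_models = 1, seed = 19)
  agg1 <- predict(ens1, x)
  expect_true(all(agg1$width == 0))
  expect_true(all(agg1$p_hat %in% c(0, 1)))
  # different seeds -> different member parameters
  ensb <- train_ensemble(x, y, x, y, h, n_models = 2, seed = 20)
  expect_false(identical(ens$members[[1]]$W1, ensb$members[[1]]$W1))
  # same seed -> identical ensembles
  ensc <- train_ensemble(x, y, x, y, h, n_models = 5, seed = 19)
  expect_identical(ens$members, ensc$members)
})

test_that("a vocabulary hash mismatch is a hard error", {
  ens <- vote_ensemble()
  x <- matrix(1, 1, 5)
  attr(x, "vocab_hash") <- "other"
  expect_error(predict(ens, x), "hash mismatch")
  expect_error(predict(ens, matrix(1, 1, 4)), "dimension mismatch")
})

test_that("ensembles round-trip through the JSON container", {
  set.seed(3)
  x <- matrix(rbinom(80, 1, 0.5), 20, 4)
  y <- encode_labels(sample(c("positive", "negative"), 20, replace = TRUE))
  h <- nn_hyperparams(n_cycles = 1, c = 20, hidden_units = 3)
  ens <- train_ensemble(x, y, x, y, h, n_models = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(length(back$members), 2L)
  for (m in 1:2) {
    expect_equal(back$members[[m]]$W1, ens$members[[m]]$W1, tolerance = 1e-12)
    expect_equal(back$members[[m]]$b2, ens$members[[m]]$b2, tolerance = 1e-12)
  }
  expect_equal(predict(back, x)$p_hat, predict(ens, x)$p_hat)
})
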