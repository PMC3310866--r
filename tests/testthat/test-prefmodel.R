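# Logistic fits, the leave-one-out protocol, threshold optimization,
# confusion metrics, rankings and the random baseline.

test_that("logistic fit handles degenerate and separable data deterministically", {
  # all-zero features, balanced labels: null model, pW = 0.5
  f <- fit_logistic(matrix(0, 10, 3), rep(c(0, 1), 5))
  expect_equal(unname(f$coef), rep(0, 4), tolerance = 1e-6)
  expect_equal(unname(predict_logistic(f, matrix(0, 1, 3))), 0.5,
               tolerance = 1e-6)
  # linearly separable toy set reaches training accuracy 1
  set.seed(3)
  X <- cbind(c(rnorm(10, -3), rnorm(10, 3)), rnorm(20), rnorm(20))
  y <- rep(c(0, 1), each = 10)
  fs <- fit_logistic(X, y)
  pw <- predict_logistic(fs, X)
  th <- optimize_thresholds(cbind(A = pw), cbind(A = y))
  pred <- (pw >= th$t[["A"]]) * 1
  expect_equal(pred, y, ignore_attr = TRUE)
  # identical labels fall back to intercept-only
  fi <- fit_logistic(matrix(rnorm(12), 4, 3), rep(1, 4))
  expect_true(fi$intercept_only)
  expect_true(all(predict_logistic(fi, matrix(0, 2, 3)) > 0.5))
  expect_error(fit_logistic(matrix(c(1, NA, 1, 1, 1, 1), 2, 3), c(0, 1)),
               "non-finite")
})

test_that("ridge logistic agrees with glm on well-conditioned data", {
  set.seed(14)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, plogis(0.3 + X %*% c(1, -0.7, 0.2)))
  ours <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-4)
})

test_that("simulated fits recover the generating weight signs", {
  set.seed(77)
  gen <- c(1.5, -1.2, 0.8)
  signs <- replicate(200, {
    X <- matrix(rnorm(23 * 3), 23, 3)
    y <- rbinom(23, 1, plogis(X %*% gen))
    if (length(unique(y)) < 2) return(c(NA, NA, NA))
    sign(fit_logistic(X, y)$coef[-1])
  })
  med <- apply(signs, 1, median, na.rm = TRUE)
  expect_equal(unname(med), sign(gen))
})

test_that("the LOO protocol is order-invariant and leak-free", {
  pt <- make_planted_model_tables(seed = 61, n_positions = 8, noise_sd = 0.5)
  loo <- loo_train_predict(pt$score_table, pt$preference_table)
  # permuting row order of the input tables leaves predictions unchanged
  idx <- sample(nrow(pt$score_table))
  loo2 <- loo_train_predict(pt$score_table[idx, ], pt$preference_table[idx, ])
  expect_equal(loo2$pW, loo$pW)
  # perturbing the held-out position's label does not change its own
  # prediction (that row is excluded from its training fold)
  pert <- pt$preference_table
  j <- which(pert$position == "pos03" & pert$aa == "L")
  pert$deltaW[j] <- 1 - pert$deltaW[j]
  loo3 <- loo_train_predict(pt$score_table, pert)
  expect_equal(loo3$pW["pos03", "L"], loo$pW["pos03", "L"])
  # two positions: degenerate but defined
  two <- pt$score_table$position %in% c("pos01", "pos02")
  loo4 <- loo_train_predict(pt$score_table[two, ],
                            pt$preference_table[two, ])
  expect_equal(dim(loo4$pW), c(2L, 20L))
  expect_true(all(is.finite(loo4$pW)))
})

test_that("threshold optimization is globally optimal over its candidate grid", {
  set.seed(19)
  pW <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("A", "C", "D")))
  dW <- matrix(rbinom(60, 1, 0.4), 20, 3, dimnames = list(NULL, c("A", "C", "D")))
  th <- optimize_thresholds(pW, dW)
  for (t in colnames(pW)) {
    u <- sort(unique(pW[, t]))
    cand <- sort(unique(c(0, 1, (u[-1] + u[-length(u)]) / 2)))
    mccs <- vapply(cand, function(tc) {
      pred <- (pW[, t] >= tc) * 1
      cdrpref::confusion_metrics(sum(pred & dW[, t]), sum(pred & !dW[, t]),
                                 sum(!pred & !dW[, t]),
                                 sum(!pred & dW[, t]))$mcc
    }, numeric(1))
    expect_equal(th$mcc[[t]], max(mccs))
    # ties broken toward the larger threshold
    expect_equal(th$t[[t]], max(cand[mccs == max(mccs)]))
  }
  # perfectly separated activations give per-type MCC 1
  sep <- optimize_thresholds(cbind(A = c(0.9, 0.8, 0.2, 0.1)),
                             cbind(A = c(1, 1, 0, 0)))
  expect_equal(sep$mcc[["A"]], 1)
  # all-positive labels: declared degenerate fallback
  deg <- optimize_thresholds(cbind(A = runif(4)), cbind(A = rep(1, 4)))
  expect_true(deg$degenerate[["A"]])
  expect_equal(deg$t[["A"]], 0.5)
})

test_that("binary thresholding treats the boundary as positive", {
  pW <- matrix(c(0.5, 0.2, 0.8, 0), 2, 2, dimnames = list(NULL, c("A", "C")))
  t <- c(A = 0.5, C = 0.8)
  d <- predict_binary(pW, t)
  expect_equal(unname(d[, "A"]), c(1L, 0L))
  expect_equal(unname(d[, "C"]), c(1L, 0L))
  # pW = 0 is negative for any positive threshold
  expect_equal(unname(predict_binary(matrix(0, 1, 1,
                                            dimnames = list(NULL, "A")),
                                     c(A = 0.01))[1, 1]), 0L)
  # elementwise comparison oracle on random matrices
  set.seed(4)
  pWr <- matrix(runif(100), 10, 10, dimnames = list(NULL, AA20[1:10]))
  tr <- setNames(runif(10), AA20[1:10])
  got <- predict_binary(pWr, tr)
  oracle <- matrix(0L, 10, 10, dimnames = dimnames(pWr))
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- as.integer(pWr[i, j] >= tr[[colnames(pWr)[j]]])
  expect_equal(got, oracle)
})

test_that("evaluation metrics match confusion arithmetic and MCC conventions", {
  # perfect prediction
  ev <- evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ev$mcc, 1)
  expect_equal(ev$accuracy, 1)
  # balanced wrongness
  ev2 <- confusion_metrics(5, 5, 5, 5)
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(ev2$mcc, 0)
  # MCC denominator 0 -> 0
  expect_equal(confusion_metrics(3, 0, 0, 2)$mcc, 0)
  expect_equal(confusion_metrics(0, 0, 4, 0)$mcc, 0)
  # brute-force counting oracle
  set.seed(5)
  pred <- matrix(rbinom(60, 1, 0.5), 6, 10)
  obs <- matrix(rbinom(60, 1, 0.5), 6, 10)
  ev3 <- evaluate_predictions(pred, obs)
  tp <- sum(pred == 1 & obs == 1); fp <- sum(pred == 1 & obs == 0)
  tn <- sum(pred == 0 & obs == 0); fn <- sum(pred == 0 & obs == 1)
  expect_equal(c(ev3$TP, ev3$FP, ev3$TN, ev3$FN), c(tp, fp, tn, fn))
  expect_equal(ev3$mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  # label-swap antisymmetry when classes balance
  predb <- c(rep(1, 6), rep(0, 6))
  obsb <- c(1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  expect_equal(evaluate_predictions(1 - predb, obsb)$mcc,
               -evaluate_predictions(predb, obsb)$mcc)
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
})

test_that("the closed-form random baseline matches Monte Carlo", {
  rb <- random_baseline(24, 20, 5.7, 5.7)
  expect_equal(rb$recall, rb$precision)
  expect_equal(random_baseline(10, 20, 4, 20)$recall, 1)
  expect_error(random_baseline(24, 20, 5, 25), "must lie")
  # Monte-Carlo cross-check: m true positives, k random predicted
  set.seed(71)
  nrep <- 2000L
  m <- 6L; k <- 6L; n <- 20L
  acc <- prec <- rec <- spec <- numeric(nrep)
  for (r in seq_len(nrep)) {
    truth <- sample(c(rep(1, m), rep(0, n - m)))
    pred <- sample(c(rep(1, k), rep(0, n - k)))
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    acc[r] <- (tp + tn) / n; prec[r] <- tp / k; rec[r] <- tp / m
    spec[r] <- tn / (n - m)
  }
  cf <- random_baseline(1, n, m, k)
  for (pair in list(c(mean(acc), cf$accuracy), c(mean(prec), cf$precision),
                    c(mean(rec), cf$recall), c(mean(spec), cf$specificity))) {
    expect_lt(abs(pair[1] - pair[2]), 3 * sd(acc) / sqrt(nrep) + 0.02)
  }
})

test_that("rankings are permutations with the native-residue conventions", {
  set.seed(81)
  act <- matrix(rnorm(40), 2, 20, dimnames = list(c("p1", "p2"), AA20))
  rk <- rank_amino_acids(act)
  expect_equal(sort(rk[1, ]), 1:20, ignore_attr = TRUE)
  expect_equal(sort(rk[2, ]), 1:20, ignore_attr = TRUE)
  # sorting oracle
  expect_equal(unname(rk[1, order(-act[1, ])]), 1:20)
  # the maximum activation has rank 1
  best <- colnames(act)[which.max(act[1, ])]
  expect_equal(unname(rank_of_native(rk, c(p1 = best))), 1L)
  # distribution table normalizes to 100 per class
  ranks <- setNames(c(1L, 1L, 3L, 20L), paste0("q", 1:4))
  classes <- setNames(c("core", "core", "rim", "rim"), paste0("q", 1:4))
  rd <- ranking_distribution(ranks, classes)
  expect_equal(sum(rd$core), 100)
  expect_equal(sum(rd$rim), 100)
  expect_equal(rd$random, rep(5, 20))
  expect_equal(rd$core[1], 100)
  # uniform random ranks approach the flat 5% line
  set.seed(82)
  rr <- setNames(sample(1:20, 4000, replace = TRUE), paste0("r", 1:4000))
  cc <- setNames(rep("core", 4000), names(rr))
  rdu <- ranking_distribution(rr, cc)
  expect_true(all(abs(rdu$core - 5) < 1.5))
})

test_that("position reports sort by W and by activation margin with tie rules", {
  pW <- matrix(c(0.9, 0.9, 0.2, 0.6), 1, 4,
               dimnames = list("p1", c("D", "A", "C", "E")))
  dW <- matrix(c(1, 0, 0, 1), 1, 4, dimnames = dimnames(pW))
  W <- matrix(c(2.0, -1.0, -0.5, 1.0), 1, 4, dimnames = dimnames(pW))
  t <- c(A = 0.5, C = 0.5, D = 0.5, E = 0.5)
  rep1 <- report_position(pW, dW, W, t, "p1")
  expect_equal(rep1$experimental$aa, c("D", "E"))
  # ties in margin broken alphabetically: A and D both at margin 0.4
  expect_equal(rep1$predicted$aa, c("A", "D", "E"))
  expect_equal(rep1$predicted$true_positive, c(FALSE, TRUE, TRUE))
  # no predicted positives -> empty right-hand column
  rep2 <- report_position(pW, dW, W, c(A = 1, C = 1, D = 1, E = 1), "p1")
  expect_equal(nrow(rep2$predicted), 0)
})

test_that("noise degrades the planted-model MCC monotonically in expectation", {
  mccs <- vapply(c(0, 1.5, 4), function(ns) {
    vals <- vapply(1:3, function(s) {
      pt <- make_planted_model_tables(seed = 90 + s, n_positions = 16,
                                      noise_sd = ns)
      fit_preference_model(pt$score_table, pt$preference_table)$evaluation$mcc
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mccs) < 0))
})
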