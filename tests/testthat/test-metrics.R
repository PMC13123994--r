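test_that("binary cross-entropy has its closed-form values", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  expect_equal(bce_loss(rep(0.5, 10), rbinom(10, 1, 0.5)), log(2),
               tolerance = 1e-12)
  set.seed(1)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(bce_loss(p, y), oracle_bce(p, y), tolerance = 1e-9)
})

test_that("confusion metrics reproduce published worked examples", {
  # four predictors on one test antigen, from printed (TP, FP, FN)
  expect_equal(round(confusion_metrics(23, 17, 4, 189)$f1, 4), 0.6866)
  expect_equal(round(confusion_metrics(23, 37, 4, 169)$f1, 4), 0.5287)
  expect_equal(round(confusion_metrics(18, 18, 9, 188)$f1, 4), 0.5714)
  expect_equal(round(confusion_metrics(5, 14, 22, 192)$f1, 4), 0.2174)
  # F1 from counts does not depend on TN
  expect_equal(confusion_metrics(23, 17, 4, 1)$f1,
               confusion_metrics(23, 17, 4, 10000)$f1)
})

test_that("confusion metrics handle perfect and degenerate inputs", {
  m <- confusion_metrics(10, 0, 0, 20)
  expect_equal(unlist(m), c(pre = 1, rec = 1, f1 = 1, mcc = 1, bacc = 1))
  z <- confusion_metrics(0, 0, 5, 5)
  expect_equal(z$pre, 0)
  expect_equal(z$f1, 0)
  expect_equal(z$mcc, 0)
})

test_that("confusion metrics equal brute-force tabulation from scores", {
  set.seed(3)
  for (case in 1:25) {
    n <- sample(20:80, 1)
    s <- round(runif(n), 2)  # force ties
    y <- rbinom(n, 1, 0.3)
    t <- runif(1)
    cm <- epigcn:::.confusion_counts(s, y, t)
    want <- oracle_confusion(s, y, t)
    expect_equal(unlist(cm), want)
  }
})

test_that("rank-based AUC equals explicit pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  set.seed(4)
  for (case in 1:20) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    expect_equal(roc_auc(s, y), oracle_auc_pairs(s, y),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC of label-independent scores concentrates near 1/2", {
  set.seed(5)
  n <- 4000
  a <- roc_auc(rnorm(n), rbinom(n, 1, 0.5))
  expect_lt(abs(a - 0.5), 3 / sqrt(n))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  s <- runif(150); y <- rbinom(150, 1, 0.35)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
})

test_that("AUPR is step-wise average precision", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # hand-computed: ranking y = 1,0,1 by score -> AP = (1 + 2/3)/2
  expect_equal(aupr(c(0.9, 0.5, 0.4), c(1, 0, 1)), (1 + 2 / 3) / 2)
  # ties processed as one block
  expect_equal(aupr(c(0.5, 0.5), c(1, 0)), 0.5)
})

test_that("threshold selection maximizes F1 and matches brute force", {
  # perfectly separated: F1 = 1 at the lowest optimal threshold
  sel <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sel$f1, 1)
  expect_lte(sel$threshold, 0.8)
  expect_gt(sel$threshold, 0.2)
  # all-negative labels: no positive F1 attainable
  sel0 <- select_threshold(runif(10), rep(0, 10))
  expect_equal(sel0$threshold, Inf)
  set.seed(7)
  for (case in 1:25) {
    s <- round(runif(20), 1)
    y <- rbinom(20, 1, 0.4)
    got <- select_threshold(s, y)
    expect_equal(got$f1, oracle_best_f1(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong test is null on identical scores, signed on different", {
  set.seed(8)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  dl <- delong_test(s, s, y)
  expect_equal(dl$delta, 0)
  expect_equal(dl$p, 1)
  s2 <- runif(40)
  dl2 <- delong_test(s, s2, y)
  expect_equal(sign(dl2$delta), sign(roc_auc(s, y) - roc_auc(s2, y)))
  expect_equal(dl2$auc_a, roc_auc(s, y))
})

test_that("DeLong agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  base <- rnorm(n) + y
  a <- base + rnorm(n, sd = 0.7)
  b <- base + rnorm(n, sd = 0.9)
  dl <- delong_test(a, b, y)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(y, a, quiet = TRUE), pROC::roc(y, b, quiet = TRUE),
    method = "delong"))
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("stratified bootstrap CIs bracket the point estimate", {
  set.seed(10)
  s <- rnorm(80) + rbinom(80, 1, 0.4)
  y <- as.integer(s > 0.5)  # degenerate-ish but both classes
  y[1:5] <- 1 - y[1:5]
  bs <- stratified_bootstrap(roc_auc, s, y, B = 300, seed = 3)
  expect_lte(bs$ci[1], bs$point)
  expect_gte(bs$ci[2], bs$point)
  # constant metric -> zero-width interval
  bs0 <- stratified_bootstrap(function(s2, y2) 0.7, s, y, B = 50,
                              seed = 4)
  expect_equal(bs0$ci, c(0.7, 0.7))
  # determinism given the seed
  bs2 <- stratified_bootstrap(roc_auc, s, y, B = 300, seed = 3)
  expect_identical(bs$replicates, bs2$replicates)
})

test_that("model comparison reports DeLong and paired bootstrap deltas", {
  set.seed(11)
  n <- 100
  y <- rbinom(n, 1, 0.4)
  a <- rnorm(n) + 1.5 * y
  cmp <- compare_models(a, a, y, B = 100, seed = 5)
  expect_equal(cmp$delong$delta, 0)
  expect_equal(cmp$delong$p, 1)
  expect_equal(cmp$f1$delta, 0)
})

test_that("evaluation reports are internally consistent", {
  set.seed(12)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60) + 0.8 * y
  ev <- evaluate_predictions(s, y, bootstrap = 100, seed = 6)
  expect_equal(ev$tp + ev$fn, sum(y))
  expect_equal(ev$tn + ev$fp, sum(1 - y))
  expect_equal(ev$f1,
               confusion_metrics(ev$tp, ev$fp, ev$fn, ev$tn)$f1)
  expect_true(all(c(ev$auc, ev$aupr, ev$bacc) <= 1))
  expect_length(ev$ci$auc, 2)
})
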