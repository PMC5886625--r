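# independent oracles: O(n^2) pair counting for the ROC area and an
# exhaustive threshold sweep for average precision
auc_paircount <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

ap_sweep <- function(scores, truth) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (th in ths) {
    called <- scores >= th
    prec <- sum(called & truth) / sum(called)
    rec <- sum(called & truth) / sum(truth)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

mat_from_offdiag <- function(v, n) {
  M <- matrix(0, n, n)
  M[row(M) != col(M)] <- v
  M
}

test_that("ROC area agrees with rank-statistic oracles and pROC", {
  G_true <- collider_G()
  expect_equal(roc_auc(G_true, G_true), 1)

  set.seed(1)
  n <- 4
  for (rep in 1:20) {
    truth_v <- sample(c(TRUE, FALSE), n * (n - 1), replace = TRUE)
    if (!any(truth_v) || all(truth_v)) next
    scores_v <- sample(0:5, n * (n - 1), replace = TRUE) / 5
    G_est <- mat_from_offdiag(scores_v, n)
    G_tr <- mat_from_offdiag(as.numeric(truth_v), n)
    expect_equal(roc_auc(G_est, G_tr), auc_paircount(scores_v, truth_v))
    expect_equal(precision_recall_score(G_est, G_tr),
                 ap_sweep(scores_v, truth_v))
  }

  set.seed(2)
  scores_v <- runif(90)
  truth_v <- runif(90) < 0.3
  G_est <- mat_from_offdiag(scores_v, 10)
  G_tr <- mat_from_offdiag(as.numeric(truth_v), 10)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(truth_v, scores_v,
                                             quiet = TRUE,
                                             direction = "<")))
  expect_equal(roc_auc(G_est, G_tr), proc_auc, tolerance = 1e-12)
})

test_that("chance-level scores give AUC near one half", {
  set.seed(3)
  G_tr <- sample_er_network(60, 0.1, 0.5, seed = 4)
  G_est <- mat_from_offdiag(runif(60 * 59), 60)
  expect_lt(abs(roc_auc(G_est, G_tr) - 0.5), 0.05)
})

test_that("AUC and average precision are invariant under monotone rescaling", {
  set.seed(5)
  G_tr <- sample_er_network(20, 0.15, 0.5, seed = 6)
  G_est <- mat_from_offdiag(runif(380), 20)
  f <- function(M) {
    out <- sign(M) * (exp(2 * abs(M)) - 1)  # strictly monotone in |.|
    out
  }
  expect_equal(roc_auc(G_est, G_tr), roc_auc(f(G_est), G_tr))
  expect_equal(precision_recall_score(G_est, G_tr),
               precision_recall_score(f(G_est), G_tr))
})

test_that("all-equal scores collapse average precision to prevalence", {
  G_tr <- sample_er_network(15, 0.2, 0.5, seed = 7)
  G_est <- mat_from_offdiag(rep(1, 15 * 14), 15)
  prevalence <- mean(G_tr[row(G_tr) != col(G_tr)] != 0)
  expect_equal(precision_recall_score(G_est, G_tr), prevalence)
})

test_that("degenerate ground truths are rejected", {
  empty <- matrix(0, 4, 4)
  full <- mat_from_offdiag(rep(1, 12), 4)
  est <- mat_from_offdiag(runif(12), 4)
  expect_error(roc_auc(est, empty), "degenerate")
  expect_error(roc_auc(est, full), "degenerate")
  expect_error(roc_auc(est, matrix(0, 3, 3)), "degenerate|shape")
  expect_error(roc_auc(est, matrix(0, 5, 5)), "shape")
})

test_that("Pearson correlation uses signed weights", {
  set.seed(8)
  G <- sample_er_network(12, 0.3, 0.5, seed = 9)
  expect_equal(pearson(G, G), 1)
  expect_equal(pearson(-G, G), -1)
  expect_equal(pearson(2 * G + 3, G), 1)
  expect_error(pearson(matrix(1, 12, 12), G), "variance")
})

test_that("confusion counts match exhaustive enumeration", {
  set.seed(10)
  for (rep in 1:10) {
    n <- 6
    G_tr <- mat_from_offdiag(sample(c(-1, 0, 1), 30, replace = TRUE,
                                    prob = c(0.2, 0.5, 0.3)), n)
    if (all(G_tr == 0)) next
    G_est <- mat_from_offdiag(runif(30, -1, 1), n)
    th <- 0.4
    r <- confusion_at_threshold(G_est, G_tr, th)
    # brute-force count over all off-diagonal cells
    tp <- fp <- tn <- fn <- 0; sgn <- c()
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      called <- abs(G_est[i, j]) > th
      true_e <- G_tr[i, j] != 0
      if (called && true_e) {
        tp <- tp + 1
        sgn <- c(sgn, sign(G_est[i, j]) == sign(G_tr[i, j]))
      }
      if (called && !true_e) fp <- fp + 1
      if (!called && true_e) fn <- fn + 1
      if (!called && !true_e) tn <- tn + 1
    }
    expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(tp, fp, tn, fn))
    expect_equal(r$fn_rate, fn / (tp + fn))
    expect_equal(r$fp_rate, fp / (fp + tn))
    if (tp > 0) expect_equal(r$sign_accuracy, mean(sgn))
    # miss rate and recall are complements by definition
    expect_equal(r$fn_rate + tp / (tp + fn), 1)
  }
})

test_that("confusion rates behave at the extremes", {
  G_tr <- collider_G()
  dense <- mat_from_offdiag(runif(6, 0.1, 1), 3)
  r <- confusion_at_threshold(dense, G_tr, 0)
  # a dense estimate at threshold zero calls every absent edge
  expect_equal(r$fp_rate, 1)
  r2 <- confusion_at_threshold(G_tr, G_tr, 0.25)
  expect_equal(r2$fn_rate, 0)
  expect_equal(r2$fp_rate, 0)
  expect_equal(r2$sign_accuracy, 1)
})

test_that("default confusion threshold is half the smallest edge weight", {
  G <- collider_G(0.6)
  r <- confusion_at_threshold(G * 0.999, G)
  expect_equal(r$threshold, 0.3)
})

test_that("the combined report bundles all measures consistently", {
  set.seed(11)
  G <- sample_er_network(15, 0.2, 0.5, seed = 12)
  rep <- performance_report(G, G)
  expect_equal(rep$auc, 1)
  expect_equal(rep$prs, 1)
  expect_equal(rep$pcc, 1)
  expect_equal(rep$fn_rate, 0)
  expect_equal(rep$fp_rate, 0)
  expect_equal(rep$sign_accuracy, 1)
})
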