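test_that("confusion counts follow the definitions and ignore sample order", {
  y <- rep(c("pos", "neg"), each = 10)
  cm <- confusion(y, y, "pos")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(10, 0, 10, 0))

  all_pos <- confusion(y, rep("pos", 20), "pos")
  expect_equal(all_pos$fn, 0)
  expect_equal(all_pos$tn, 0)
  expect_equal(all_pos$fp, 10)

  set.seed(51)
  pred <- sample(c("pos", "neg"), 20, replace = TRUE)
  o <- sample(20)
  cm1 <- confusion(y, pred, "pos")
  cm2 <- confusion(y[o], pred[o], "pos")
  expect_equal(cm1[c("tp", "fp", "tn", "fn")], cm2[c("tp", "fp", "tn", "fn")])

  expect_error(confusion(c(y, "odd"), c(pred, "pos"), "pos", "neg"), "unknown")
})

test_that("metrics reproduce the external-validation arithmetic", {
  # 104 positives with 13 false negatives; 54 negatives with 4 false positives
  cm <- list(tp = 91, fn = 13, tn = 50, fp = 4)
  m <- qc_metrics(cm)
  expect_equal(m$sensitivity, 87.5)
  expect_equal(m$specificity, 92.6)
  expect_equal(m$accuracy, round(100 * 141 / 158, 1))  # 89.2
  # good-vs-poor external counts
  m2 <- qc_metrics(list(tp = 198, fn = 0, tn = 157, fp = 1))
  expect_equal(m2$sensitivity, 100.0)
  expect_equal(m2$specificity, 99.4)
  expect_equal(m2$accuracy, 99.7)
})

test_that("metrics of a perfect prediction are all 100 and zero denominators are NA", {
  set.seed(52)
  y <- sample(c("a", "b"), 30, replace = TRUE)
  m <- qc_metrics(confusion(y, y, "a"))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(100, 100, 100))
  m0 <- qc_metrics(list(tp = 0, fn = 0, tn = 5, fp = 5))
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 50.0)
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(53)
  for (rep in 1:5) {
    n <- c(20, 35, 50, 40, 30)[rep]
    y <- sample(c("p", "n"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    scores <- switch(rep,
      rnorm(n),
      rnorm(n) + (y == "p"),
      round(runif(n), 1),              # heavy ties
      as.numeric(y == "p"),            # perfectly separated
      rep(0.5, n)                      # all tied
    )
    roc <- roc_auc(y, scores, "p")
    expect_lt(abs(roc$auc - oracle_auc(y, scores, "p")), 1e-12)
  }
  y <- rep(c("p", "n"), each = 10)
  expect_equal(roc_auc(y, as.numeric(y == "p"), "p")$auc, 1.0)
  expect_error(roc_auc(rep("p", 5), rnorm(5), "p"), "both classes")
})

test_that("AUC of label-independent scores is near one half", {
  set.seed(54)
  y <- sample(c("p", "n"), 1000, replace = TRUE)
  expect_lt(abs(roc_auc(y, rnorm(1000), "p")$auc - 0.5), 0.03)
})

test_that("misclassification shares match the printed breakdown arithmetic", {
  # false negatives: CRVO 7, vitreous opacity 6 -> 53.8 / 46.2
  y_true <- c(rep("eye_abnormality", 104), rep("artefact", 54))
  y_pred <- y_true
  y_pred[1:7] <- "artefact"    # CRVO misread as artefact
  y_pred[8:13] <- "artefact"   # vitreous opacity misread
  y_pred[105:107] <- "eye_abnormality"  # blur misread
  y_pred[108] <- "eye_abnormality"      # underexposure misread
  subtype <- c(rep("crvo", 7), rep("vitreous_opacity", 6), rep("cataract", 91),
               rep("blur", 3), "underexposure", rep("blur", 50))
  bd <- misclassification_breakdown(y_true, y_pred, subtype, "eye_abnormality")
  fn <- bd[bd$direction == "false_negative", ]
  expect_equal(fn$share_pct[fn$subtype == "crvo"], 53.8)
  expect_equal(fn$share_pct[fn$subtype == "vitreous_opacity"], 46.2)
  expect_equal(sum(fn$n), 13)
  fp <- bd[bd$direction == "false_positive", ]
  expect_equal(fp$share_pct[fp$subtype == "blur"], 75.0)
  expect_equal(fp$share_pct[fp$subtype == "underexposure"], 25.0)
  expect_equal(sum(fp$n), 4)
})

test_that("shares always sum to exactly 100 under largest-remainder rounding", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    counts <- sample(1:40, k, replace = TRUE)
    y_true <- rep("pos", sum(counts))
    y_pred <- rep("neg", sum(counts))
    sub <- rep(letters[seq_len(k)], counts)
    bd <- misclassification_breakdown(c(y_true, "neg"), c(y_pred, "neg"), c(sub, "x"), "pos")
    expect_equal(sum(bd$share_pct[bd$direction == "false_negative"]), 100)
  }
  empty <- misclassification_breakdown(c("a", "b"), c("a", "b"), c("s", "t"), "a")
  expect_equal(nrow(empty), 0)
})

test_that("quality_report bundles metrics, ROC and breakdown coherently", {
  set.seed(56)
  y <- rep(c("pos", "neg"), c(30, 30))
  prob <- pmin(pmax(rnorm(60, ifelse(y == "pos", 0.8, 0.2), 0.25), 0), 1)
  rep_ <- quality_report(y, prob, "pos", subtypes = sample(c("u", "v"), 60, TRUE))
  expect_s3_class(rep_, "fqc_report")
  expect_equal(rep_$cm$tp + rep_$cm$fn, 30)
  expect_equal(rep_$auc, roc_auc(y, prob, "pos")$auc)
  g <- glance(rep_)
  expect_true(all(c("sensitivity", "specificity", "accuracy", "auc") %in% names(g)))
  pl <- autoplot(rep_$roc)
  expect_s3_class(pl, "ggplot")
})
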