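sim_logit_data <- function(n, p_noise, n_inf = 0, effect = 2, seed = 1) {
  set.seed(seed)
  p <- p_noise + n_inf
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c(sprintf("inf_%02d", seq_len(n_inf)),
                   sprintf("noise_%03d", seq_len(p_noise)))[seq_len(p)]
  eta <- if (n_inf > 0) X[, seq_len(n_inf), drop = FALSE] %*% rep(effect, n_inf) else rep(0, n)
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y)
}

test_that("the penalty limit and standardization contracts hold", {
  d <- sim_logit_data(200, p_noise = 30, n_inf = 3, seed = 61)
  sel <- fit_elastic_net(d$X, d$y, rng_seed = 1)
  # at the largest lambda of the path every coefficient is zero
  expect_true(all(sel$coef_path[, 1] == 0))
  expect_gt(nrow(sel$selected), 0)
  expect_true(all(sel$selected$feature %in% colnames(d$X)))
  # constant columns are dropped with a warning
  X2 <- cbind(d$X, const = 1)
  expect_warning(fit_elastic_net(X2, d$y, rng_seed = 1), "constant")
  # single-class labels are an error
  expect_error(fit_elastic_net(d$X, rep(1, 200)), "single class")
  ix <- c(which(d$y == 0)[1:3], which(d$y == 1)[1:3])
  expect_error(fit_elastic_net(d$X[ix, ], d$y[ix], cv_folds = 10), "cv_folds")
})

test_that("selection is deterministic given data and seed", {
  d <- sim_logit_data(150, p_noise = 40, n_inf = 2, seed = 62)
  s1 <- fit_elastic_net(d$X, d$y, rng_seed = 7)
  s2 <- fit_elastic_net(d$X, d$y, rng_seed = 7)
  expect_identical(s1$chosen_lambda, s2$chosen_lambda)
  expect_identical(tidy(s1), tidy(s2))
  expect_equal(glance(s1)$n_selected, nrow(s1$selected))
})

test_that("informative features are recovered and permuted labels select little", {
  d <- sim_logit_data(500, p_noise = 100, n_inf = 5, effect = 2, seed = 63)
  sel <- fit_elastic_net(d$X, d$y, rng_seed = 2)
  expect_gte(sum(grepl("^inf_", sel$selected$feature)), 4)

  set.seed(64)
  yperm <- sample(d$y)
  sperm <- fit_elastic_net(d$X, yperm, rng_seed = 3)
  # null labels keep the selected set very small (non-empty by contract)
  expect_lte(nrow(sperm$selected), 10)
})

test_that("random forests separate what is separable and are reproducible", {
  set.seed(65)
  X <- cbind(a = c(rnorm(50, -3), rnorm(50, 3)), b = rnorm(100))
  y <- rep(c("neg", "pos"), each = 50)
  sel <- fit_elastic_net(X, y, positive_class = "pos", rng_seed = 1, cv_folds = 5)
  rf <- train_classifier(X, y, sel, kind = "random_forest", rng_seed = 9,
                         positive_class = "pos")
  expect_equal(mean(predict_label(rf, X) == y), 1.0)
  rf2 <- train_classifier(X, y, sel, kind = "random_forest", rng_seed = 9,
                          positive_class = "pos")
  expect_identical(rf$fitted$votes, rf2$fitted$votes)

  pr <- predict_proba(rf, X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(predict_label(rf, X, threshold = 0) == "pos"))
  # calibration: mean training probability tracks prevalence
  expect_lt(abs(mean(pr) - mean(y == "pos")), 0.1)

  Xbad <- X[, "b", drop = FALSE]
  expect_error(predict_proba(rf, Xbad), "missing feature")
})

test_that("forests capture the XOR interaction that linear selection misses", {
  set.seed(66)
  n <- 400
  cl <- sample(0:3, n, replace = TRUE)
  X <- cbind(x = ifelse(cl %in% c(0, 1), -1, 1) + rnorm(n, 0, 0.3),
             y = ifelse(cl %in% c(0, 2), -1, 1) + rnorm(n, 0, 0.3))
  y <- ifelse(cl %in% c(0, 3), "pos", "neg")
  tr <- seq_len(300)
  sel <- structure(list(
    selected = tibble::tibble(index = 1:2, feature = c("x", "y"),
                              coefficient = c(1, 1)),
    standardization = list(mean = colMeans(X[tr, ]),
                           sd = apply(X[tr, ], 2, sd),
                           kept = c("x", "y")),
    positive_class = "pos", negative_class = "neg"
  ), class = "fqc_selection")
  rf <- train_classifier(X[tr, ], y[tr], sel, rng_seed = 3, positive_class = "pos")
  acc <- mean(predict_label(rf, X[-tr, ]) == y[-tr])
  expect_gt(acc, 0.9)
})

test_that("SVM probabilities are deterministic and rank like the decision values", {
  set.seed(67)
  X <- cbind(a = c(rnorm(60, -1.5), rnorm(60, 1.5)), b = rnorm(120))
  y <- rep(c("neg", "pos"), each = 60)
  sel <- fit_elastic_net(X, y, positive_class = "pos", rng_seed = 1, cv_folds = 5)
  m1 <- train_classifier(X, y, sel, kind = "svm", positive_class = "pos")
  m2 <- train_classifier(X, y, sel, kind = "svm", positive_class = "pos")
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  pr <- predict_proba(m1, X)
  expect_gt(mean(pr[y == "pos"]), mean(pr[y == "neg"]))
  expect_gt(mean((pr >= 0.5) == (y == "pos")), 0.9)
})

test_that("cross-validation pools a partition and nails separable data", {
  set.seed(68)
  X <- cbind(s = c(rnorm(40, -4), rnorm(40, 4)), n1 = rnorm(80), n2 = rnorm(80))
  y <- rep(c("neg", "pos"), each = 40)
  cv <- crossvalidate(X, y, k = 5, kind = "svm", positive_class = "pos",
                      rng_seed = 11)
  expect_equal(cv$report$metrics$accuracy, 100)
  # every sample is out-of-fold exactly once
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  expect_equal(nrow(cv$predictions), 80)
  expect_equal(tabulate(cv$predictions$fold[y == "pos"], 5), rep(8, 5))
  # determinism of the pooled confusion matrix
  cv2 <- crossvalidate(X, y, k = 5, kind = "svm", positive_class = "pos",
                       rng_seed = 11)
  expect_identical(cv$report$cm, cv2$report$cm)
  expect_identical(tidy(cv), tidy(cv2))
  expect_error(crossvalidate(X[1:12, ], y[c(1:6, 41:46)], k = 10), "smaller k")
})

test_that("cross-validation on pure noise hovers at chance", {
  set.seed(69)
  X <- matrix(rnorm(200 * 10), 200, 10)
  colnames(X) <- sprintf("n%02d", 1:10)
  y <- rep(c("neg", "pos"), each = 100)
  cv <- crossvalidate(X, y, k = 5, kind = "svm", positive_class = "pos",
                      rng_seed = 13)
  expect_gte(cv$report$metrics$accuracy, 40)
  expect_lte(cv$report$metrics$accuracy, 60)
})
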