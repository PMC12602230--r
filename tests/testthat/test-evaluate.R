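test_that("AUC equals exhaustive concordant-pair counting", {
  expect_equal(auc_delong(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(auc_delong(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1.0)
  expect_equal(auc_delong(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(auc_delong(1:4, rep(1, 4)), "both classes")

  set.seed(71)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    y <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    s <- sample(seq_len(n %/% 2), n, replace = TRUE) / 10  # forces ties
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                          ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(auc_delong(s, y)$auc, oracle, tolerance = 1e-12)
  }
})

test_that("DeLong variance and CI agree with the reference implementation", {
  set.seed(72)
  y <- rep(0:1, each = 40)
  s <- rnorm(80) + y
  de <- auc_delong(s, y)
  expect_gte(de$variance, 0)
  ro <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(ro, method = "delong")
  expect_equal(de$auc, as.numeric(pROC::auc(ro)), tolerance = 1e-12)
  expect_equal(de$ci[1], as.numeric(ci[1]), tolerance = 1e-9)
  expect_equal(de$ci[2], as.numeric(ci[3]), tolerance = 1e-9)
})

test_that("CI width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    y <- rep(0:1, each = n / 2)
    s <- rnorm(n) + y
    diff(auc_delong(s, y)$ci)
  }, 0)
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1] / 2.5)
})

test_that("the paired DeLong test is calibrated and powered", {
  y <- rep(0:1, each = 30)
  s <- rnorm(60) + y
  same <- delong_test(s, s, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(s[-1], s, y), "paired")

  # cross-check against pROC's paired test
  set.seed(73)
  s2 <- rnorm(60) + 0.5 * y
  mine <- delong_test(s, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                        pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)

  # power: informative vs pure noise at n = 200
  hits <- vapply(1:10, function(ss) {
    set.seed(200 + ss)
    yy <- rep(0:1, each = 100)
    good <- rnorm(200) + 1.2 * yy
    noise <- rnorm(200)
    delong_test(good, noise, yy)$p_value < 0.05
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("threshold metrics reproduce closed-form confusion ratios", {
  # confusion TP=15 FN=2 TN=26 FP=14 at threshold 0.5
  scores <- c(rep(0.9, 15), rep(0.1, 2), rep(0.2, 26), rep(0.8, 14))
  labels <- c(rep(1, 17), rep(0, 40))
  tm <- threshold_metrics(scores, labels, threshold = 0.5)
  expect_equal(tm$sensitivity, 15 / 17)
  expect_equal(tm$specificity, 26 / 40)
  expect_equal(tm$ppv, 15 / 29)
  expect_equal(tm$npv, 26 / 28)
  expect_equal(tm$accuracy, 41 / 57)

  perfect <- threshold_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")]) == 1))

  allpos <- suppressWarnings(
    threshold_metrics(rep(0.9, 10), rep(0:1, 5), threshold = 0.5))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$ppv, 0.5)   # prevalence
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  set.seed(74)
  y <- rep(0:1, each = 50)
  s <- rnorm(100) + 1.5 * y
  thr <- youden_threshold(s, y)
  j_at <- function(t) {
    tm <- threshold_metrics(s, y, t)
    tm$sensitivity + tm$specificity - 1
  }
  expect_true(all(j_at(thr) >= vapply(unique(s), j_at, 0) - 1e-12))
})

test_that("Hosmer-Lemeshow vanishes for perfectly grouped probabilities", {
  p <- rep(c(0.2, 0.8), each = 20)
  y <- c(rep(c(1, 0, 0, 0, 0), 4), rep(c(1, 1, 1, 1, 0), 4))
  hl <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_error(hosmer_lemeshow(runif(15), rbinom(15, 1, 0.5), groups = 10),
               "at least")
})

test_that("Hosmer-Lemeshow p-values are roughly uniform for calibrated fitted models", {
  # the chi-square(g-2) reference is derived for fitted probabilities, so
  # the calibration simulation fits a logistic model per replicate
  set.seed(75)
  pv <- replicate(100, {
    x <- rnorm(300)
    y <- rbinom(300, 1, plogis(x))
    p <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(p, y)$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.001)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("decision curves follow the net-benefit closed form", {
  set.seed(76)
  y <- rep(0:1, each = 50)
  dca <- decision_curve(runif(100), y, thresholds = c(0.01, 0.25, 0.5, 1.0))
  expect_equal(nrow(dca), 3L)            # pt = 1 excluded
  prev <- 0.5
  expect_equal(dca$treat_all,
               prev - (1 - prev) * dca$threshold / (1 - dca$threshold))
  expect_equal(dca$treat_all[1], prev - 0.5 * 0.01 / 0.99)
  expect_equal(dca$treat_all[dca$threshold == 0.5], 0)
  expect_true(all(dca$treat_none == 0))

  # a perfect model has net benefit = prevalence at every threshold
  perf <- decision_curve(y, y, thresholds = seq(0.05, 0.95, 0.1))
  expect_true(all(abs(perf$net_benefit - prev) < 1e-12))
  expect_true(all(perf$net_benefit >= perf$treat_all - 1e-12))
})

test_that("Shapley attributions satisfy local accuracy and match enumeration", {
  tab <- data.frame(f1 = rnorm(80), f2 = rnorm(80), f3 = rnorm(80))
  tab$response <- rbinom(80, 1, plogis(1.5 * tab$f1 - tab$f2))
  for (alg in c("xgb", "lr", "rf")) {
    m <- train_model(tab, c("f1", "f2", "f3"), alg, seed = 2)
    at <- shapley_attribution(m, tab[1:5, ], tab[1:40, ], n_perm = 30,
                              seed = 3)
    recon <- at$base + rowSums(at$contributions)
    expect_equal(unname(recon), unname(at$prediction), tolerance = 1e-6)
  }

  # additive logistic model: phi_j = w_j (x_j - mean background_j), equal to
  # exhaustive 2^3 coalition enumeration on the link scale
  m <- train_model(tab, c("f1", "f2", "f3"), "lr", seed = 2)
  beta <- coef(m$object)
  bg <- tab[1:40, ]
  at <- shapley_attribution(m, tab[1, ], bg)
  f_link <- function(z) beta[1] + sum(beta[-1] * z)
  oracle <- exact_shapley(f_link, as.numeric(tab[1, 1:3]),
                          colMeans(bg[, 1:3]))
  expect_equal(unname(at$contributions[1, ]), oracle, tolerance = 1e-9)

  # a feature the trees never use gets zero contribution
  tab2 <- tab; tab2$dead <- 0
  m2 <- train_model(tab2, c("f1", "dead"), "xgb", seed = 2)
  at2 <- shapley_attribution(m2, tab2[1:5, ], tab2[1:20, ])
  expect_true(all(at2$contributions[, "dead"] == 0))

  expect_error(shapley_attribution(m, tab[1, ], tab[0, ]), "background")
})

test_that("nomogram export reconstructs the logistic model exactly", {
  set.seed(77)
  n <- 120
  tab <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  tab$response <- rbinom(n, 1, plogis(0.6 * tab$a - 0.3 * tab$b - 1))
  m <- train_model(tab, c("a", "b"), "lr", seed = 1)
  nom <- nomogram_export(m, tab)
  # largest coefficient-x-range span anchors the 100-point axis; the other
  # axis scales by its span ratio
  mp <- sort(nom$max_points, decreasing = TRUE)
  expect_equal(unname(mp[1]), 100)
  beta <- abs(coef(m$object)[-1])
  spans <- beta * c(diff(range(tab$a)), diff(range(tab$b)))
  expect_equal(unname(mp[2] / mp[1]),
               unname(min(spans) / max(spans)), tolerance = 1e-9)
  # round trip: probability(points(x)) = model probability(x)
  for (i in c(1, 7, 33)) {
    total <- sum(nom$points_of(tab[i, ]))
    expect_equal(nom$prob_of_total(total), unname(predict(m, tab[i, ])),
                 tolerance = 1e-6)
  }
  m_xgb <- train_model(tab, c("a", "b"), "xgb", seed = 1)
  expect_error(nomogram_export(m_xgb, tab), "logistic")
})

test_that("evaluation reports are internally consistent", {
  set.seed(78)
  y <- rep(0:1, each = 30)
  s <- plogis(rnorm(60) + 1.5 * y)
  rp <- evaluate_model(s, y, hl_groups = 5)
  expect_true(rp$ci[1] <= rp$auc && rp$auc <= rp$ci[2])
  cm <- rp$confusion
  expect_equal(rp$accuracy, (cm["tp"] + cm["tn"]) / 60, ignore_attr = TRUE)
  expect_true(all(rp$dca$net_benefit <= mean(y) + 1e-12))
})
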