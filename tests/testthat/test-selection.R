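test_that("the significance filter keeps separated features and drops flat ones", {
  set.seed(41)
  y <- rep(0:1, each = 20)
  X <- cbind(sep = c(rnorm(20, 0), rnorm(20, 10)),  # disjoint supports
             flat = rep(1, 40),
             noise = rnorm(40))
  out <- significance_filter(X, y)
  expect_true("sep" %in% out$survivors)
  expect_lt(out$p_values["sep"], 1e-6)
  expect_equal(unname(out$p_values["flat"]), 1)
  expect_false("flat" %in% out$survivors)
  expect_error(significance_filter(X[c(1, 2, 21), ], y[c(1, 2, 21)]),
               "at least 3")
})

test_that("the significance filter chooses the test per class-wise normality", {
  set.seed(42)
  y <- rep(0:1, each = 30)
  X <- cbind(gauss = rnorm(60) + y,
             heavy = rcauchy(60) + 5 * y)
  out <- significance_filter(X, y)
  expect_equal(unname(out$test_used["gauss"]), "t")
  expect_equal(unname(out$test_used["heavy"]), "wilcox")
})

test_that("correlation pruning keeps one member per correlated clique", {
  set.seed(43)
  a <- rnorm(50)
  X <- cbind(a = a, dup = a, b = rnorm(50))
  out <- correlation_prune(X, 0.9)
  expect_length(intersect(c("a", "dup"), out$survivors), 1L)
  expect_true("b" %in% out$survivors)

  # orthogonal features all survive
  O <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(O) <- paste0("f", 1:5)
  expect_setequal(correlation_prune(O, 0.9)$survivors, colnames(O))

  # documented victim rule: f1 is highly correlated with both f2 and f3,
  # which correlate less with each other -> f1 has the larger mean
  # absolute correlation and is dropped, f2 and f3 both survive
  n <- 4000
  z <- rnorm(n)
  X3 <- cbind(f1 = z, f2 = z + rnorm(n, sd = 0.33), f3 = z + rnorm(n, sd = 0.33))
  r <- abs(cor(X3))
  stopifnot(r["f1", "f2"] > 0.93, r["f1", "f3"] > 0.93, r["f2", "f3"] < 0.93)
  out3 <- correlation_prune(X3, threshold = 0.93)
  expect_setequal(out3$survivors, c("f2", "f3"))
  expect_true("f1" %in% names(out3$dropped))
})

test_that("recursive elimination retains a planted predictor", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    y <- rep(0:1, each = 25)
    X <- cbind(signal = y * 2 + rnorm(50, sd = 0.5),
               matrix(rnorm(50 * 9), ncol = 9,
                      dimnames = list(NULL, paste0("n", 1:9))))
    "signal" %in% recursive_elimination(X, y, target_n = 1, step = 2)
  }, TRUE)
  expect_gte(sum(hits), 4)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(0:1, 5)
  expect_warning(out <- recursive_elimination(X, y, target_n = 4), "all")
  expect_setequal(out, colnames(X))
  expect_error(recursive_elimination(X, y, target_n = 2, step = 0), "step")
})

test_that("mRMR ranks by the documented greedy criterion", {
  set.seed(44)
  n <- 100
  y <- rep(0:1, each = n / 2)
  base <- y + rnorm(n, sd = 0.7)
  X <- cbind(top = base,
             copy = base + rnorm(n, sd = 0.05),
             weak = y + rnorm(n, sd = 2),
             noise = rnorm(n))
  out <- mrmr_select(X, y, 3)
  expect_equal(out$survivors[1], "top")        # max relevance first
  expect_false(out$survivors[2] == "copy")     # redundancy penalty

  # full greedy order equals brute-force evaluation of the criterion
  f_stat <- apply(X, 2, function(x) {
    m <- tapply(x, y, mean); nn <- tapply(x, y, length)
    ssb <- sum(nn * (m - mean(x))^2)
    ssw <- sum((x - m[as.character(y)])^2)
    f <- ssb / (ssw / (n - 2))
    sqrt(f / (f + n - 2))     # correlation-scale relevance
  })
  sel <- character(0); cand <- colnames(X)
  for (s in 1:4) {
    crit <- vapply(cand, function(f) {
      red <- if (!length(sel)) 0 else mean(abs(cor(X[, f], X[, sel])))
      f_stat[f] - red
    }, 0)
    sel <- c(sel, cand[which.max(crit)])
    cand <- setdiff(cand, sel)
  }
  expect_identical(mrmr_select(X, y, 4)$survivors, sel)
  expect_warning(mrmr_select(X, y, 10), "truncating")
})

test_that("LASSO selection shrinks to nothing at huge lambda and flags it", {
  set.seed(45)
  X <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(60, 1, 0.5)
  out <- lasso_select(X, y, cv_folds = 5, lambda = c(1e4, 5e3), seed = 1)
  expect_length(out$survivors, 0L)
  expect_true(out$no_signal)
})

test_that("LASSO recovers planted predictors across seeds", {
  ok <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    n <- 200
    X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("f", 1:50)))
    lp <- 1.5 * X[, 1] - 1.5 * X[, 2] + 1.2 * X[, 3]
    y <- rbinom(n, 1, plogis(lp))
    out <- lasso_select(X, y, seed = s)
    all(c("f1", "f2", "f3") %in% out$survivors)
  }, TRUE)
  expect_gte(sum(ok), 4)
})

test_that("cascade stages are strictly nested and deterministic", {
  set.seed(46)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(matrix(rnorm(n * 40), ncol = 40,
                    dimnames = list(NULL, paste0("x", 1:40))),
             s1 = y + rnorm(n, sd = 0.6), s2 = -y + rnorm(n, sd = 0.6))
  rep1 <- run_selection(X, y, rfe_target = 20, mrmr_target = 8, seed = 2)
  rep2 <- run_selection(X, y, rfe_target = 20, mrmr_target = 8, seed = 2)
  expect_identical(rep1$stages, rep2$stages)
  st <- rep1$stages
  for (i in seq_len(length(st) - 1)) {
    expect_true(all(st[[i + 1]] %in% st[[i]]))
  }
  expect_true(all(rep1$final %in% st$mrmr))
})
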