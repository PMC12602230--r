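# Five-stage feature-selection cascade:
# significance filter -> correlation pruning -> recursive elimination ->
# mRMR -> LASSO. All statistics are computed on training rows only.

#' Univariate significance filter
#'
#' Per feature, class-wise normality is assessed with Shapiro-Wilk
#' (alpha = 0.05); normal features are compared with Welch's t-test,
#' non-normal with the Mann-Whitney U test. Features with p < `alpha`
#' survive.
#'
#' @param X numeric matrix/data.frame, training rows x features.
#' @param y binary response (0/1), one per row.
#' @param alpha significance level.
#' @return list with `survivors` (names), `p_values`, `test_used`.
#' @export
significance_filter <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < 3) stop("each class needs at least 3 observations")
  pv <- numeric(ncol(X)); tu <- character(ncol(X))
  for (j in seq_len(ncol(X))) {
    a <- X[y == 0, j]; b <- X[y == 1, j]
    if (var(a) < 1e-24 && var(b) < 1e-24) {
      # no variation: no evidence of a difference
      pv[j] <- 1; tu[j] <- "none"; next
    }
    normal <- function(v) {
      if (var(v) < 1e-24) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }
    if (normal(a) && normal(b)) {
      pv[j] <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
      tu[j] <- "t"
    } else {
      pv[j] <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      tu[j] <- "wilcox"
    }
  }
  names(pv) <- names(tu) <- colnames(X)
  list(survivors = colnames(X)[pv < alpha], p_values = pv, test_used = tu)
}

#' Correlation pruning
#'
#' Greedy removal of highly correlated pairs: while any pair has
#' |Pearson r| >= `threshold`, the member with the larger mean absolute
#' correlation to all remaining features is dropped. Zero-variance
#' features are dropped first.
#'
#' @param X numeric matrix, rows x features (>= 2 features).
#' @param threshold correlation threshold (default 0.9).
#' @return list with `survivors` and `dropped` (with reasons).
#' @export
correlation_prune <- function(X, threshold = 0.9) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(list(survivors = colnames(X), dropped = character(0)))
  dropped <- character(0)
  zv <- apply(X, 2, var) < 1e-24
  if (any(zv)) {
    dropped <- setNames(rep("zero variance", sum(zv)), colnames(X)[zv])
    X <- X[, !zv, drop = FALSE]
  }
  if (ncol(X) >= 2) {
    R <- abs(cor(X))
    diag(R) <- 0
    while (ncol(R) >= 2 && max(R) >= threshold) {
      idx <- which(R == max(R), arr.ind = TRUE)[1, ]
      mac <- rowMeans(R)
      victim <- if (mac[idx[1]] >= mac[idx[2]]) idx[1] else idx[2]
      other <- if (victim == idx[1]) idx[2] else idx[1]
      dropped <- c(dropped, setNames(
        sprintf("|r|=%.3f with %s", max(R), colnames(R)[other]),
        colnames(R)[victim]))
      R <- R[-victim, -victim, drop = FALSE]
    }
    surv <- colnames(R)
  } else surv <- colnames(X)
  list(survivors = surv, dropped = dropped)
}

# ridge-logistic importance used by the recursive eliminator
ridge_importance <- function(X, y) {
  sds <- apply(X, 2, sd)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 0.1, standardize = TRUE)
  abs(as.numeric(coef(fit))[-1]) * sds   # coefficient on the SD scale
}

#' Recursive feature elimination
#'
#' Iteratively refits a ridge-penalized logistic model and removes the
#' `step` features with the smallest standardized coefficient magnitude
#' until `target_n` remain. Deterministic.
#'
#' @param X numeric matrix, training rows x features.
#' @param y binary response.
#' @param target_n number of features to retain.
#' @param step features removed per iteration.
#' @return character vector of surviving feature names.
#' @export
recursive_elimination <- function(X, y, target_n, step = 10) {
  X <- as.matrix(X)
  if (step <= 0) stop("step must be positive")
  if (target_n >= ncol(X)) {
    warning("target_n >= number of features: returning all")
    return(colnames(X))
  }
  keep <- colnames(X)
  while (length(keep) > target_n) {
    imp <- ridge_importance(X[, keep, drop = FALSE], y)
    ndrop <- min(step, length(keep) - target_n)
    keep <- keep[-order(imp)[seq_len(ndrop)]]
  }
  keep
}

#' Minimum-redundancy maximum-relevance ranking
#'
#' Greedy difference variant: relevance is the one-way F statistic of the
#' feature against the class, mapped to the correlation scale
#' `sqrt(F / (F + n - 2))` so it is commensurate with the redundancy term;
#' redundancy is the mean absolute Pearson correlation with
#' already-selected features. The first pick maximizes relevance; each
#' later pick maximizes relevance minus mean redundancy.
#'
#' @param X numeric matrix, training rows x features.
#' @param y binary response.
#' @param target_n number of features to rank (truncated with a warning if
#'   more than available).
#' @return list with `survivors` (in selection order) and `scores`.
#' @export
mrmr_select <- function(X, y, target_n) {
  X <- as.matrix(X)
  if (target_n > ncol(X)) {
    warning("target_n exceeds available features; truncating")
    target_n <- ncol(X)
  }
  y <- as.integer(y)
  n <- length(y)
  f_stat <- apply(X, 2, function(x) {
    m <- tapply(x, y, mean)
    nn <- tapply(x, y, length)
    ssb <- sum(nn * (m - mean(x))^2)
    ssw <- sum((x - m[as.character(y)])^2)
    if (ssw < 1e-24) return(Inf)
    (ssb / 1) / (ssw / (n - 2))
  })
  # correlation-scale relevance, commensurate with the |r| redundancy term
  f_stat <- sqrt(f_stat / (f_stat + n - 2))
  f_stat[is.nan(f_stat)] <- 1
  selected <- integer(0)
  scores <- numeric(0)
  cand <- seq_len(ncol(X))
  redsum <- numeric(ncol(X))   # cumulative |r| with the selected set
  for (s in seq_len(target_n)) {
    crit <- if (s == 1) f_stat[cand] else f_stat[cand] - redsum[cand] / (s - 1)
    pick <- cand[which.max(crit)]
    scores <- c(scores, max(crit))
    selected <- c(selected, pick)
    cand <- setdiff(cand, pick)
    if (!length(cand)) break
    r <- abs(suppressWarnings(cor(X[, cand, drop = FALSE], X[, pick])))
    r[is.na(r)] <- 0
    redsum[cand] <- redsum[cand] + as.numeric(r)
  }
  list(survivors = colnames(X)[selected],
       scores = setNames(scores, colnames(X)[selected]))
}

#' LASSO logistic selection
#'
#' Internal z-scoring on training rows, then a cross-validated logistic
#' LASSO path; survivors are the features with nonzero coefficients at the
#' selected lambda. Emits the Rad-score weights (linear predictor on the
#' standardized scale).
#'
#' @param X numeric matrix, training rows x features.
#' @param y binary response.
#' @param cv_folds folds for lambda selection (default 10).
#' @param lambda optional lambda grid.
#' @param rule `"min"` (CV-deviance minimum, default) or `"1se"`.
#' @param seed RNG seed for fold assignment.
#' @return list with `survivors`, `weights` (named, standardized scale),
#'   `intercept`, `lambda`, `path` (lambda grid + nonzero counts),
#'   `scaler`, and `no_signal` flag.
#' @export
lasso_select <- function(X, y, cv_folds = 10, lambda = NULL,
                         rule = c("min", "1se"), seed = 1L) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  mu <- colMeans(X); sds <- apply(X, 2, sd)
  sds[sds < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  cvfit <- with_seed(seed, function() {
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(Xs)))
    glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                      lambda = lambda, foldid = foldid,
                      type.measure = "deviance", standardize = FALSE)
  })
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  co <- as.numeric(coef(cvfit, s = lam))
  nz <- which(co[-1] != 0)
  list(survivors = colnames(X)[nz],
       weights = setNames(co[-1][nz], colnames(X)[nz]),
       intercept = co[1],
       lambda = lam,
       path = data.frame(lambda = cvfit$lambda,
                         nonzero = cvfit$nzero,
                         cvm = cvfit$cvm),
       scaler = list(mean = mu, sd = sds),
       no_signal = length(nz) == 0)
}

#' Run the full selection cascade
#'
#' Significance filter, correlation pruning, recursive elimination (to
#' `rfe_target`), mRMR (to `mrmr_target`), then LASSO. Stage survivors are
#' strictly nested. If the LASSO retains nothing, the pipeline falls back
#' to the mRMR set with a `no_signal` flag.
#'
#' @param X numeric matrix, training rows x features.
#' @param y binary response for the same rows.
#' @param alpha significance level of stage 1.
#' @param cor_threshold stage-2 |r| threshold.
#' @param rfe_target,mrmr_target intermediate stage sizes.
#' @param cv_folds,seed LASSO cross-validation controls.
#' @return A `selection_report`: per-stage survivor lists and diagnostics.
#' @export
run_selection <- function(X, y, alpha = 0.05, cor_threshold = 0.9,
                          rfe_target = 100, mrmr_target = 30,
                          cv_folds = 10, seed = 1L) {
  X <- as.matrix(X)
  st1 <- significance_filter(X, y, alpha)
  stages <- list(significance = st1$survivors)
  cur <- st1$survivors
  if (!length(cur))
    return(structure(list(stages = stages, final = character(0),
                          no_signal = TRUE), class = "selection_report"))
  st2 <- correlation_prune(X[, cur, drop = FALSE], cor_threshold)
  stages$correlation <- st2$survivors
  cur <- st2$survivors
  if (length(cur) > rfe_target) {
    cur <- recursive_elimination(X[, cur, drop = FALSE], y, rfe_target)
  }
  stages$rfe <- cur
  if (length(cur) > mrmr_target) {
    cur <- mrmr_select(X[, cur, drop = FALSE], y, mrmr_target)$survivors
  }
  stages$mrmr <- cur
  las <- lasso_select(X[, cur, drop = FALSE], y, cv_folds = cv_folds,
                      seed = seed)
  stages$lasso <- las$survivors
  final <- if (las$no_signal) cur else las$survivors
  structure(list(stages = stages, final = final, lasso = las,
                 p_values = st1$p_values, dropped_corr = st2$dropped,
                 no_signal = las$no_signal),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %d features\n", nm, length(x$stages[[nm]])))
  cat(sprintf("  final        %d features%s\n", length(x$final),
              if (isTRUE(x$no_signal)) " (no-signal fallback)" else ""))
  invisible(x)
}
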