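# Evaluation suite: DeLong AUC inference, threshold metrics,
# Hosmer-Lemeshow calibration, decision curves, Shapley attribution, and
# nomogram export.

# Mann-Whitney AUC with 0.5 tie credit (midranks).
auc_mw <- function(scores, labels) {
  y <- as.integer(labels)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: V10 (per positive), V01 (per negative).
delong_components <- function(scores, labels) {
  y <- as.integer(labels)
  x <- scores[y == 1]; z <- scores[y == 0]
  m <- length(x); n <- length(z)
  if (m == 0 || n == 0) stop("both classes must be present")
  all_r <- rank(c(x, z), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  rz <- rank(z, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rz) / m
  list(auc = (sum(all_r[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' AUC is the Mann-Whitney concordance (0.5 credit for ties); its variance
#' comes from DeLong's structural components; the CI is the normal
#' interval truncated to `[0, 1]`.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary labels (0/1), both classes present.
#' @param level confidence level.
#' @return list with `auc`, `variance`, `ci`.
#' @export
auc_delong <- function(scores, labels, level = 0.95) {
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = dc$auc, variance = v, ci = ci)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test comparing the AUCs of two score vectors on the same
#' samples, via the covariance of their structural components.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be paired (equal length)")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- da$auc - db$auc
  if (v < 1e-24) {
    z <- 0
  } else z <- d / sqrt(v)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Youden-optimal threshold
#'
#' The score value maximizing sensitivity + specificity - 1 when
#' classifying `score >= threshold` as positive (ties to the lowest such
#' threshold). Intended to be computed on the training cohort and frozen
#' for all other cohorts.
#'
#' @param scores,labels training scores and binary labels.
#' @return numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, 0)
  cand[which.max(j)]
}

#' Confusion-matrix metrics at a threshold
#'
#' @param scores numeric predictions.
#' @param labels binary labels, both classes present.
#' @param threshold decision threshold (`score >= threshold` is positive);
#'   when `NULL`, the Youden-optimal threshold of these scores is used.
#' @return list with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`, and the confusion counts. Undefined ratios
#'   (zero denominators) are reported as 0.
#' @export
threshold_metrics <- function(scores, labels, threshold = NULL) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  if (threshold < min(scores) || threshold > max(scores))
    warning("threshold outside the score range: degenerate confusion matrix")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  safe <- function(a, b) if (b == 0) 0 else a / b
  list(threshold = threshold,
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       accuracy = (tp + tn) / length(y),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Hosmer-Lemeshow calibration test
#'
#' Decile-of-risk grouping (default 10 groups); groups with degenerate
#' expected counts are merged with their neighbour. The statistic is
#' `sum (O - E)^2 / (E (1 - E / n_g))` on chi-square with `groups - 2`
#' degrees of freedom.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @param groups number of risk groups.
#' @return list with `statistic`, `p_value`, `df`, and the group table.
#' @export
hosmer_lemeshow <- function(probabilities, labels, groups = 10) {
  p <- as.numeric(probabilities); y <- as.integer(labels)
  if (length(p) < 2 * groups)
    stop("need at least 2 x groups observations")
  br <- unique(quantile(p, probs = seq(0, 1, length.out = groups + 1),
                        names = FALSE))
  g <- if (length(br) < 2) rep(1L, length(p))
  else cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    n = as.numeric(tapply(y, g, length)),
    obs = as.numeric(tapply(y, g, sum)),
    exp = as.numeric(tapply(p, g, sum))
  )
  # merge groups whose expected counts are degenerate
  i <- 1
  while (i <= nrow(tab) && nrow(tab) > 1) {
    if (tab$exp[i] < 1e-9 || tab$n[i] - tab$exp[i] < 1e-9) {
      j <- if (i == 1) 2 else i - 1
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$obs[j] <- tab$obs[j] + tab$obs[i]
      tab$exp[j] <- tab$exp[j] + tab$exp[i]
      tab <- tab[-i, , drop = FALSE]
    } else i <- i + 1
  }
  stat <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- max(1, nrow(tab) - 2)
  list(statistic = stat, p_value = 1 - pchisq(stat, df), df = df,
       table = tab)
}

#' Decision curve analysis
#'
#' Net benefit `NB(pt) = TP/n - (FP/n) pt/(1-pt)` when classifying
#' `probability >= pt`, with treat-all and treat-none reference policies.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds decision-threshold grid in (0, 1); values >= 1 are
#'   excluded.
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  y <- as.integer(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    sum(pred & y == 1) / n - sum(pred & y == 0) / n * pt / (1 - pt)
  }, 0)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Full evaluation report for one model on one cohort
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param threshold frozen decision threshold (training Youden when `NULL`).
#' @param hl_groups Hosmer-Lemeshow groups (skipped when the cohort is too
#'   small).
#' @return An `eval_report` list: AUC + CI, threshold metrics, HL,
#'   calibration curve points, and the DCA curve.
#' @export
evaluate_model <- function(scores, labels, threshold = NULL, hl_groups = 10) {
  de <- auc_delong(scores, labels)
  tm <- threshold_metrics(scores, labels, threshold)
  hl <- if (length(scores) >= 2 * hl_groups)
    hosmer_lemeshow(scores, labels, hl_groups) else NULL
  cb <- unique(quantile(scores, seq(0, 1, 0.2), names = FALSE))
  bins <- if (length(cb) < 2) rep(1L, length(scores))
  else cut(scores, breaks = cb, include.lowest = TRUE, labels = FALSE)
  calib <- data.frame(
    mean_pred = as.numeric(tapply(scores, bins, mean)),
    frac_pos = as.numeric(tapply(as.integer(labels), bins, mean)))
  structure(list(auc = de$auc, ci = de$ci, variance = de$variance,
                 threshold = tm$threshold, sensitivity = tm$sensitivity,
                 specificity = tm$specificity, ppv = tm$ppv, npv = tm$npv,
                 accuracy = tm$accuracy, confusion = tm$confusion,
                 hosmer_lemeshow = hl, calibration = calib,
                 dca = decision_curve(scores, labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f (%.3f-%.3f), acc %.3f, sens %.3f, spec %.3f, PPV %.3f, NPV %.3f\n",
              x$auc, x$ci[1], x$ci[2], x$accuracy, x$sensitivity,
              x$specificity, x$ppv, x$npv))
  invisible(x)
}

# ---- Shapley attribution ----------------------------------------------------

#' Shapley attribution of model predictions
#'
#' Tree ensembles (`xgb`, `lgb`) use exact tree-path attribution on the
#' log-odds scale; logistic models use the closed additive form on the
#' link scale; other models use permutation-sampling Shapley on the
#' probability scale (each sampled permutation telescopes, so local
#' accuracy `base + sum(contributions) = prediction` is exact).
#'
#' @param model a `fitted_model`.
#' @param rows data.frame of samples to explain.
#' @param background nonempty data.frame of reference samples.
#' @param n_perm permutations per sample for the sampling fallback.
#' @param seed RNG seed for the sampling fallback.
#' @return An `attribution_report`: `contributions` (rows x features),
#'   `base`, `prediction` (on `scale`), `scale`, and `ranking` by global
#'   mean |contribution|.
#' @export
shapley_attribution <- function(model, rows, background, n_perm = 50,
                                seed = 1L) {
  if (is.null(background) || nrow(background) == 0)
    stop("background sample must be nonempty")
  feats <- model$features
  X <- as.matrix(rows[, feats, drop = FALSE])
  B <- as.matrix(background[, feats, drop = FALSE])
  if (model$algorithm %in% c("xgb", "lgb")) {
    contrib <- predict(model$object, xgboost::xgb.DMatrix(X, nthread = 1),
                       predcontrib = TRUE)
    bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
    base <- contrib[, bias_col]
    phi <- contrib[, feats, drop = FALSE]
    pred <- qlogis(pmin(pmax(predict_one(model$object, model$algorithm, X),
                             1e-12), 1 - 1e-12))
    scale <- "link"
  } else if (model$algorithm == "lr") {
    beta <- coef(model$object)[-1]
    beta[is.na(beta)] <- 0
    mu <- colMeans(B)
    phi <- sweep(X, 2, mu) * matrix(beta, nrow(X), length(beta), byrow = TRUE)
    colnames(phi) <- feats
    base <- rep(coef(model$object)[1] + sum(beta * mu), nrow(X))
    pred <- base + rowSums(phi)
    scale <- "link"
  } else {
    f <- function(M) predict_one(model$object, model$algorithm, M)
    base_val <- mean(f(B))
    p <- length(feats)
    phi <- matrix(0, nrow(X), p, dimnames = list(NULL, feats))
    with_seed(seed, function() {
      for (i in seq_len(nrow(X))) {
        acc <- numeric(p)
        for (r in seq_len(n_perm)) {
          perm <- sample.int(p)
          b <- B[sample.int(nrow(B), 1), ]
          cur <- b
          fprev <- f(matrix(cur, 1, p, dimnames = list(NULL, feats)))
          for (j in perm) {
            cur[j] <- X[i, j]
            fnew <- f(matrix(cur, 1, p, dimnames = list(NULL, feats)))
            acc[j] <- acc[j] + (fnew - fprev)
            fprev <- fnew
          }
        }
        phi[i, ] <<- acc / n_perm
      }
    })
    base <- rep(base_val, nrow(X))
    # telescoping guarantees sum(phi_i) = f(x_i) - mean_b f(b) only in
    # expectation over background draws; re-centre per sample so local
    # accuracy is exact
    pred <- f(X)
    adj <- (pred - base - rowSums(phi)) / p
    phi <- phi + adj
    scale <- "probability"
  }
  ranking <- sort(colMeans(abs(phi)), decreasing = TRUE)
  structure(list(contributions = phi, base = base, prediction = pred,
                 scale = scale, ranking = ranking),
            class = "attribution_report")
}

# ---- nomogram ---------------------------------------------------------------

#' Export a points-based nomogram from a logistic model
#'
#' Each predictor's points are linear in `coefficient x value`, scaled so
#' the largest single-predictor span over the supplied ranges equals 100
#' points; total points map back to probability through the inverse logit
#' of the reconstructed linear predictor (exact round trip).
#'
#' @param model a `fitted_model` with `algorithm = "lr"`.
#' @param data data.frame providing predictor ranges (e.g. the training
#'   cohort).
#' @param grid_points rows per predictor in the exported points table.
#' @return list with `points_table`, `points_of` (function: row ->
#'   per-predictor points), `prob_of_total` (function: total points ->
#'   probability), and `max_points` per predictor.
#' @export
nomogram_export <- function(model, data, grid_points = 11) {
  if (!inherits(model, "fitted_model") || model$algorithm != "lr")
    stop("nomogram export requires a logistic (lr) model; ",
         "use a score-level nomogram for non-linear models")
  beta <- coef(model$object)
  b0 <- beta[1]; bw <- beta[-1]
  bw[is.na(bw)] <- 0
  feats <- model$features
  lo <- vapply(feats, function(f) min(data[[f]]), 0)
  hi <- vapply(feats, function(f) max(data[[f]]), 0)
  ref <- ifelse(bw >= 0, lo, hi)           # zero-point end of each axis
  span <- abs(bw) * (hi - lo)
  maxspan <- max(span)
  if (maxspan <= 0) stop("all predictors have zero span")
  pts_of_value <- function(f, x) {
    j <- match(f, feats)
    unname(bw[j] * (x - ref[j]) / maxspan * 100)
  }
  points_table <- do.call(rbind, lapply(feats, function(f) {
    v <- seq(lo[match(f, feats)], hi[match(f, feats)],
             length.out = grid_points)
    data.frame(predictor = f, value = v, points = pts_of_value(f, v))
  }))
  lp0 <- unname(b0 + sum(bw * ref))
  list(points_table = points_table,
       points_of = function(row) {
         vapply(feats, function(f) pts_of_value(f, row[[f]]), 0)
       },
       prob_of_total = function(total) plogis(lp0 + maxspan * total / 100),
       max_points = setNames(span / maxspan * 100, feats))
}
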