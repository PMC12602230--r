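# Clinical covariate engineering (PNI/SIRI), cohort splitting, and
# univariable -> multivariable logistic modelling.

#' Derive the nutritional and inflammation indices
#'
#' PNI = serum albumin (g/L) + 5 x absolute lymphocyte count (10^9/L);
#' SIRI = neutrophils x monocytes / lymphocytes (all 10^9/L). With a
#' non-positive lymphocyte count SIRI is returned missing (flagged) while
#' PNI is still computed.
#'
#' @param row data.frame (or list) with `albumin`, `lymphocytes`,
#'   `neutrophils`, `monocytes`. Vectorized over rows.
#' @return list with `pni`, `siri`, and `siri_missing` flags.
#' @export
derive_indices <- function(row) {
  alb <- row$albumin; ly <- row$lymphocytes
  ne <- row$neutrophils; mo <- row$monocytes
  if (any(is.na(alb)) || any(is.na(ly)) || any(is.na(ne)) || any(is.na(mo)))
    stop("albumin, lymphocytes, neutrophils and monocytes must be present")
  pni <- alb + 5 * ly
  bad <- ly <= 0
  siri <- ifelse(bad, NA_real_, ne * mo / ly)
  list(pni = pni, siri = siri, siri_missing = bad)
}

#' Stratified cohort split
#'
#' Random split stratified on the response; the training side receives
#' `round(ratio * n_c)` members of each class c. Deterministic given the
#' seed.
#'
#' @param table data.frame with a `response` column.
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with `train` and `validation` data.frames.
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1L) {
  if (nrow(table) < 10) stop("need at least 10 rows to split")
  y <- table$response
  if (is.null(y)) stop("table must have a response column")
  # largest-remainder allocation: the training side has exactly
  # round(ratio * n) rows, distributed across classes in proportion
  classes <- unique(y)
  n_c <- vapply(classes, function(cl) sum(y == cl), 0L)
  want <- ratio * n_c
  take <- floor(want)
  left <- round(ratio * nrow(table)) - sum(take)
  if (left > 0) {
    ord <- order(want - take, decreasing = TRUE)
    take[ord[seq_len(left)]] <- take[ord[seq_len(left)]] + 1L
  }
  idx_tr <- with_seed(seed, function() {
    unlist(lapply(seq_along(classes), function(i) {
      sample(which(y == classes[i]), take[i])
    }))
  })
  idx_tr <- sort(idx_tr)
  train <- table[idx_tr, , drop = FALSE]
  valid <- table[-idx_tr, , drop = FALSE]
  if (length(unique(train$response)) < 2 || length(unique(valid$response)) < 2)
    stop("a class is absent from one side of the split")
  list(train = train, validation = valid)
}

# Wald OR summary for one fitted glm, skipping the intercept.
wald_or <- function(fit, level = 0.95) {
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    term = rownames(sm)[-1],
    or = exp(sm[-1, 1]),
    ci_low = exp(sm[-1, 1] - z * sm[-1, 2]),
    ci_high = exp(sm[-1, 1] + z * sm[-1, 2]),
    p_value = sm[-1, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Univariable and multivariable logistic analysis
#'
#' Fits one univariable logistic model per covariate (odds ratio, Wald 95%
#' CI, p-value); covariates with p < `alpha` plus any `forced_in` enter a
#' single multivariable fit. Complete-separation fits are flagged and
#' refit with a small ridge penalty.
#'
#' @param table data.frame with `response` and numeric or factor
#'   covariates.
#' @param covariates character vector of covariate names (default: all
#'   columns except `response`).
#' @param alpha inclusion threshold for the multivariable model.
#' @param forced_in covariates always kept in the multivariable model.
#' @return list with `univariable` and `multivariable` OR tables, the
#'   fitted multivariable model, and `selected` covariate names.
#' @export
uni_multi_logistic <- function(table, covariates = NULL, alpha = 0.05,
                               forced_in = character(0)) {
  if (is.null(covariates))
    covariates <- setdiff(names(table), c("response", "patient_id", "cohort"))
  y <- table$response
  if (is.null(y) || length(unique(y)) < 2)
    stop("binary response required")
  uni <- do.call(rbind, lapply(covariates, function(v) {
    f <- stats::as.formula(paste("response ~", v))
    fit <- suppressWarnings(glm(f, data = table, family = binomial()))
    out <- wald_or(fit)
    if (nrow(out) == 0) {  # constant covariate dropped by the fit
      out <- data.frame(term = v, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = 1,
                        stringsAsFactors = FALSE)
    }
    out$covariate <- v
    # covariate-level screening p from the likelihood-ratio test: Wald
    # p-values collapse toward 1 under (quasi-)separation (Hauck-Donner)
    out$p_lrt <- tryCatch(
      suppressWarnings(stats::anova(fit, test = "Chisq")[2, "Pr(>Chi)"]),
      error = function(e) out$p_value[1])
    out
  }))
  pv <- tapply(uni$p_lrt, uni$covariate, min)
  keep <- union(names(pv)[pv < alpha], forced_in)
  keep <- keep[keep %in% covariates]
  multi <- NULL; fit_m <- NULL; separation <- FALSE
  if (length(keep)) {
    f <- stats::as.formula(paste("response ~", paste(keep, collapse = " + ")))
    fit_m <- suppressWarnings(glm(f, data = table, family = binomial()))
    separation <- !fit_m$converged ||
      any(abs(coef(fit_m)[-1]) > 15, na.rm = TRUE) ||
      any(fit_m$fitted.values > 1 - 1e-8) ||
      any(fit_m$fitted.values < 1e-8)
    if (separation) {
      # penalized fallback: small ridge via glmnet keeps ORs finite
      mm <- stats::model.matrix(f, table)[, -1, drop = FALSE]
      mm2 <- if (ncol(mm) < 2) cbind(mm, `.pad` = 0) else mm  # glmnet needs >= 2 cols
      rf <- glmnet::glmnet(mm2, table$response, family = "binomial",
                           alpha = 0, lambda = 0.05)
      co <- as.numeric(coef(rf))[seq_len(ncol(mm) + 1)]
      multi <- data.frame(term = c("(ridge)", colnames(mm)),
                          or = exp(co), ci_low = NA, ci_high = NA,
                          p_value = NA, stringsAsFactors = FALSE)[-1, ]
      multi$covariate <- multi$term
    } else {
      multi <- wald_or(fit_m)
      multi$covariate <- multi$term
    }
  }
  list(univariable = uni, multivariable = multi, fit = fit_m,
       selected = keep, separation_flag = separation)
}
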