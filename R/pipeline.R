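# End-to-end orchestration: simulate -> preprocess -> habitat -> regions ->
# features -> selection -> models -> evaluation.

# Background "noise" control region: a sphere in normal-appearing tissue,
# far from the lesion, used to benchmark signatures against a region that
# carries no outcome signal by construction.
noise_region_mask <- function(mask, radius_mm = 4, inset_mm = 6) {
  d <- dim(mask$values)
  sp <- mask$spacing
  ctr <- inset_mm / sp + 1
  cx <- (seq_len(d[1]) - ctr[1]) * sp[1]
  cy <- (seq_len(d[2]) - ctr[2]) * sp[2]
  cz <- (seq_len(d[3]) - ctr[3]) * sp[3]
  E <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  out <- array(as.integer(E <= radius_mm^2), d)
  out[mask$values != 0L] <- 0L
  hb_mask(out, sp, mask$origin)
}

#' Preprocess one synthetic patient
#'
#' Bias-field correction followed by isotropic resampling of image, mask
#' and truth labels to the target grid.
#'
#' @param patient one element of `generate_cohort()$patients`.
#' @param target_mm isotropic target spacing.
#' @param correct_bias_field logical; skip to study the uncorrected path.
#' @param normalize_intensity inter-patient intensity standardization
#'   applied after bias correction (MR units are arbitrary and a
#'   patient-level multiplicative gain is unidentifiable from a single
#'   image): `"none"` (default), `"tissue"` (calibrate so the median
#'   normal-appearing background — beyond the peritumoral halo — maps to a
#'   fixed reference, leaving lesion contrast untouched), `"scale"`
#'   (rescale so the mean lesion intensity is 100), or `"zscore"`
#'   (centre/scale by lesion mean/SD).
#' @param halo_clearance_mm distance beyond which background voxels are
#'   treated as normal tissue for `"tissue"` calibration.
#' @return list with resampled `volume`, `mask`, `truth`, and the
#'   estimated `bias_field`.
#' @export
preprocess_patient <- function(patient, target_mm = 1.0,
                               correct_bias_field = TRUE,
                               normalize_intensity = c("none", "tissue",
                                                       "scale", "zscore"),
                               halo_clearance_mm = 6) {
  normalize_intensity <- match.arg(normalize_intensity)
  vol <- patient$volume
  bf <- NULL
  if (correct_bias_field) {
    cb <- correct_bias(vol, patient$mask, positivity = "shift")
    vol <- cb$corrected
    bf <- cb$bias_field
  }
  rs <- resample_isotropic(vol, patient$mask, target_mm)
  tr <- resample_isotropic(patient$volume, patient$truth_labels, target_mm)
  vol <- rs$volume
  inm <- vol$values[rs$mask$values != 0L]
  if (normalize_intensity == "tissue") {
    d <- dim(vol$values)
    dist_mm <- sqrt(cpp_edt_sq(as.integer(rs$mask$values != 0L), d,
                               vol$spacing))
    ref <- vol$values[dist_mm > halo_clearance_mm]
    if (!length(ref)) ref <- vol$values[rs$mask$values == 0L]
    vol <- hb_volume(vol$values * 40 / stats::median(ref), vol$spacing,
                     vol$origin)
  } else if (normalize_intensity == "scale") {
    vol <- hb_volume(vol$values * 100 / mean(inm), vol$spacing, vol$origin)
  } else if (normalize_intensity == "zscore") {
    vol <- hb_volume((vol$values - mean(inm)) / max(sd(inm), 1e-12),
                     vol$spacing, vol$origin)
  }
  list(volume = vol, mask = rs$mask, truth = tr$mask, bias_field = bf)
}

#' Run the full habitat-peritumoral pipeline on a synthetic cohort
#'
#' Preprocesses every patient, discovers habitats on the training cohort
#' (pooled voxel features, K-means at `k` or validity-index-selected),
#' builds tumor/ring/habitat regions, extracts the radiomic feature bank,
#' runs the selection cascade per signature, trains one model per
#' signature plus the clinical and combined models, and evaluates every
#' model on the training and validation cohorts.
#'
#' @param cohort result of [generate_cohort()].
#' @param k habitat count; `NULL` selects it via [select_k()].
#' @param radii peritumoral ring radii in mm.
#' @param algorithm classifier for the signature models.
#' @param feature_cfg a [feature_config()].
#' @param voxels_per_patient pooled-voxel subsample per patient for
#'   clustering.
#' @param include_noise_region add a background control-region signature.
#' @param split_ratio,seed cohort split controls.
#' @return A `pipeline_result` list (tables, models, reports, habitat
#'   model, selection reports).
#' @export
run_pipeline <- function(cohort, k = 3, radii = c(1, 2, 3),
                         algorithm = "xgb",
                         feature_cfg = feature_config(),
                         voxels_per_patient = 2000,
                         include_noise_region = FALSE,
                         split_ratio = 0.7, seed = 1L) {
  n <- length(cohort$patients)
  clin <- cohort$clinical

  # --- preprocess + local features -----------------------------------------
  # tissue calibration: pooled habitat clustering needs intensities on a
  # common patient-level scale (MR units are arbitrary); normal-appearing
  # background anchors the gain without touching lesion contrast
  prep <- lapply(cohort$patients, preprocess_patient,
                 normalize_intensity = "tissue")
  maps <- lapply(prep, function(p) local_features(p$volume, p$mask))

  # --- cohort split (patients) ---------------------------------------------
  split <- split_cohort(clin, ratio = split_ratio, seed = seed)
  tr_idx <- match(split$train$patient_id, clin$patient_id)
  va_idx <- match(split$validation$patient_id, clin$patient_id)

  # --- habitat discovery on training voxels --------------------------------
  pooled <- pool_voxel_features(maps[tr_idx], voxels_per_patient, seed)
  mu <- colMeans(pooled); sdv <- apply(pooled, 2, sd)
  if (is.null(k)) {
    ps <- sweep(sweep(pooled, 2, mu), 2, pmax(sdv, 1e-12), "/")
    k <- select_k(ps, n_seeds = 10, seed = seed)$k
  }
  hmodel <- fit_habitats(pooled, k, n_seeds = 10, seed = seed)

  # --- regions + feature extraction ----------------------------------------
  region_names <- c("tumor", paste0("peri", radii, "mm"),
                    if (include_noise_region) "noise")
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prep[[i]]
    hl <- assign_habitats(hmodel, maps[[i]])
    rs <- build_region_set(p$mask, hl, radii)
    bank <- filter_bank(p$volume, feature_cfg)
    per_region <- list(tumor = extract_region_features(bank, p$mask, feature_cfg))
    for (rn in names(rs$rings))
      per_region[[rn]] <- extract_region_features(bank, rs$rings[[rn]],
                                                  feature_cfg)
    if (include_noise_region)
      per_region$noise <- extract_region_features(
        bank, noise_region_mask(p$mask), feature_cfg)
    hvecs <- lapply(seq_len(k), function(h) {
      hm <- rs$habitats[[paste0("habitat", h)]]
      if (is.null(hm)) NULL else extract_region_features(bank, hm, feature_cfg)
    })
    per_region$habitat <- fuse_habitat_features(hvecs, k)
    feats[[i]] <- per_region
  }

  # assemble per-signature tables (finite features only)
  signatures <- c(region_names, "habitat")
  tables <- lapply(signatures, function(sg) {
    M <- do.call(rbind, lapply(feats, function(f) f[[sg]]))
    M[!is.finite(M)] <- NA
    ok <- colSums(is.na(M)) == 0
    df <- as.data.frame(M[, ok, drop = FALSE])
    names(df) <- paste0(sg, "__", colnames(M)[ok])
    df$response <- clin$response
    df$patient_id <- clin$patient_id
    df
  })
  names(tables) <- signatures

  # --- selection + models per signature ------------------------------------
  sel <- list(); models <- list(); preds <- list()
  for (sg in signatures) {
    tab <- tables[[sg]]
    fcols <- setdiff(names(tab), c("response", "patient_id"))
    rep_sg <- run_selection(as.matrix(tab[tr_idx, fcols]),
                            clin$response[tr_idx], seed = seed)
    sel[[sg]] <- rep_sg
    if (!length(rep_sg$final)) next
    models[[sg]] <- train_model(tab[tr_idx, ], rep_sg$final, algorithm,
                                seed = seed)
    preds[[sg]] <- list(train = predict(models[[sg]], tab[tr_idx, ]),
                        validation = predict(models[[sg]], tab[va_idx, ]))
  }

  # --- clinical model -------------------------------------------------------
  clin_covs <- c("age", "gender_male", "smoking", "ici_line_gt2",
                 "ici_anti_pdl1", "chemo_combo", "ecog_ge2", "pdl1_gt50",
                 "n_met_sites", "multiple_bm", "t_stage_34", "n_stage_34",
                 "m_stage_34", "rbc", "wbc", "platelets", "ldh", "cea",
                 "ca125", "ca199", "pni", "siri")
  um <- uni_multi_logistic(split$train, covariates = clin_covs,
                           forced_in = "gender_male")
  models$clinical <- train_model(split$train, um$selected, "lr", seed = seed)
  preds$clinical <- list(train = predict(models$clinical, split$train),
                         validation = predict(models$clinical, split$validation))

  # --- combined model: habitat + peri-1mm survivors + clinical predictors ---
  peri1 <- paste0("peri", radii[1], "mm")
  comb_feats <- c(sel$habitat$final,
                  if (!is.null(sel[[peri1]])) sel[[peri1]]$final,
                  um$selected)
  comb_tab <- cbind(tables$habitat[, sel$habitat$final, drop = FALSE],
                    if (!is.null(sel[[peri1]]) && length(sel[[peri1]]$final))
                      tables[[peri1]][, sel[[peri1]]$final, drop = FALSE],
                    clin[, um$selected, drop = FALSE])
  comb_tab$response <- clin$response
  models$combined <- train_model(comb_tab[tr_idx, ], comb_feats, algorithm,
                                 seed = seed)
  preds$combined <- list(train = predict(models$combined, comb_tab[tr_idx, ]),
                         validation = predict(models$combined, comb_tab[va_idx, ]))

  # --- evaluation -----------------------------------------------------------
  reports <- list(); summary_rows <- list()
  for (m in names(preds)) {
    thr <- youden_threshold(preds[[m]]$train, clin$response[tr_idx])
    for (co in c("train", "validation")) {
      y <- clin$response[if (co == "train") tr_idx else va_idx]
      rp <- evaluate_model(preds[[m]][[co]], y, threshold = thr,
                           hl_groups = 5)
      reports[[paste(m, co, sep = ".")]] <- rp
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        cohort = co, signature = m, accuracy = rp$accuracy, auc = rp$auc,
        ci_low = rp$ci[1], ci_high = rp$ci[2],
        sensitivity = rp$sensitivity, specificity = rp$specificity,
        ppv = rp$ppv, npv = rp$npv)
    }
  }
  structure(list(tables = tables, combined_table = comb_tab,
                 habitat_model = hmodel, selection = sel,
                 clinical_analysis = um, models = models,
                 predictions = preds, reports = reports,
                 summary = do.call(rbind, summary_rows),
                 train_idx = tr_idx, validation_idx = va_idx,
                 k = k, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Serialize a habitat model to JSON
#' @param model a `habitat_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_habitat_model <- function(model, path) {
  jsonlite::write_json(list(k = model$k, centers = model$centers,
                            scaler = model$scaler, inertia = model$inertia,
                            consistency = model$consistency,
                            seeds_used = model$seeds_used),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a habitat model from JSON
#' @param path path written by [write_habitat_model()].
#' @return A `habitat_model`.
#' @export
read_habitat_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = j$k, centers = as.matrix(j$centers),
                 scaler = list(mean = setNames(as.numeric(j$scaler$mean),
                                               j$scaler$channels),
                               sd = setNames(as.numeric(j$scaler$sd),
                                             j$scaler$channels),
                               channels = j$scaler$channels),
                 inertia = j$inertia, consistency = j$consistency,
                 seeds_used = j$seeds_used),
            class = "habitat_model")
}
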