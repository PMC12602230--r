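# Synthetic cohort generator: 3D lesions with latent phenotype subregions,
# a peritumoral halo, multiplicative bias fields, anisotropic native spacing,
# and a clinical table whose response follows a documented logistic model.

# Evaluate fn under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specify a lesion phenotype (latent habitat)
#'
#' @param id small integer identifier.
#' @param intensity_mean,intensity_sd marginal intensity distribution
#'   (arbitrary MR units); `intensity_sd` must be positive.
#' @param texture_granularity correlation length in mm of the smoothed-noise
#'   texture realized inside the phenotype.
#' @param volume_fraction expected fraction of lesion volume in `[0, 1]`.
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(id, intensity_mean, intensity_sd,
                           texture_granularity, volume_fraction) {
  if (intensity_sd <= 0) stop("intensity_sd must be > 0")
  if (volume_fraction < 0 || volume_fraction > 1)
    stop("volume_fraction must lie in [0, 1]")
  structure(list(id = as.integer(id), intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 texture_granularity = texture_granularity,
                 volume_fraction = volume_fraction),
            class = "phenotype_spec")
}

#' Default three-phenotype mixture
#'
#' Three phenotypes with well-separated intensity means (4.5 SD apart),
#' distinct texture correlation lengths, and expected volume fractions
#' (0.5, 0.3, 0.2).
#' @return list of [phenotype_spec()].
#' @export
default_phenotypes <- function() {
  list(
    phenotype_spec(1L, 100, 10, 0.8, 0.5),
    phenotype_spec(2L, 145, 10, 1.6, 0.3),
    phenotype_spec(3L, 190, 10, 2.5, 0.2)
  )
}

#' Configure a synthetic cohort
#'
#' @param n_patients number of patients (>= 2).
#' @param phenotypes list of [phenotype_spec()]; volume fractions must sum
#'   to 1.
#' @param native_spacing native voxel spacing in mm, anisotropic by default
#'   (0.9 x 0.9 x 3.0) to exercise isotropic resampling.
#' @param bias_amplitude relative amplitude of the multiplicative
#'   low-frequency bias field (0.2 = +/-20 percent).
#' @param halo_width_mm e-folding width of the peritumoral intensity
#'   gradient outside the lesion.
#' @param halo_amplitude peak added intensity of the halo at the margin.
#' @param diameter_range_mm lesion diameter range (uniform draw).
#' @param fraction_concentration Dirichlet concentration of the per-patient
#'   volume-fraction jitter around the phenotype means.
#' @param blend_sigma_mm width of the gradual intensity transition between
#'   phenotype subregions (smoothed-indicator blending); 0 gives step
#'   edges.
#' @param contrast_sd SD of the per-patient intensity-contrast shift added
#'   to phenotype 2's mean (arbitrary MR units); the imaging effect that
#'   habitat-level first-order features measure directly.
#' @param clinical_effects named log-odds coefficients of the response
#'   model. The name `habitat2_vf` refers to the per-patient volume fraction
#'   of phenotype 2 (centred at its expectation), `habitat2_contrast` to the
#'   per-patient contrast shift; other names refer to columns of the
#'   clinical table (centred at the cohort mean).
#' @param response_prevalence target response fraction in (0, 1); the model
#'   intercept is solved so the mean response probability equals it.
#' @param seed RNG seed; identical configs give byte-identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 60,
                          phenotypes = default_phenotypes(),
                          native_spacing = c(0.9, 0.9, 3.0),
                          bias_amplitude = 0.2,
                          halo_width_mm = 3,
                          halo_amplitude = 30,
                          diameter_range_mm = c(8, 30),
                          fraction_concentration = 20,
                          blend_sigma_mm = 0.5,
                          contrast_sd = 8,
                          clinical_effects = c(habitat2_vf = 8,
                                               habitat2_contrast = 0.12,
                                               gender_male = -0.8,
                                               pni = 0.08),
                          response_prevalence = 0.45,
                          seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (length(phenotypes) < 1) stop("need at least one phenotype")
  fr <- vapply(phenotypes, function(p) p$volume_fraction, 0)
  if (abs(sum(fr) - 1) > 1e-9) stop("phenotype volume fractions must sum to 1")
  if (any(native_spacing <= 0)) stop("native_spacing must be positive")
  if (response_prevalence <= 0 || response_prevalence >= 1)
    stop("response_prevalence must lie in (0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 n_phenotypes = length(phenotypes),
                 phenotypes = phenotypes,
                 native_spacing = as.numeric(native_spacing),
                 bias_amplitude = bias_amplitude,
                 halo_width_mm = halo_width_mm,
                 halo_amplitude = halo_amplitude,
                 diameter_range_mm = diameter_range_mm,
                 fraction_concentration = fraction_concentration,
                 blend_sigma_mm = blend_sigma_mm,
                 contrast_sd = contrast_sd,
                 clinical_effects = clinical_effects,
                 response_prevalence = response_prevalence,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) stats::rgamma(1, shape = a, rate = 1), 0)
  if (sum(g) <= 0) return(alpha / sum(alpha))
  g / sum(g)
}

# Generate one lesion image/mask/truth triplet on its own native grid.
# `contrast` shifts phenotype 2's mean intensity for this patient.
generate_patient_image <- function(config, vf, contrast = 0) {
  sp <- config$native_spacing
  diam <- runif(1, config$diameter_range_mm[1], config$diameter_range_mm[2])
  margin <- config$halo_width_mm + 5
  box <- diam + 2 * margin
  d <- pmax(5L, as.integer(ceiling(box / sp)))
  # physical voxel-centre coordinates
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  ax <- diam / 2 * runif(3, 0.8, 1.2)    # ellipsoid semi-axes
  E <- outer(outer((cx / ax[1])^2, (cy / ax[2])^2, "+"), (cz / ax[3])^2, "+")
  mask <- array(as.integer(E <= 1), dim = d)
  if (sum(mask) < 8) {  # guard tiny lesions on coarse slices
    mask[d[1] %/% 2 + (-1:0), d[2] %/% 2 + (-1:0), d[3] %/% 2 + (-1:0)] <- 1L
  }
  vox <- which(mask == 1L)
  n <- length(vox)
  coords <- cbind(cx[(vox - 1) %% d[1] + 1],
                  cy[((vox - 1) %/% d[1]) %% d[2] + 1],
                  cz[(vox - 1) %/% (d[1] * d[2]) + 1])

  # partition into compact phenotype subregions: multiplicatively weighted
  # Voronoi cells around random seeds, weights iterated so realized volume
  # fractions approach vf
  k <- config$n_phenotypes
  for (attempt in 1:5) {
    # farthest-point seeds give well-separated compact cells
    seed_idx <- sample.int(n, 1)
    if (k > 1) {
      dmin <- sqrt(rowSums((coords - matrix(coords[seed_idx, ], n, 3,
                                            byrow = TRUE))^2))
      for (j in 2:k) {
        seed_idx <- c(seed_idx, which.max(dmin))
        dj <- sqrt(rowSums((coords - matrix(coords[seed_idx[j], ], n, 3,
                                            byrow = TRUE))^2))
        dmin <- pmin(dmin, dj)
      }
    }
    D <- vapply(seq_len(k), function(j) {
      sqrt(rowSums((coords - matrix(coords[seed_idx[j], ], n, 3,
                                    byrow = TRUE))^2))
    }, numeric(n))
    w <- rep(1, k)
    for (it in 1:60) {
      truth <- max.col(-sweep(D, 2, w, "/"), ties.method = "first")
      cur <- tabulate(truth, k) / n
      w <- w * (pmax(vf, 1e-3) / pmax(cur, 1e-3))^0.2
      w <- w / exp(mean(log(w)))   # keep the scale bounded
    }
    truth <- max.col(-sweep(D, 2, w, "/"), ties.method = "first")
    if (max(abs(tabulate(truth, k) / n - vf)) < 0.1) break
  }

  # tissue signal: background + per-phenotype smoothed-noise texture.
  # Phenotype signals blend gradually at subregion interfaces (smoothed
  # indicator weights, ~2 mm transition) the way real habitats grade into
  # one another rather than meeting at step edges.
  blend_sigma <- config$blend_sigma_mm
  tissue <- 40 + 5 * array(rnorm(prod(d)), dim = d)
  A <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ind <- array(0, dim = d)
    ind[vox[truth == j]] <- 1
    A[, j] <- gaussian_smooth(ind, sp, blend_sigma)[vox]
  }
  A <- pmax(A, 0)
  A <- A / pmax(rowSums(A), 1e-12)
  mix <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ph <- config$phenotypes[[j]]
    fld <- gaussian_smooth(array(rnorm(prod(d)), dim = d), sp,
                           ph$texture_granularity)
    fld <- fld / max(sd(fld), 1e-12)
    shift <- if (j == 2) contrast else 0
    mix[, j] <- ph$intensity_mean + shift + ph$intensity_sd * fld[vox]
  }
  tissue[vox] <- rowSums(A * mix)

  # peritumoral halo: intensity gradient decaying with distance to lesion
  dist_mm <- sqrt(cpp_edt_sq(as.integer(mask), d, sp))
  outside <- mask == 0L
  halo <- array(0, dim = d)
  halo[outside] <- config$halo_amplitude *
    exp(-dist_mm[outside] / config$halo_width_mm)

  # multiplicative low-frequency bias field (unit mean, bounded amplitude)
  bias <- gaussian_smooth(array(rnorm(prod(d)), dim = d), sp, 20)
  bias <- 1 + config$bias_amplitude * bias / max(abs(bias))

  img <- tissue * bias + halo
  truth_arr <- array(0L, dim = d)
  truth_arr[vox] <- truth

  list(volume = hb_volume(img, sp),
       mask = hb_mask(mask, sp),
       truth_labels = hb_mask(truth_arr, sp),
       bias_field = hb_volume(bias, sp),
       vf_realized = as.numeric(table(factor(truth, levels = seq_len(k)))) / n)
}

# Clinical covariates matching the published cohort summaries.
generate_clinical_row <- function() {
  lymph <- rlnorm(1, log(1.6), 0.35)
  data.frame(
    age = round(rnorm(1, 64, 8), 1),
    gender_male = rbinom(1, 1, 0.67),
    smoking = rbinom(1, 1, 0.5),
    ici_line_gt2 = rbinom(1, 1, 0.25),
    ici_anti_pdl1 = rbinom(1, 1, 0.1),
    chemo_combo = rbinom(1, 1, 0.88),
    ecog_ge2 = rbinom(1, 1, 0.5),
    pathology = sample(c("adeno", "squamous", "other"), 1,
                       prob = c(0.73, 0.18, 0.09)),
    pdl1_gt50 = rbinom(1, 1, 0.15),
    n_met_sites = rpois(1, 1.7),
    multiple_bm = rbinom(1, 1, 0.33),
    t_stage_34 = rbinom(1, 1, 0.64),
    n_stage_34 = rbinom(1, 1, 0.36),
    m_stage_34 = rbinom(1, 1, 0.88),
    rbc = round(rnorm(1, 4.3, 0.6), 2),
    wbc = round(rlnorm(1, log(6.6), 0.3), 2),
    platelets = round(rnorm(1, 245, 94)),
    ldh = round(rlnorm(1, log(220), 0.35), 1),
    cea = round(rlnorm(1, log(8), 1.2), 2),
    ca125 = round(rlnorm(1, log(25), 1.0), 2),
    ca199 = round(rlnorm(1, log(15), 0.9), 2),
    albumin = round(rnorm(1, 40, 4), 1),
    lymphocytes = round(lymph, 2),
    neutrophils = round(rlnorm(1, log(4.2), 0.35), 2),
    monocytes = round(rlnorm(1, log(0.55), 0.3), 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic patient cohort
#'
#' Produces, per patient, a 3D contrast-like volume with a lesion composed of
#' latent phenotype subregions, the binary lesion mask, the generating truth
#' labels, the true bias field, a clinical covariate row (with PNI/SIRI), and
#' a binary response drawn from a logistic model over the phenotype-2 volume
#' fraction and the configured clinical effects.
#'
#' @param config a [cohort_config()].
#' @return list with `patients` (list of per-patient lists), `clinical`
#'   (data.frame with `response` and derived indices), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, function() {
    base_fr <- vapply(config$phenotypes, function(p) p$volume_fraction, 0)
    patients <- vector("list", config$n_patients)
    clin <- NULL
    vf2 <- numeric(config$n_patients)
    contrast <- numeric(config$n_patients)
    for (i in seq_len(config$n_patients)) {
      vf <- if (config$n_phenotypes == 1) 1 else
        rdirichlet1(base_fr * config$fraction_concentration)
      contrast[i] <- if (config$n_phenotypes >= 2)
        rnorm(1, 0, config$contrast_sd) else 0
      p <- generate_patient_image(config, vf, contrast[i])
      row <- generate_clinical_row()
      idx <- derive_indices(row)
      row$pni <- idx$pni
      row$siri <- idx$siri
      vf2[i] <- if (config$n_phenotypes >= 2) p$vf_realized[2] else 0
      p$clinical_row <- row
      patients[[i]] <- p
      clin <- rbind(clin, row)
    }
    clin$habitat2_vf <- vf2
    clin$habitat2_contrast <- contrast

    # linear predictor without intercept, each effect centred
    eff <- config$clinical_effects
    lp <- rep(0, config$n_patients)
    for (nm in names(eff)) {
      x <- if (nm == "habitat2_vf") vf2 - base_fr[min(2, length(base_fr))]
      else if (nm == "habitat2_contrast") contrast
      else {
        if (!nm %in% names(clin)) stop("unknown clinical effect: ", nm)
        clin[[nm]] - mean(clin[[nm]])
      }
      lp <- lp + eff[[nm]] * x
    }
    # intercept solved so mean response probability hits the target prevalence
    b0 <- uniroot(function(b) mean(plogis(b + lp)) - config$response_prevalence,
                  c(-20, 20))$root
    pr <- plogis(b0 + lp)
    resp <- rbinom(config$n_patients, 1, pr)
    clin$response <- resp
    clin$patient_id <- sprintf("P%03d", seq_len(config$n_patients))
    for (i in seq_len(config$n_patients)) {
      patients[[i]]$response <- resp[i]
      patients[[i]]$patient_id <- clin$patient_id[i]
    }
    list(patients = patients, clinical = clin, config = config,
         intercept = b0, probabilities = pr)
  })
}

#' Perturb a mask as a simulated second rater
#'
#' Adds a smooth random field to the signed distance of the boundary so the
#' contour is locally eroded or dilated by up to about `perturb_mm`.
#'
#' @param mask a nonempty binary [hb_mask()].
#' @param perturb_mm maximum boundary displacement in mm (>= 0); 0 returns
#'   an identical mask.
#' @param seed RNG seed.
#' @return A perturbed [hb_mask()].
#' @export
generate_second_rater_mask <- function(mask, perturb_mm, seed = 1L) {
  if (perturb_mm < 0) stop("perturb_mm must be >= 0")
  if (mask_count(mask) == 0) stop("mask is empty")
  if (perturb_mm == 0) return(mask)
  with_seed(seed, function() {
    d <- dim(mask$values)
    m <- as.integer(mask$values != 0L)
    dist_out <- sqrt(cpp_edt_sq(m, d, mask$spacing))
    dist_in <- sqrt(cpp_edt_sq(1L - m, d, mask$spacing))
    signed <- dist_out - dist_in            # negative inside
    eta <- gaussian_smooth(array(rnorm(prod(d)), dim = d), mask$spacing, 3)
    eta <- perturb_mm * eta / max(sd(eta), 1e-12)
    out <- array(as.integer(signed + eta <= 0), dim = d)
    hb_mask(out, mask$spacing, mask$origin)
  })
}

#' Dice overlap between two binary masks
#' @param a,b aligned binary [hb_mask()] objects.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_aligned(a, b)
  x <- a$values != 0L; y <- b$values != 0L
  2 * sum(x & y) / (sum(x) + sum(y))
}

#' Write a synthetic patient to NIfTI
#'
#' Writes the volume, mask, and truth-label triplet for one patient.
#' @param patient one element of `generate_cohort()$patients`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_patient <- function(patient, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- patient$patient_id
  write_volume(patient$volume, file.path(dir, paste0(id, "_image.nii.gz")))
  write_volume(patient$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
  write_volume(patient$truth_labels, file.path(dir, paste0(id, "_truth.nii.gz")))
  invisible(dir)
}

#' Write a cohort to disk (NIfTI triplets + clinical CSV + manifest)
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) write_patient(p, dir)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$phenotypes <- lapply(cfg$phenotypes, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
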