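# Synthetic two-center 3D breast phantoms.
#
# Geometry (axis convention: x = left-right, y = anterior-posterior with low
# y anterior, z = inferior-superior):
#   * two anterior gland half-ellipsoids that overlap at the midline so the
#     gland region is a single connected component;
#   * a posterior midline "heart" sphere whose intensity is deliberately
#     close to lesion intensity -- the confounder the gland-first cascade
#     exists to exclude;
#   * one or more lesions, each a union of 1-3 overlapping spherelets, fully
#     contained in the gland.
# Two simulated centers differ by a multiplicative gain and additive offset,
# giving a genuine cross-center intensity shift for harmonization to remove.

#' Specification of the synthetic breast phantom generator
#'
#' Defaults are the package's reference study conditions: a 64^3 grid at
#' 1 mm isotropic spacing; background/gland/lesion/heart mean intensities
#' 50/120/220/210 on an 8-bit-like scale with tissue-level SD 15 and voxel
#' noise SD 10, so lesion and heart are confusable (their means differ by
#' less than one tissue SD) while gland and background separate cleanly;
#' center 2 applies gain 1.25 and offset +30, a shift large enough that the
#' two centers' gland-intensity distributions differ by a two-sample KS
#' distance well above 0.2.
#'
#' @param volume_shape Integer length-3 grid shape in voxels.
#' @param spacing Voxel size in mm per axis.
#' @param gland_axes Length-2 range (mm) for gland ellipsoid semi-axes.
#' @param lesion_count_range Integer length-2 range for the number of
#'   lesions; the default `c(1, 1)` matches a solid-single-tumor cohort.
#' @param lesion_radius_range Length-2 range (mm) of lesion spherelet radii.
#' @param heart_radius_range Length-2 range (mm) of the heart sphere radius.
#' @param intensity_means Named means for `background`, `gland`, `lesion`,
#'   `heart`.
#' @param intensity_sd Tissue-level SD: each phantom draws a common
#'   brightness shift `N(0, intensity_sd)` applied to all tissues plus
#'   independent per-tissue jitter `N(0, intensity_sd/5)` (so the
#'   lesion/heart confound survives the jitter).
#' @param noise_sd Voxelwise additive Gaussian noise SD.
#' @param center_gain,center_offset Per-center multiplicative gain and
#'   additive intensity offset (length = number of simulated centers).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         gland_axes = c(12, 16),
                         lesion_count_range = c(1, 1),
                         lesion_radius_range = c(4, 7),
                         heart_radius_range = c(8, 11),
                         intensity_means = c(background = 50, gland = 120,
                                             lesion = 220, heart = 210),
                         intensity_sd = 15,
                         noise_sd = 10,
                         center_gain = c(1, 1.25),
                         center_offset = c(0, 30)) {
  assert_that(length(volume_shape) == 3 && all(volume_shape >= 16),
              "`volume_shape` must be 3 integers >= 16")
  assert_that(abs(intensity_means[["lesion"]] - intensity_means[["heart"]]) <
                intensity_sd,
              "lesion and heart means must differ by less than one tissue SD (the confound)")
  assert_that(length(center_gain) == length(center_offset),
              "center_gain and center_offset must have equal length")
  structure(
    list(volume_shape = as.integer(volume_shape), spacing = as.numeric(spacing),
         gland_axes = gland_axes, lesion_count_range = as.integer(lesion_count_range),
         lesion_radius_range = lesion_radius_range,
         heart_radius_range = heart_radius_range,
         intensity_means = intensity_means, intensity_sd = intensity_sd,
         noise_sd = noise_sd, center_gain = center_gain,
         center_offset = center_offset),
    class = "phantom_spec"
  )
}

#' Logistic outcome model linking markers and lesion volume to pCR
#'
#' `P(pCR = 1) = plogis(intercept + b_her2 her2 + b_er er + b_pr pr +
#' b_ki67 ki67 + b_vol V)` with `V` the realized lesion volume in mL.
#' Default signs follow clinical direction — HER2-positive and hormone
#' receptor-positive status raise the chance of pCR, high Ki-67 and larger
#' lesions lower it — and the default magnitudes make the marker signal
#' unambiguous (the true-probability AUC of a generated cohort is around
#' 0.75-0.85), so that recovering or failing to recover it is a property
#' of a model, not of the scenario.  The intercept puts prevalence near
#' 0.5.
#'
#' @param intercept,coef_her2,coef_er,coef_pr,coef_ki67,coef_lesion_volume
#'   Logistic-model coefficients.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(intercept = 0.8, coef_her2 = 2.0, coef_er = 1.0,
                          coef_pr = 1.0, coef_ki67 = -4.0,
                          coef_lesion_volume = -0.8) {
  structure(list(intercept = intercept, coef_her2 = coef_her2, coef_er = coef_er,
                 coef_pr = coef_pr, coef_ki67 = coef_ki67,
                 coef_lesion_volume = coef_lesion_volume),
            class = "outcome_model")
}

pcr_probability <- function(outcome, her2, er, pr, ki67, lesion_volume_ml) {
  stats::plogis(outcome$intercept + outcome$coef_her2 * her2 +
                  outcome$coef_er * er + outcome$coef_pr * pr +
                  outcome$coef_ki67 * ki67 +
                  outcome$coef_lesion_volume * lesion_volume_ml)
}

# mm coordinates of all voxel centers, one column per axis
phantom_coords <- function(shape, spacing) {
  g <- coord_grid(shape)
  for (a in 1:3) g[, a] <- g[, a] * spacing[a]
  g
}

in_ellipsoid <- function(coords, center, semi) {
  ((coords[, 1] - center[1]) / semi[1])^2 +
    ((coords[, 2] - center[2]) / semi[2])^2 +
    ((coords[, 3] - center[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic breast phantom
#'
#' Deterministic given `(spec, seed, center)`.  Voxel intensities are the
#' phantom's tissue mean plus Gaussian noise, then the chosen center's
#' gain/offset is applied.  Returned masks satisfy the label invariants:
#' the lesion is contained in the gland and the heart is disjoint from it.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param center Which simulated center's intensity transform to apply
#'   (index into `spec$center_gain`).
#' @return A list with elements `volume` ([image_volume()]), `gland_mask`,
#'   `lesion_mask`, `heart_mask` (each a [label_mask()]), and
#'   `lesion_volume_ml`.
#' @export
generate_phantom <- function(spec, seed, center = 1L) {
  assert_that(inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec")
  assert_that(center >= 1 && center <= length(spec$center_gain),
              "`center` out of range")
  with_preserved_rng(seed, {
    shape <- spec$volume_shape
    sp <- spec$spacing
    ext <- shape * sp                       # physical extent, mm
    coords <- phantom_coords(shape, sp)

    # two anterior gland half-ellipsoids, overlapping at the midline
    semi <- stats::runif(3, spec$gland_axes[1], spec$gland_axes[2])
    gc_y <- 0.30 * ext[2]
    gc_z <- 0.50 * ext[3]
    centers_x <- c(0.32, 0.68) * ext[1]
    gland <- rep(FALSE, nrow(coords))
    for (cx in centers_x) {
      gland <- gland | (in_ellipsoid(coords, c(cx, gc_y, gc_z), semi) &
                          coords[, 2] <= gc_y + 0.4 * semi[2])
    }

    # posterior midline heart sphere, disjoint from the glands
    heart_r <- stats::runif(1, spec$heart_radius_range[1], spec$heart_radius_range[2])
    heart_c <- c(0.5 * ext[1], 0.78 * ext[2], 0.5 * ext[3])
    heart <- in_ellipsoid(coords, heart_c, rep(heart_r, 3))
    heart <- heart & !gland

    # lesions: unions of 1-3 overlapping spherelets, fully inside the gland
    n_lesions <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2]) {
      spec$lesion_count_range[1]
    } else {
      sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1)
    }
    gland_idx <- which(gland)
    # candidate lesion centers live in the deep interior of a gland, so a
    # several-mm spherelet union has room; the exact containment check below
    # still decides
    deep <- rep(FALSE, nrow(coords))
    for (cx in centers_x) {
      deep <- deep | (in_ellipsoid(coords, c(cx, gc_y, gc_z), semi * 0.5) &
                        coords[, 2] <= gc_y + 0.4 * semi[2])
    }
    deep_idx <- which(deep & gland)
    if (length(deep_idx) == 0) deep_idx <- gland_idx
    lesion <- rep(FALSE, nrow(coords))
    for (l in seq_len(n_lesions)) {
      placed <- FALSE
      for (attempt in 1:200) {
        r <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        seed_vox <- coords[sample(deep_idx, 1), ]
        n_blob <- sample(1:3, 1)
        blob <- rep(FALSE, nrow(coords))
        for (b in seq_len(n_blob)) {
          off <- stats::rnorm(3, 0, r / 3)
          blob <- blob | in_ellipsoid(coords, seed_vox + off, rep(r, 3))
        }
        if (all(gland[blob])) { lesion <- lesion | blob; placed <- TRUE; break }
      }
      if (!placed) {
        stop_cs("could not place a lesion inside the gland after 200 attempts",
                "cs_generation_error")
      }
    }

    # intensities: a common per-phantom brightness shift (full tissue SD)
    # plus small independent per-tissue jitter (SD/5) -- independent jitter
    # at the full SD would often break the lesion/heart intensity confound
    mu <- spec$intensity_means + stats::rnorm(1, 0, spec$intensity_sd) +
      stats::rnorm(4, 0, spec$intensity_sd / 5)
    names(mu) <- names(spec$intensity_means)
    tissue <- rep(mu[["background"]], nrow(coords))
    tissue[gland] <- mu[["gland"]]
    tissue[heart] <- mu[["heart"]]
    tissue[lesion] <- mu[["lesion"]]
    vals <- tissue + stats::rnorm(length(tissue), 0, spec$noise_sd)
    vals <- vals * spec$center_gain[center] + spec$center_offset[center]

    voxel_ml <- prod(sp) / 1000
    list(
      volume = image_volume(array(vals, dim = shape), spacing = sp),
      gland_mask = label_mask(array(as.integer(gland), dim = shape), spacing = sp),
      lesion_mask = label_mask(array(as.integer(lesion), dim = shape), spacing = sp),
      heart_mask = label_mask(array(as.integer(heart), dim = shape), spacing = sp),
      lesion_volume_ml = sum(lesion) * voxel_ml
    )
  })
}

#' Generate a synthetic two-center cohort with a known marker-outcome link
#'
#' Writes `n` phantoms (image + gland/lesion masks as NIfTI) to `out_dir`
#' and returns the cohort tibble.  Markers are sampled independently (HER2
#' Bernoulli 0.3, ER 0.6, PR 0.55, Ki-67 ~ Beta(2, 3)); the pCR label is
#' drawn from the logistic [outcome_model()] evaluated at the markers and
#' the realized lesion volume; `center_id` is Bernoulli(`center_mix`) for
#' center 2, and the chosen center's intensity gain/offset is applied to
#' the image.
#'
#' @param n Number of patients (>= 1).
#' @param spec A [phantom_spec()].
#' @param outcome An [outcome_model()].
#' @param center_mix Probability that a sample comes from center 2.
#' @param seed Integer master seed; all per-patient randomness is derived
#'   from it via [split_seed()].
#' @param out_dir Output directory (created if missing).
#' @param marker_rates Named Bernoulli rates for `her2`, `er`, `pr` and
#'   Beta parameters `ki67_shape` for Ki-67.
#' @param write_heart If `TRUE` also write the heart confounder mask.
#' @return The cohort tibble (see [load_cohort()]), with extra columns
#'   `lesion_volume_ml` and `p_pcr_true`.
#' @export
generate_cohort <- function(n, spec = phantom_spec(), outcome = outcome_model(),
                            center_mix = 0.3, seed = 1L,
                            out_dir = tempfile("cohort_"),
                            marker_rates = c(her2 = 0.3, er = 0.6, pr = 0.55),
                            write_heart = FALSE) {
  assert_that(is_count(n) && n >= 1, "`n` must be a positive integer")
  assert_that(center_mix >= 0 && center_mix <= 1, "`center_mix` must lie in [0,1]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(seed, n + 1)
  meta <- with_preserved_rng(seeds[n + 1], {
    list(
      her2 = stats::rbinom(n, 1, marker_rates[["her2"]]),
      er = stats::rbinom(n, 1, marker_rates[["er"]]),
      pr = stats::rbinom(n, 1, marker_rates[["pr"]]),
      ki67 = stats::rbeta(n, 2, 3),
      center = 1L + stats::rbinom(n, 1, center_mix),
      u_label = stats::runif(n)
    )
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, seeds[i], center = meta$center[i])
    id <- sprintf("P%04d", i)
    image_path <- file.path(out_dir, paste0(id, "_img.nii.gz"))
    gland_path <- file.path(out_dir, paste0(id, "_gland.nii.gz"))
    lesion_path <- file.path(out_dir, paste0(id, "_lesion.nii.gz"))
    save_volume(ph$volume, image_path)
    save_volume(ph$gland_mask, gland_path)
    save_volume(ph$lesion_mask, lesion_path)
    if (write_heart) {
      save_volume(ph$heart_mask, file.path(out_dir, paste0(id, "_heart.nii.gz")))
    }
    p <- pcr_probability(outcome, meta$her2[i], meta$er[i], meta$pr[i],
                         meta$ki67[i], ph$lesion_volume_ml)
    rows[[i]] <- tibble::tibble(
      patient_id = id, her2 = meta$her2[i], er = meta$er[i], pr = meta$pr[i],
      ki67 = meta$ki67[i], pcr_label = as.integer(meta$u_label[i] < p),
      center_id = paste0("C", meta$center[i]),
      image_path = image_path, gland_mask_path = gland_path,
      lesion_mask_path = lesion_path,
      lesion_volume_ml = ph$lesion_volume_ml, p_pcr_true = p
    )
  }
  cohort <- dplyr::bind_rows(rows)
  save_cohort(cohort, file.path(out_dir, "cohort.csv"))
  cohort
}
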