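## Synthetic fundus-style scenes. A scene is latent geometry — retina disc,
## optic disc, fovea/macula centre and radii, bright lesion blobs, candidate
## question regions — from which the image, the region masks and every ground
## truth answer are derived. Pixel coordinates are 0-based (row, col).

.RENDER <- list(bg = 0.03, retina = 0.30, disc_gain = 0.45, macula_dip = 0.12)

#' Configuration of the synthetic dataset generator
#'
#' All geometric quantities expressed as `*_frac` are fractions of the shorter
#' image side. The generator enforces the scene invariants
#' `fovea_radius <= macula_radius < retina_radius` at the configuration level:
#' the radius ranges must be compatible, otherwise a configuration error is
#' raised immediately.
#'
#' @param n Named integer vector of per-split sample counts
#'   (`train`, `val`, `test`).
#' @param typeMix Proportions over question types (must sum to 1): either one
#'   vector applied to every split, or a named list with one vector per split.
#' @param binaryBalance Target proportions over YES/NO for presence questions
#'   (must sum to 1); per-split list allowed as for `typeMix`.
#' @param gradeBalance Target proportions over GRADE_0/1/2 for grade questions
#'   (must sum to 1); per-split list allowed as for `typeMix`.
#' @param imageSize `(H, W)` in pixels.
#' @param lesionLambda Mean of the Poisson lesion-count distribution.
#' @param retinaRadiusFrac,discRadiusFrac,foveaRadiusFrac,maculaRadiusFrac
#'   Ranges (length-2) for the corresponding radii.
#' @param lesionRadiusPx Lesion radius range, in pixels.
#' @param lesionIntensity Lesion peak-intensity range.
#' @param noiseSd Additive Gaussian noise standard deviation range.
#' @param illumination Multiplicative illumination gain range.
#' @param nCandidateRegions Candidate region masks drawn per scene.
#' @param regionRadiusFrac Candidate-region radius range.
#' @param maxOversampling Rejection-sampling budget per (split, type, answer)
#'   cell, as a multiple of the cell's sample count.
#' @param seed Generator seed.
#' @return A validated `bivqa_synth_config` list.
#' @export
synthConfig <- function(n = c(train = 80, val = 10, test = 10),
                        typeMix = c(WHOLE = 0.25, REGION = 0.25, FOVEA = 0.25, GRADE = 0.25),
                        binaryBalance = c(YES = 0.5, NO = 0.5),
                        gradeBalance = c(GRADE_0 = 1 / 3, GRADE_1 = 1 / 3, GRADE_2 = 1 / 3),
                        imageSize = c(96, 96),
                        lesionLambda = 2,
                        retinaRadiusFrac = c(0.42, 0.46),
                        discRadiusFrac = c(0.08, 0.11),
                        foveaRadiusFrac = c(0.055, 0.075),
                        maculaRadiusFrac = c(0.11, 0.14),
                        lesionRadiusPx = c(2, 5),
                        lesionIntensity = c(0.5, 0.9),
                        noiseSd = c(0, 0.03),
                        illumination = c(0.9, 1.1),
                        nCandidateRegions = 3L,
                        regionRadiusFrac = c(0.10, 0.22),
                        maxOversampling = 50L,
                        seed = 42L) {
  cfg <- list(n = n, type_mix = typeMix, binary_balance = binaryBalance,
              grade_balance = gradeBalance, image_size = as.integer(imageSize),
              lesion_lambda = lesionLambda,
              retina_radius_frac = retinaRadiusFrac, disc_radius_frac = discRadiusFrac,
              fovea_radius_frac = foveaRadiusFrac, macula_radius_frac = maculaRadiusFrac,
              lesion_radius_px = lesionRadiusPx, lesion_intensity = lesionIntensity,
              noise_sd = noiseSd, illumination = illumination,
              n_candidate_regions = as.integer(nCandidateRegions),
              region_radius_frac = regionRadiusFrac,
              max_oversampling = as.integer(maxOversampling), seed = as.integer(seed))
  class(cfg) <- "bivqa_synth_config"
  validate_synth_config(cfg)
  cfg
}

## A per-split proportion setting is either one vector for all splits or a
## named list with one vector per split.
split_prop <- function(x, split) {
  if (is.list(x)) x[[split]] else x
}

validate_synth_config <- function(cfg) {
  if (!all(c("train", "val", "test") %in% names(cfg$n)))
    contract_error("n must name train, val and test counts")
  for (split in c("train", "val", "test")) {
    tm <- split_prop(cfg$type_mix, split)
    if (is.null(tm) || abs(sum(tm) - 1) > 1e-9)
      contract_error("typeMix proportions must sum to 1 (split %s)", split)
    if (!setequal(names(tm), questionTypes()))
      contract_error("typeMix must cover exactly the four question types")
    if (abs(sum(split_prop(cfg$binary_balance, split)) - 1) > 1e-9)
      contract_error("binaryBalance proportions must sum to 1 (split %s)", split)
    if (abs(sum(split_prop(cfg$grade_balance, split)) - 1) > 1e-9)
      contract_error("gradeBalance proportions must sum to 1 (split %s)", split)
  }
  if (max(cfg$fovea_radius_frac) > min(cfg$macula_radius_frac))
    contract_error("configuration error: fovea radius range exceeds macula radius range")
  if (max(cfg$macula_radius_frac) >= min(cfg$retina_radius_frac))
    contract_error("configuration error: macula radius range reaches the retina radius")
  invisible(cfg)
}

#' Dataset presets
#'
#' `dmeLikePreset()` mirrors the per-split question-type and answer
#' distributions of the reference DME VQA dataset: region questions carry
#' 8498/9779 (about 86.9%) of the training split but only 918/1311 (about
#' 70%) of the test split, presence answers are nearly balanced in training
#' and lean towards "no" in testing, and the grade answers follow each
#' split's grade proportions (grade 2 most frequent, grade 1 rare).
#' `tinyPreset()` is a fast small-image configuration for smoke tests and
#' examples.
#'
#' @param n Per-split sample counts.
#' @param seed Generator seed.
#' @param ... Overrides passed on to [synthConfig()].
#' @return A `bivqa_synth_config`.
#' @export
dmeLikePreset <- function(n = c(train = 1400, val = 400, test = 200), seed = 42L, ...) {
  synthConfig(
    n = n,
    typeMix = list(
      train = c(WHOLE = 427, REGION = 8498, FOVEA = 427, GRADE = 427) / 9779,
      val = c(WHOLE = 106, REGION = 2062, FOVEA = 106, GRADE = 106) / 2380,
      test = c(WHOLE = 131, REGION = 918, FOVEA = 131, GRADE = 131) / 1311),
    binaryBalance = list(
      train = c(YES = 4713, NO = 4639) / 9352,
      val = c(YES = 1151, NO = 1123) / 2274,
      test = c(YES = 530, NO = 650) / 1180),
    gradeBalance = list(
      train = c(GRADE_0 = 166, GRADE_1 = 41, GRADE_2 = 220) / 427,
      val = c(GRADE_0 = 39, GRADE_1 = 8, GRADE_2 = 59) / 106,
      test = c(GRADE_0 = 49, GRADE_1 = 15, GRADE_2 = 67) / 131),
    seed = seed, ...)
}

#' @rdname dmeLikePreset
#' @export
tinyPreset <- function(n = c(train = 64, val = 24, test = 24), seed = 42L, ...) {
  synthConfig(n = n, imageSize = c(48, 48), lesionLambda = 1.5, seed = seed, ...)
}

## ------------------------------------------------------------------
## Scenes

#' Draw one latent scene from a generator configuration
#'
#' Consumes the current global RNG stream: identical RNG state gives an
#' identical scene. All lesion centres lie inside the retina disc and
#' `fovea_radius <= macula_radius < retina_radius` by construction.
#'
#' @param config A [synthConfig()] object.
#' @param lesionCount Optional forced lesion count (used by the generator to
#'   sample the exact conditional for answers that require an empty lesion
#'   list); `NULL` draws from the configured Poisson distribution.
#' @return A `bivqa_scene` list: image size, retina/disc/fovea geometry,
#'   lesion blobs, candidate regions, illumination gain, noise sd and a
#'   private noise seed for reproducible rendering.
#' @export
sampleScene <- function(config, lesionCount = NULL) {
  H <- config$image_size[1]; W <- config$image_size[2]
  s <- min(H, W)
  ctr <- c((H - 1) / 2, (W - 1) / 2) + runif(2, -0.02 * s, 0.02 * s)
  retina_r <- runif(1, config$retina_radius_frac[1], config$retina_radius_frac[2]) * s

  ## optic disc: off-centre within the retina
  da <- runif(1, 0, 2 * pi); dd <- runif(1, 0.45, 0.65) * retina_r
  disc_r <- runif(1, config$disc_radius_frac[1], config$disc_radius_frac[2]) * s
  disc_c <- ctr + dd * c(sin(da), cos(da))

  ## fovea/macula: one centre, two radii
  fa <- runif(1, 0, 2 * pi); fd <- runif(1, 0, 0.35) * retina_r
  fovea_c <- ctr + fd * c(sin(fa), cos(fa))
  fovea_r <- runif(1, config$fovea_radius_frac[1], config$fovea_radius_frac[2]) * s
  macula_r <- runif(1, config$macula_radius_frac[1], config$macula_radius_frac[2]) * s

  n_les <- if (is.null(lesionCount)) rpois(1, config$lesion_lambda) else as.integer(lesionCount)
  lesions <- lapply(seq_len(n_les), function(i) {
    r <- retina_r * sqrt(runif(1)) * 0.95  # centre strictly inside the retina
    a <- runif(1, 0, 2 * pi)
    list(center = ctr + r * c(sin(a), cos(a)),
         radius = runif(1, config$lesion_radius_px[1], config$lesion_radius_px[2]),
         intensity = runif(1, config$lesion_intensity[1], config$lesion_intensity[2]))
  })

  regions <- lapply(seq_len(config$n_candidate_regions), function(i) {
    r <- retina_r * sqrt(runif(1)) * 0.9
    a <- runif(1, 0, 2 * pi)
    list(center = ctr + r * c(sin(a), cos(a)),
         radius = runif(1, config$region_radius_frac[1], config$region_radius_frac[2]) * s)
  })

  scene <- list(image_size = c(H, W), retina_center = ctr, retina_radius = retina_r,
                disc_center = disc_c, disc_radius = disc_r,
                fovea_center = fovea_c, fovea_radius = fovea_r, macula_radius = macula_r,
                lesions = lesions, candidate_regions = regions,
                noise_sd = runif(1, config$noise_sd[1], config$noise_sd[2]),
                illumination_gain = runif(1, config$illumination[1], config$illumination[2]),
                noise_seed = sample.int(.Machine$integer.max, 1))
  class(scene) <- "bivqa_scene"
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  if (!(scene$fovea_radius <= scene$macula_radius &&
        scene$macula_radius < scene$retina_radius))
    contract_error("scene invariant violated: need fovea <= macula < retina radius")
  for (l in scene$lesions) {
    if (sqrt(sum((l$center - scene$retina_center)^2)) > scene$retina_radius)
      contract_error("scene invariant violated: lesion centre outside the retina disc")
  }
  invisible(scene)
}

## Squared distance of every pixel (0-based row, col) from a centre.
pixel_dist2 <- function(H, W, center) {
  outer((0:(H - 1) - center[1])^2, rep(1, W)) +
    outer(rep(1, H), (0:(W - 1) - center[2])^2)
}

## Logical H x W raster of a disk.
disk_raster <- function(H, W, center, radius) {
  pixel_dist2(H, W, center) <= radius^2
}

## Smooth radial blob profile: cosine taper, exactly zero beyond the radius so
## that pixels outside every blob keep their closed-form base level.
blob_profile <- function(d2, radius) {
  d <- sqrt(d2)
  ifelse(d <= radius, 0.5 * (1 + cos(pi * d / radius)), 0)
}

#' Render a scene to an image and candidate region masks
#'
#' The image is a dark background with a brighter retina disc, a bright smooth
#' optic-disc blob, a darker macula, and bright smooth lesion blobs; a
#' multiplicative illumination gain and additive Gaussian noise (drawn from the
#' scene's private noise seed, so rendering is deterministic per scene) are
#' applied and the result is clipped to [0, 1]. Candidate region masks are
#' binary disk rasters clipped to the retina.
#'
#' @param scene A `bivqa_scene`.
#' @return List with `image` (H x W matrix in [0, 1]) and `masks` (list of
#'   binary H x W matrices).
#' @export
renderImage <- function(scene) {
  validate_scene(scene)
  H <- scene$image_size[1]; W <- scene$image_size[2]
  d2_ret <- pixel_dist2(H, W, scene$retina_center)
  base <- matrix(.RENDER$bg, H, W)
  inside <- d2_ret <= scene$retina_radius^2
  base[inside] <- .RENDER$retina

  ## macula: a darker region around the fovea centre (also what makes fovea
  ## and grade questions answerable from pixels)
  d2_fov <- pixel_dist2(H, W, scene$fovea_center)
  base <- base - .RENDER$macula_dip * blob_profile(d2_fov, scene$macula_radius) * inside

  ## optic disc blob
  base <- base + .RENDER$disc_gain *
    blob_profile(pixel_dist2(H, W, scene$disc_center), scene$disc_radius) * inside

  for (l in scene$lesions) {
    base <- base + l$intensity *
      blob_profile(pixel_dist2(H, W, l$center), l$radius) * inside
  }

  img <- scene$illumination_gain * base
  if (scene$noise_sd > 0) {
    img <- img + with_seed(scene$noise_seed,
                           matrix(rnorm(H * W, sd = scene$noise_sd), H, W))
  }
  img <- pmin(pmax(img, 0), 1)

  masks <- lapply(scene$candidate_regions, function(rg) {
    (disk_raster(H, W, rg$center, rg$radius) & inside) * 1
  })
  list(image = img, masks = masks)
}

## ------------------------------------------------------------------
## Ground-truth answers from geometry

lesion_intersects_disk <- function(scene, center, radius) {
  for (l in scene$lesions) {
    if (sqrt(sum((l$center - center)^2)) <= l$radius + radius) return(TRUE)
  }
  FALSE
}

lesion_intersects_mask <- function(scene, mask) {
  H <- nrow(mask); W <- ncol(mask)
  for (l in scene$lesions) {
    if (any(mask > 0 & disk_raster(H, W, l$center, l$radius))) return(TRUE)
  }
  FALSE
}

#' Derive the ground-truth answer for a scene and question type
#'
#' WHOLE: YES iff any lesion exists. REGION: YES iff any rasterised lesion disk
#' shares at least one pixel with the mask. FOVEA: YES iff any lesion disk
#' intersects the fovea disk. GRADE: grade 0 with no lesions; grade 2 when any
#' lesion disk intersects the macula disk (same centre, macula radius); grade 1
#' otherwise (peripheral lesions only).
#'
#' @param scene A `bivqa_scene`.
#' @param questionType A question type token.
#' @param mask Binary H x W matrix; required (only) for REGION questions.
#' @return An answer label token.
#' @export
deriveAnswer <- function(scene, questionType, mask = NULL) {
  questionType <- asQuestionType(questionType)
  if (questionType == "REGION" && is.null(mask))
    contract_error("REGION questions require a mask")
  if (questionType != "REGION" && !is.null(mask))
    contract_error("only REGION questions take a mask")
  switch(questionType,
    WHOLE = if (length(scene$lesions) > 0) "YES" else "NO",
    REGION = if (lesion_intersects_mask(scene, mask)) "YES" else "NO",
    FOVEA = if (lesion_intersects_disk(scene, scene$fovea_center, scene$fovea_radius))
      "YES" else "NO",
    GRADE = {
      if (length(scene$lesions) == 0) "GRADE_0"
      else if (lesion_intersects_disk(scene, scene$fovea_center, scene$macula_radius))
        "GRADE_2"
      else "GRADE_1"
    })
}

#' Question template for a question type
#'
#' Returns the fixed question template for each type; paraphrase augmentation
#' is deliberately not applied by default, so the question language is a small
#' closed set.
#'
#' @param questionType A question type token.
#' @return The question string.
#' @export
questionText <- function(questionType) {
  questionType <- asQuestionType(questionType)
  unname(c(
    WHOLE = "Are there hard exudates in this image?",
    REGION = "Are there hard exudates in the region?",
    FOVEA = "Are there hard exudates in the fovea?",
    GRADE = "What is the diabetic macular edema grade for this image?"
  )[questionType])
}
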