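# Synthetic scene generation: determinism, geometric invariants, answer
# derivation rules, rendering contracts, and distributional targets.

test_that("identical RNG state yields bit-identical scenes", {
  cfg <- tinyPreset()
  set.seed(7); s1 <- sampleScene(cfg)
  set.seed(7); s2 <- sampleScene(cfg)
  expect_identical(s1, s2)
})

test_that("sampled scenes satisfy the geometric invariants", {
  cfg <- synthConfig(seed = 3)
  set.seed(3)
  for (i in 1:100) {
    s <- sampleScene(cfg)
    expect_lte(s$fovea_radius, s$macula_radius)
    expect_lt(s$macula_radius, s$retina_radius)
    for (l in s$lesions)
      expect_lte(sqrt(sum((l$center - s$retina_center)^2)), s$retina_radius)
  }
})

test_that("a forced zero lesion count yields an empty lesion list", {
  set.seed(1)
  s <- sampleScene(synthConfig(), lesionCount = 0)
  expect_length(s$lesions, 0)
})

test_that("infeasible geometry ranges are configuration errors", {
  expect_error(synthConfig(maculaRadiusFrac = c(0.5, 0.6)),
               class = "bivqa_contract_error")  # macula >= retina
  expect_error(synthConfig(foveaRadiusFrac = c(0.2, 0.3)),
               class = "bivqa_contract_error")  # fovea > macula
})

test_that("empirical lesion-count mean matches the configured distribution", {
  cfg <- synthConfig(lesionLambda = 2)
  set.seed(11)
  n <- 10000
  counts <- vapply(seq_len(n), function(i) length(sampleScene(cfg)$lesions), 0)
  se <- sqrt(2 / n)  # Poisson variance = mean
  expect_lt(abs(mean(counts) - 2), 3 * se)
})

base_scene <- function(lesions = list(), noise_sd = 0, gain = 1,
                       fovea = c(47.5, 47.5)) {
  s <- list(image_size = c(96L, 96L), retina_center = c(47.5, 47.5),
            retina_radius = 42, disc_center = c(30, 60), disc_radius = 9,
            fovea_center = fovea, fovea_radius = 6, macula_radius = 12,
            lesions = lesions, candidate_regions = list(
              list(center = c(60, 30), radius = 12)),
            noise_sd = noise_sd, illumination_gain = gain, noise_seed = 5L)
  class(s) <- "bivqa_scene"
  s
}

test_that("answer derivation follows the grading and presence rules", {
  empty <- base_scene()
  expect_identical(deriveAnswer(empty, "WHOLE"), "NO")
  expect_identical(deriveAnswer(empty, "GRADE"), "GRADE_0")

  at_fovea <- base_scene(lesions = list(list(center = c(47.5, 47.5),
                                             radius = 3, intensity = 0.8)))
  expect_identical(deriveAnswer(at_fovea, "GRADE"), "GRADE_2")
  expect_identical(deriveAnswer(at_fovea, "FOVEA"), "YES")
  expect_identical(deriveAnswer(at_fovea, "WHOLE"), "YES")

  # strictly outside the macula disk: peripheral, hence grade 1
  peripheral <- base_scene(lesions = list(list(center = c(47.5, 47.5 + 30),
                                               radius = 3, intensity = 0.8)))
  expect_identical(deriveAnswer(peripheral, "GRADE"), "GRADE_1")
  expect_identical(deriveAnswer(peripheral, "FOVEA"), "NO")

  # mask disjoint from every lesion disk
  mask <- (bivqa:::pixel_dist2(96, 96, c(20, 20)) <= 25) * 1
  expect_identical(deriveAnswer(peripheral, "REGION", mask), "NO")
  mask_on <- (bivqa:::pixel_dist2(96, 96, c(47.5, 77.5)) <= 100) * 1
  expect_identical(deriveAnswer(peripheral, "REGION", mask_on), "YES")

  expect_error(deriveAnswer(peripheral, "REGION"), class = "bivqa_contract_error")
  expect_error(deriveAnswer(peripheral, "WHOLE", mask), class = "bivqa_contract_error")
})

test_that("macula covering the whole retina forces grade 2 for any lesion", {
  set.seed(21)
  cfg <- synthConfig()
  for (i in 1:20) {
    s <- sampleScene(cfg)
    if (length(s$lesions) == 0) next
    s$fovea_center <- s$retina_center
    s$macula_radius <- 0.999 * s$retina_radius
    expect_identical(deriveAnswer(s, "GRADE"), "GRADE_2")
  }
})

test_that("question templates match the four question families", {
  expect_identical(questionText("WHOLE"), "Are there hard exudates in this image?")
  expect_identical(questionText("REGION"), "Are there hard exudates in the region?")
  expect_identical(questionText("FOVEA"), "Are there hard exudates in the fovea?")
  expect_identical(questionText("GRADE"),
                   "What is the diabetic macular edema grade for this image?")
})

test_that("rendering honours the closed-form base levels and clipping", {
  rnd <- renderImage(base_scene())
  img <- rnd$image
  expect_true(min(img) >= 0 && max(img) <= 1)
  # with no lesions, no noise, unit gain: outside the optic-disc blob and the
  # macula dip, values are exactly background or retina base
  d2_disc <- bivqa:::pixel_dist2(96, 96, c(30, 60))
  d2_fov <- bivqa:::pixel_dist2(96, 96, c(47.5, 47.5))
  d2_ret <- bivqa:::pixel_dist2(96, 96, c(47.5, 47.5))
  outside_blobs <- d2_disc > 9^2 & d2_fov > 12^2
  inside_ret <- d2_ret <= 42^2
  expect_equal(max(img[outside_blobs & !inside_ret]), bivqa:::.RENDER$bg)
  expect_equal(max(img[outside_blobs & inside_ret]), bivqa:::.RENDER$retina)

  # a bright lesion raises its centre pixel at least to the retina base
  les <- base_scene(lesions = list(list(center = c(70, 40), radius = 4,
                                        intensity = 0.9)))
  img2 <- renderImage(les)$image
  expect_gte(img2[71, 41], bivqa:::.RENDER$retina)

  # candidate masks are binary and lie inside the retina
  for (m in rnd$masks) {
    expect_true(all(m %in% c(0, 1)))
    expect_true(all(d2_ret[m == 1] <= 42^2))
  }
})

test_that("rendering is deterministic per scene (private noise stream)", {
  s <- base_scene(noise_sd = 0.05)
  expect_identical(renderImage(s)$image, renderImage(s)$image)
})

test_that("generation is deterministic and the manifest validates", {
  fx <- tiny_dataset()
  dir2 <- file.path(tempdir(), "bivqa-tiny-2")
  generateDataset(tinyPreset(seed = 42L), dir2)
  expect_file_identical(file.path(fx$dir, "manifest.jsonl"),
                        file.path(dir2, "manifest.jsonl"))
  expect_file_identical(file.path(fx$dir, "scenes.jsonl"),
                        file.path(dir2, "scenes.jsonl"))
  expect_identical(nrow(validateManifest(fx$manifest)), 0L)
})

test_that("per-split counts and type proportions match the configuration", {
  fx <- tiny_dataset()
  cnt <- manifestCounts(fx$manifest)
  expect_identical(as.integer(cnt$per_split), c(64L, 24L, 24L))
  # uniform mix at n = 64: exactly 16 of each type in train
  expect_true(all(cnt$per_type["train", ] == 16L))
})

test_that("stored answers are reproducible from the stored latent scenes", {
  fx <- tiny_dataset()
  scn <- readScenes(file.path(fx$dir, "scenes.jsonl"))
  df <- samples(fx$manifest)
  for (i in seq_len(nrow(df))) {
    rec <- scn[[df$id[i]]]
    mask <- if (!is.na(df$mask_path[i]))
      readMaskPNG(file.path(fx$dir, df$mask_path[i])) else NULL
    expect_identical(deriveAnswer(rec$scene, df$question_type[i], mask),
                     df$answer[i])
  }
})

test_that("generated answer frequencies converge to the configured balance", {
  cfg <- synthConfig(n = c(train = 2000, val = 0, test = 0), seed = 9)
  recs <- generateRecords(cfg)
  ans <- vapply(recs, `[[`, "", "answer")
  # expected whole-dataset answer frequencies under the uniform type mix:
  # 3/4 of questions are binary (yes/no at 1/2 each), 1/4 graded (1/3 each)
  target <- c(YES = 3 / 8, NO = 3 / 8, GRADE_0 = 1 / 12, GRADE_1 = 1 / 12,
              GRADE_2 = 1 / 12)
  for (a in names(target))
    expect_lt(abs(mean(ans == a) - target[[a]]), 0.03)
})

test_that("the dme-like allocation reproduces the published region share", {
  alloc <- bivqa:::allocate_counts(
    1400, bivqa:::split_prop(dmeLikePreset()$type_mix, "train"))
  expect_lt(abs(alloc[["REGION"]] / 1400 - 8498 / 9779), 0.01)
})
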