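## Dataset generation: allocate question types per split (largest-remainder,
## so realised proportions match the mix to within rounding), draw a target
## answer per sample from the configured balance, and rejection-sample scenes
## until the geometry-derived answer matches the target. Answers are always
## derived from geometry, never sampled independently of it.

## Largest-remainder allocation of n samples over the type mix.
allocate_counts <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

draw_target_answer <- function(config, type, split) {
  bal <- if (type == "GRADE") split_prop(config$grade_balance, split)
         else split_prop(config$binary_balance, split)
  sample(names(bal), 1, prob = bal)
}

## Answers whose exact conditional scene distribution is "no lesions at all";
## sampled directly instead of rejected (distributionally identical).
forces_empty_lesions <- function(type, target) {
  (type == "WHOLE" && target == "NO") || (type == "GRADE" && target == "GRADE_0")
}

#' Generate sample records (latent scenes, no file I/O)
#'
#' Draws the full dataset — split/type allocation, target answers, accepted
#' scenes and, for REGION questions, the index of the candidate region that
#' realises the target — without rendering pixels. [generateDataset()] renders
#' and writes these records to disk; this function is also useful on its own
#' for distributional checks at large n.
#'
#' @param config A [synthConfig()] object.
#' @return A list of records: `id`, `split`, `question_type`, `question`,
#'   `answer`, `scene`, `region_index` (NA unless REGION).
#' @export
generateRecords <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  records <- list()
  attempts <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())

  for (split in .SPLITS) {
    n_split <- as.integer(config$n[[split]])
    alloc <- allocate_counts(n_split, split_prop(config$type_mix, split))
    types <- sample(rep(names(alloc), times = alloc))
    for (i in seq_len(n_split)) {
      type <- types[i]
      target <- draw_target_answer(config, type, split)
      cell <- paste(split, type, target, sep = ":")
      counts[[cell]] <- (counts[[cell]] %||% 0L) + 1L
      budget <- config$max_oversampling * counts[[cell]]
      found <- FALSE
      while (!found) {
        if ((attempts[[cell]] %||% 0L) >= budget)
          contract_error(
            "rejection budget exhausted for cell split=%s type=%s answer=%s (%dx oversampling)",
            split, type, target, config$max_oversampling)
        attempts[[cell]] <- (attempts[[cell]] %||% 0L) + 1L
        scene <- sampleScene(config,
                             lesionCount = if (forces_empty_lesions(type, target)) 0L else NULL)
        region_index <- NA_integer_
        if (type == "REGION") {
          H <- scene$image_size[1]; W <- scene$image_size[2]
          inside <- disk_raster(H, W, scene$retina_center, scene$retina_radius)
          for (ri in seq_along(scene$candidate_regions)) {
            rg <- scene$candidate_regions[[ri]]
            mask <- (disk_raster(H, W, rg$center, rg$radius) & inside) * 1
            if (sum(mask) == 0) next
            if (deriveAnswer(scene, "REGION", mask) == target) {
              region_index <- ri
              found <- TRUE
              break
            }
          }
        } else {
          found <- deriveAnswer(scene, type) == target
        }
      }
      records[[length(records) + 1L]] <- list(
        id = sprintf("%s-%05d", split, i), split = split, question_type = type,
        question = questionText(type), answer = target, scene = scene,
        region_index = region_index)
    }
  }
  records
}

#' Generate a synthetic fundus VQA dataset on disk
#'
#' Writes PNG images (and, for REGION samples, PNG masks), a JSON-lines
#' manifest, and a `scenes.jsonl` sidecar storing the latent geometry each
#' sample was derived from (the test oracle for answer consistency). A fixed
#' seed yields a byte-identical manifest and sidecar.
#'
#' @param config A [synthConfig()] object.
#' @param dir Output directory (created if needed).
#' @return The dataset [VQAManifest-class], invisibly validated.
#' @export
generateDataset <- function(config, dir) {
  records <- generateRecords(config)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    rendered <- renderImage(rec$scene)
    image_path <- file.path("images", paste0(rec$id, ".png"))
    png::writePNG(rendered$image, file.path(dir, image_path))
    mask_path <- NA_character_
    if (!is.na(rec$region_index)) {
      mask_path <- file.path("masks", paste0(rec$id, ".png"))
      png::writePNG(rendered$masks[[rec$region_index]], file.path(dir, mask_path))
    }
    rows[[k]] <- data.frame(id = rec$id, image_path = image_path, mask_path = mask_path,
                            question = rec$question, question_type = rec$question_type,
                            answer = rec$answer, split = rec$split,
                            stringsAsFactors = FALSE)
  }
  manifest <- newManifest(do.call(rbind, rows), dir = dir)
  writeManifest(manifest, file.path(dir, "manifest.jsonl"))
  write_scenes(records, file.path(dir, "scenes.jsonl"))

  viol <- validateManifest(manifest)
  if (nrow(viol) > 0)
    contract_error("generated manifest failed validation (%d violations)", nrow(viol))
  log_event("generate", dir = dir, n = length(records), config_hash = config_hash(config),
            seed = config$seed)
  manifest
}

## ------------------------------------------------------------------
## Latent-geometry sidecar

scene_to_list <- function(scene) {
  list(image_size = scene$image_size, retina_center = scene$retina_center,
       retina_radius = scene$retina_radius, disc_center = scene$disc_center,
       disc_radius = scene$disc_radius, fovea_center = scene$fovea_center,
       fovea_radius = scene$fovea_radius, macula_radius = scene$macula_radius,
       lesions = lapply(scene$lesions, function(l)
         list(center = l$center, radius = l$radius, intensity = l$intensity)),
       candidate_regions = lapply(scene$candidate_regions, function(r)
         list(center = r$center, radius = r$radius)),
       noise_sd = scene$noise_sd, illumination_gain = scene$illumination_gain,
       noise_seed = scene$noise_seed)
}

list_to_scene <- function(x) {
  x$lesions <- lapply(x$lesions, function(l)
    list(center = as.numeric(l$center), radius = l$radius, intensity = l$intensity))
  x$candidate_regions <- lapply(x$candidate_regions, function(r)
    list(center = as.numeric(r$center), radius = r$radius))
  x$retina_center <- as.numeric(x$retina_center)
  x$disc_center <- as.numeric(x$disc_center)
  x$fovea_center <- as.numeric(x$fovea_center)
  x$image_size <- as.integer(x$image_size)
  class(x) <- "bivqa_scene"
  x
}

write_scenes <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    line <- jsonlite::toJSON(
      list(id = rec$id, question_type = rec$question_type, answer = rec$answer,
           region_index = if (is.na(rec$region_index)) NULL else rec$region_index,
           scene = scene_to_list(rec$scene)),
      auto_unbox = TRUE, digits = 10, null = "null")
    writeLines(as.character(line), con, sep = "\n")
  }
  invisible(path)
}

#' Read the latent-scene sidecar of a generated dataset
#'
#' @param path Path to `scenes.jsonl`.
#' @return A named list (by sample id) with elements `scene` (a
#'   `bivqa_scene`), `question_type`, `answer` and `region_index`.
#' @export
readScenes <- function(path) {
  if (!file.exists(path)) io_error("scene sidecar not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(scene = list_to_scene(x$scene), question_type = x$question_type,
         answer = x$answer,
         region_index = if (is.null(x$region_index)) NA_integer_ else x$region_index)
  })
  names(out) <- vapply(lines, function(l) jsonlite::fromJSON(l)$id, "")
  out
}
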