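## Dataset manifests: JSON-lines on disk, one sample per line with fields
## id, image_path, mask_path (nullable), question, question_type, answer, split.
## Images and masks are PNG; masks are strictly 0/255 on disk and {0,1} in
## memory (1 = inside region). Pixel coordinates are 0-based (row, col).

.MANIFEST_COLS <- c("id", "image_path", "mask_path", "question",
                    "question_type", "answer", "split")
.SPLITS <- c("train", "val", "test")

#' Construct a manifest from a sample table
#'
#' @param df A data.frame with the manifest columns (`id`, `image_path`,
#'   `mask_path`, `question`, `question_type`, `answer`, `split`).
#' @param dir Directory against which relative paths resolve.
#' @return A [VQAManifest-class].
#' @export
newManifest <- function(df, dir = ".") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"mask_path" %in% names(df)) df$mask_path <- NA_character_
  df <- df[, .MANIFEST_COLS]
  rownames(df) <- NULL
  new("VQAManifest", samples = df, dir = dir)
}

#' Read / write a JSON-lines manifest
#'
#' One JSON object per line. Writing then reading a manifest reproduces the
#' sample ordering and tallies exactly; with fixed inputs the byte stream is
#' reproducible.
#'
#' @param path Path to a `.jsonl` manifest file.
#' @param dir Directory for resolving relative image/mask paths; defaults to
#'   the manifest's own directory.
#' @return A [VQAManifest-class] (for `readManifest`); the path, invisibly
#'   (for `writeManifest`).
#' @export
readManifest <- function(path, dir = dirname(path)) {
  if (!file.exists(path)) io_error("manifest file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  df <- data.frame(
    id = vapply(recs, function(r) as.character(r$id), ""),
    image_path = vapply(recs, function(r) as.character(r$image_path), ""),
    mask_path = vapply(recs, function(r)
      if (is.null(r$mask_path)) NA_character_ else as.character(r$mask_path), ""),
    question = vapply(recs, function(r) as.character(r$question), ""),
    question_type = vapply(recs, function(r) as.character(r$question_type), ""),
    answer = vapply(recs, function(r) as.character(r$answer), ""),
    split = vapply(recs, function(r) as.character(r$split), ""),
    stringsAsFactors = FALSE
  )
  newManifest(df, dir = dir)
}

#' @rdname readManifest
#' @param manifest A [VQAManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  df <- samples(manifest)
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    rec <- list(id = df$id[i], image_path = df$image_path[i],
                mask_path = if (is.na(df$mask_path[i])) NULL else df$mask_path[i],
                question = df$question[i], question_type = df$question_type[i],
                answer = df$answer[i], split = df$split[i])
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")),
               con, sep = "\n")
  }
  invisible(path)
}

#' Recomputed per-split tallies of a manifest
#'
#' @param x A [VQAManifest-class].
#' @param ... Unused.
#' @return A list with `per_split`, `per_answer` (split x answer) and
#'   `per_type` (split x question type) contingency tables.
#' @rdname accessors
#' @export
setMethod("manifestCounts", "VQAManifest", function(x, ...) {
  df <- samples(x)
  sp <- factor(df$split, levels = .SPLITS)
  list(per_split = table(split = sp),
       per_answer = table(split = sp, answer = factor(df$answer, levels = .ANSWER_LABELS)),
       per_type = table(split = sp, type = factor(df$question_type, levels = .QUESTION_TYPES)))
})

#' Validate a manifest against the domain invariants
#'
#' Checks every sample record: unique ids, known split/type/answer tokens,
#' mask present if and only if the question type is REGION, type/answer
#' compatibility, and (optionally) that all referenced files exist. Unreadable
#' files are I/O errors at read time, distinct from validation failures.
#'
#' @param manifest A [VQAManifest-class].
#' @param checkFiles Also check that referenced image/mask paths exist.
#' @return A data.frame of violations (columns `id`, `rule`, `detail`); empty
#'   when all invariants hold.
#' @export
validateManifest <- function(manifest, checkFiles = TRUE) {
  df <- samples(manifest)
  v <- list()
  add <- function(id, rule, detail) v[[length(v) + 1L]] <<- data.frame(
    id = id, rule = rule, detail = detail, stringsAsFactors = FALSE)

  dup <- df$id[duplicated(df$id)]
  for (d in unique(dup)) add(d, "unique_id", "duplicated sample id")

  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    if (!df$split[i] %in% .SPLITS)
      add(id, "split", sprintf("unknown split '%s'", df$split[i]))
    if (!df$question_type[i] %in% .QUESTION_TYPES) {
      add(id, "question_type", sprintf("unknown question type '%s'", df$question_type[i]))
      next
    }
    if (!df$answer[i] %in% .ANSWER_LABELS) {
      add(id, "answer", sprintf("unknown answer '%s'", df$answer[i]))
      next
    }
    has_mask <- !is.na(df$mask_path[i])
    if (df$question_type[i] == "REGION" && !has_mask)
      add(id, "mask_presence", "REGION sample without a mask")
    if (df$question_type[i] != "REGION" && has_mask)
      add(id, "mask_presence", sprintf("%s sample with a mask", df$question_type[i]))
    if (!answer_compatible(df$question_type[i], df$answer[i]))
      add(id, "type_answer", sprintf("answer %s incompatible with type %s",
                                     df$answer[i], df$question_type[i]))
    if (checkFiles) {
      ip <- file.path(manifest@dir, df$image_path[i])
      if (!file.exists(ip)) add(id, "image_exists", sprintf("missing image %s", df$image_path[i]))
      if (has_mask) {
        mp <- file.path(manifest@dir, df$mask_path[i])
        if (!file.exists(mp)) add(id, "mask_exists", sprintf("missing mask %s", df$mask_path[i]))
      }
    }
  }
  if (length(v) == 0)
    return(data.frame(id = character(), rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Subset a manifest by split
#'
#' @param manifest A [VQAManifest-class].
#' @param split One of "train", "val", "test".
#' @return A [VQAManifest-class] restricted to the split.
#' @export
manifestSplit <- function(manifest, split) {
  split <- match.arg(split, .SPLITS)
  df <- samples(manifest)
  newManifest(df[df$split == split, , drop = FALSE], dir = manifest@dir)
}

## ------------------------------------------------------------------
## Pixel I/O

#' Read an image or mask PNG into memory
#'
#' Images come back as H x W (grayscale) or H x W x 3 arrays with values in
#' [0, 1]; masks come back as H x W binary {0,1} matrices (0/255 on disk).
#'
#' @param path PNG file path.
#' @return Numeric array in [0, 1].
#' @export
readImagePNG <- function(path) {
  if (!file.exists(path)) io_error("image file not found: %s", path)
  img <- tryCatch(png::readPNG(path), error = function(e)
    io_error("unreadable PNG %s: %s", path, conditionMessage(e)))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname readImagePNG
#' @export
readMaskPNG <- function(path) {
  m <- readImagePNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1
}

## Load one manifest row as an in-memory sample record: list(id, question,
## question_type, answer, split, image, mask). Masks are NULL when absent.
load_sample <- function(manifest, i) {
  df <- samples(manifest)
  img <- readImagePNG(file.path(manifest@dir, df$image_path[i]))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale model input
  msk <- if (is.na(df$mask_path[i])) NULL else
    readMaskPNG(file.path(manifest@dir, df$mask_path[i]))
  if (!is.null(msk) && !all(dim(msk) == dim(img)))
    contract_error("sample %s: image and mask dimensions differ", df$id[i])
  list(id = df$id[i], question = df$question[i],
       question_type = df$question_type[i], answer = df$answer[i],
       split = df$split[i], image = img, mask = msk)
}

## Load all rows of (one split of) a manifest into memory once; the returned
## list feeds the training loop and evaluators.
load_split_tensors <- function(manifest, split = NULL) {
  m <- if (is.null(split)) manifest else manifestSplit(manifest, split)
  lapply(seq_len(nrow(samples(m))), function(i) load_sample(m, i))
}
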