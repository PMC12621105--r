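#' @import methods
#' @importFrom stats rnorm runif rpois pt sd setNames
#' @importFrom utils head tail
NULL

## Error classes: contract errors (invariant/precondition breaches) are kept
## distinct from I/O and usage errors so callers (and the CLI) can map them to
## different exit codes.

contract_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("bivqa_contract_error", "error")))
}

io_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("bivqa_io_error", "error")))
}

usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("bivqa_usage_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. Used where reproducibility must not disturb
## the global generator (e.g. re-rendering a stored scene).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Row-wise softmax. Logits in this package are bounded, so a single global
## shift is numerically sufficient and avoids a slow per-row apply().
softmax_rows <- function(S) {
  E <- exp(S - max(S))
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## Add a bias (length-k vector) to every row of an n x k matrix without sweep().
add_rows <- function(M, b) M + rep(b, each = nrow(M))

relu <- function(x) pmax(x, 0)

l2_normalize <- function(x, eps = 1e-12) {
  n <- sqrt(sum(x * x))
  if (n < eps) return(x * 0)
  x / n
}

## Canonical JSON used for hashing and diff-friendly artifacts.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null")
}

config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(canonical_json(x)), tf)
  unname(tools::md5sum(tf))
}

## Minimal structured JSONL logger (INFO by default).
log_event <- function(event, ..., file = getOption("bivqa.log", NULL)) {
  if (is.null(file)) return(invisible(NULL))
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), event = event), list(...))
  cat(as.character(canonical_json(rec)), "\n", sep = "", file = file, append = TRUE)
  invisible(NULL)
}
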