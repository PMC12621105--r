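## Closed label spaces shared by every module. The answer space is a single
## global 5-way space for all models; specialisation comes from routing, not
## from restricting per-model label spaces.

.QUESTION_TYPES <- c("WHOLE", "REGION", "FOVEA", "GRADE")
.ANSWER_LABELS <- c("YES", "NO", "GRADE_0", "GRADE_1", "GRADE_2")
.BINARY_ANSWERS <- c("YES", "NO")
.GRADE_ANSWERS <- c("GRADE_0", "GRADE_1", "GRADE_2")

#' Question type and answer label spaces
#'
#' The framework operates over a closed set of four question types (presence in
#' the whole image, in a masked region, in the fovea, and the overall edema
#' grade) and five answers (yes/no for presence questions; grades 0-2 for
#' grading questions, where grade 0 means no hard exudates, grade 1 peripheral
#' exudates only, and grade 2 macular involvement).
#'
#' @return A character vector of label tokens.
#' @examples
#' questionTypes()
#' answerLabels()
#' compatibleAnswers("GRADE")
#' @export
questionTypes <- function() .QUESTION_TYPES

#' @rdname questionTypes
#' @export
answerLabels <- function() .ANSWER_LABELS

#' @rdname questionTypes
#' @param type A question type token.
#' @export
compatibleAnswers <- function(type) {
  type <- asQuestionType(type)
  if (type == "GRADE") .GRADE_ANSWERS else .BINARY_ANSWERS
}

#' Parse label tokens
#'
#' Strict parsers for the closed label spaces: any token outside the space is a
#' contract error, so labels cannot silently leak between spaces.
#'
#' @param x A character token (or vector of tokens).
#' @return The validated token(s), as character.
#' @export
asQuestionType <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .QUESTION_TYPES)
  if (length(bad) > 0)
    contract_error("unknown question type token(s): %s", paste(bad, collapse = ", "))
  x
}

#' @rdname asQuestionType
#' @export
asAnswerLabel <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .ANSWER_LABELS)
  if (length(bad) > 0)
    contract_error("unknown answer label token(s): %s", paste(bad, collapse = ", "))
  x
}

## TRUE iff `answer` is admissible for `type` (GRADE questions take GRADE_*,
## presence questions take YES/NO).
answer_compatible <- function(type, answer) {
  answer %in% if (type == "GRADE") .GRADE_ANSWERS else .BINARY_ANSWERS
}
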