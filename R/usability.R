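#' System Usability Scale scoring
#'
#' Scores a ten-item SUS questionnaire. Items alternate polarity: odd
#' items are positively phrased (higher is better), even items negatively
#' phrased. Each answer is an integer 1..5 and the total score is
#'
#' \deqn{2.5 \times \left( \sum_{odd} (x_i - 1) + \sum_{even} (5 - x_i) \right)}
#'
#' giving a range of exactly 0..100.
#'
#' @param x numeric vector of ten answers in 1..5 (a single respondent),
#'   or a data frame / matrix with ten columns (one row per respondent).
#' @return `sus_score()`: score(s) in `[0, 100]`; `sus_batch()`: the mean
#'   score over all respondents.
#' @examples
#' sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
#' sus_score(rep(3, 10))                       # 50
#' sus_batch(rbind(rep(5, 10), rep(1, 10)))    # 50
#' @export
sus_score <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != 10) stop("need ten items per respondent", call. = FALSE)
    if (nrow(x) == 0) return(numeric(0))
    return(apply(x, 1, sus_score))
  }
  if (length(x) != 10) stop("need ten items", call. = FALSE)
  if (any(!is.finite(x)) || any(x != trunc(x)) || any(x < 1 | x > 5))
    stop("items must be integers in 1..5", call. = FALSE)
  odd <- x[c(1, 3, 5, 7, 9)]
  even <- x[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' @rdname sus_score
#' @export
sus_batch <- function(x) {
  scores <- sus_score(x)
  if (length(scores) == 0) stop("no responses", call. = FALSE)
  mean(scores)
}

#' Read SUS responses from CSV
#'
#' Expects one row per respondent with answer columns `a1..a10` (extra
#' columns such as a respondent id are ignored).
#'
#' @param path CSV file path.
#' @return data frame of the ten answer columns.
#' @export
read_sus_csv <- function(path) {
  d <- read.csv(path)
  cols <- paste0("a", 1:10)
  if (!all(cols %in% names(d)))
    stop("CSV must contain columns a1..a10", call. = FALSE)
  d[cols]
}
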