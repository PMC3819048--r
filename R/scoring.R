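#' Comprehension-test scoring scheme
#'
#' The test has `n_questions` multi-select questions with `n_choices` answer
#' options each; any number of options may be correct, participants are told
#' at least one is, so the admissible selections per question are the
#' non-empty subsets (15 for 4 choices).  A question scores 1 only when the
#' selection equals the key exactly.  Readers scoring at or above
#' `good_cutoff` are good comprehenders.
#'
#' @param n_questions number of questions (default 4).
#' @param n_choices options per question (default 4).
#' @param admissible_patterns allowed selections per question (default
#'   `2^n_choices - 1`).
#' @param good_cutoff minimum good-comprehender score (default 3).
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(n_questions = 4, n_choices = 4,
                           admissible_patterns = 2^n_choices - 1,
                           good_cutoff = 3) {
  stop_if_not(n_questions >= 1, "need at least one question")
  stop_if_not(n_choices >= 1, "need at least one choice")
  stop_if_not(admissible_patterns >= 1, "admissible_patterns must be >= 1")
  stop_if_not(good_cutoff >= 0 && good_cutoff <= n_questions,
              "good_cutoff must lie in [0, n_questions]")
  structure(list(n_questions = n_questions, n_choices = n_choices,
                 admissible_patterns = admissible_patterns,
                 good_cutoff = good_cutoff), class = "scoring_scheme")
}

#' Score a multi-select comprehension test
#'
#' All-or-none per question: a question is correct iff the selected set
#' equals the key set (all correct options and no incorrect ones).
#'
#' @param selections list of per-question selected options (vectors; any
#'   atomic type comparable with the key).
#' @param key list of per-question correct options.
#' @param scheme a [scoring_scheme()].
#' @return integer score in `[0, n_questions]`.
#' @export
score_test <- function(selections, key, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  stop_if_not(length(selections) == scheme$n_questions,
              "expected %d selections, got %d", scheme$n_questions, length(selections))
  stop_if_not(length(key) == scheme$n_questions,
              "expected %d key entries, got %d", scheme$n_questions, length(key))
  if (any(vapply(selections, length, 1L) == 0)) {
    stop("empty selection: participants must select at least one option per question",
         call. = FALSE)
  }
  sum(mapply(function(s, k) setequal(s, k), selections, key))
}

#' Exact chance distribution of the comprehension score
#'
#' Under uniform guessing over the admissible selections (independent across
#' questions) each question is correct with probability
#' `1 / admissible_patterns`, so the score is Binomial(n_questions, 1/15)
#' under the defaults: expectation 4/15 (about 0.27 questions), and scoring
#' 2+ by chance (p = 0.024) is more than 20 times as likely as scoring 3+
#' (p = 0.0011) — the basis for the good/poor cutoff at 3.
#'
#' @param scheme a [scoring_scheme()].
#' @return list with `pmf` (named, scores 0..n), `expectation`, and
#'   `p_upper` — `p_upper[k + 1]` = P(score >= k) for k = 0..n.
#' @export
chance_distribution <- function(scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  n <- scheme$n_questions
  p <- 1 / scheme$admissible_patterns
  pmf <- dbinom(0:n, n, p)
  names(pmf) <- 0:n
  p_upper <- rev(cumsum(rev(pmf)))
  names(p_upper) <- 0:n
  list(pmf = pmf, expectation = n * p, p_upper = p_upper)
}

#' Split subjects into good and poor comprehenders
#'
#' @param scores integer vector of test scores.
#' @param scheme a [scoring_scheme()].
#' @return factor with levels `poor`, `good`; attribute `sizes` holds the
#'   group counts.
#' @export
assign_groups <- function(scores, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  stop_if_not(all(scores >= 0 & scores <= scheme$n_questions),
              "scores must lie in [0, %d]", scheme$n_questions)
  g <- factor(ifelse(scores >= scheme$good_cutoff, "good", "poor"),
              levels = c("poor", "good"))
  attr(g, "sizes") <- table(g)
  g
}
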