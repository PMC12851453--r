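#' Average scores within each relationship
#'
#' Collapses the ragged set of agents in each network into per-factor
#' relationship components: `vertical` (mean of the available parents),
#' `horizontal` (mean of the available friends), `grandparental` (mean of
#' the available grandparents) and `student` (the focal student's own
#' score). A component is `NA` — undefined, not zero — when no contributing
#' role is present; single available members pass through unchanged.
#'
#' @param table A [network_table()].
#' @return Tibble with columns `network_id`, `factor`, `student`,
#'   `vertical`, `horizontal`, `grandparental`.
#' @export
#' @examples
#' tab <- network_table(tibble::tibble(
#'   network_id = "n1",
#'   role = c("student", "mother", "father"),
#'   factor = "Religiosity",
#'   score = c(0.2, 0.4, -0.2)
#' ))
#' aggregate_components(tab) # vertical = 0.1
aggregate_components <- function(table) {
  mean_if_any <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  table |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$network_id, .data$factor) |>
    dplyr::summarise(
      student = mean_if_any(.data$score[.data$role == "student"]),
      vertical = mean_if_any(.data$score[.data$role %in% role_parents()]),
      horizontal = mean_if_any(.data$score[.data$role %in% role_friends()]),
      grandparental =
        mean_if_any(.data$score[.data$role %in% role_grandparents()]),
      .groups = "drop"
    )
}

#' Dichotomise a factor score into a binary trait
#'
#' Factor scores are centred, so zero is the sample mean: a score greater
#' than or equal to the threshold is coded 1 (has the trait — high
#' religiosity, right-wing orientation, ...), below it 0 (has the opposite
#' trait). The opposite-polarity value is always the complement.
#'
#' @param score Numeric vector of finite factor scores.
#' @param threshold Cut point; the conventional and default choice is 0.
#' @param polarity `"trait"` or `"opposite"`.
#' @return Integer vector of 0/1 trait values.
#' @export
#' @examples
#' dichotomize(c(-0.3, 0, 1.7))              # 0 1 1
#' dichotomize(1.7, polarity = "opposite")   # 0
dichotomize <- function(score, threshold = 0,
                        polarity = c("trait", "opposite")) {
  polarity <- match.arg(polarity)
  if (any(!is.finite(score))) {
    stop("dichotomize() requires finite scores; impute missing values first",
         call. = FALSE)
  }
  v <- as.integer(score >= threshold)
  if (polarity == "opposite") v <- 1L - v
  v
}
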