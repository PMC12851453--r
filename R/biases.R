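# negative log-likelihood / error contributions of one binomial cell,
# vectorised over candidate probabilities p (0*log(0) treated as 0)
cell_nll <- function(P, N, p) {
  p <- pmin(pmax(p, 0), 1)
  out <- numeric(length(p))
  if (N > 0) out <- out - N * log(p)
  if (P - N > 0) out <- out - (P - N) * log1p(-p)
  out
}

cell_sse_prop <- function(P, N, p) {
  if (P == 0) return(rep(0, length(p)))
  (N / P - p)^2
}

cell_sse_counts <- function(P, N, p) {
  (N - P * p)^2
}

# objective over the four parental-type cells of one polarity, vectorised
# over (v, h) for a fixed baseline (other) bias
polarity_objective <- function(cells, v, h, other, objective) {
  f <- switch(objective,
    binomial_loglik = cell_nll,
    sse_proportions = cell_sse_prop,
    sse_counts = cell_sse_counts
  )
  # cells ordered VH, Vh, vH, vh
  f(cells$P[1], cells$N[1], other + v + h) +
    f(cells$P[2], cells$N[2], other + v) +
    f(cells$P[3], cells$N[3], other + h) +
    f(cells$P[4], cells$N[4], rep(other, length(v)))
}

polarity_cells <- function(t) {
  lv <- parental_type_levels()
  idx <- match(lv, t$type)
  list(P = t$P[idx], N = t$N[idx])
}

#' Estimate Vertical, Horizontal and Other transmission biases
#'
#' Fits the additive model
#' \deqn{N_{VH} = P_{VH}(O + V + H),\quad N_{Vh} = P_{Vh}(O + V),\quad
#'       N_{vH} = P_{vH}(O + H),\quad N_{vh} = P_{vh}\,O}
#' to the observed parental-type counts by exhaustive grid search. The
#' trait and opposite-trait tables are fitted jointly: the Vertical and
#' Horizontal biases are shared between polarities (the two tables are
#' complementary), while each polarity has its own Other bias. Biases are
#' constrained non-negative with `other + vertical + horizontal <= 1` in
#' each polarity, so every cell probability is a valid Bernoulli
#' parameter.
#'
#' Three objectives are available: `binomial_loglik` (the default —
#' maximises the joint binomial likelihood of the eight cell counts),
#' `sse_proportions` (least squares on the coefficients `B_i`) and
#' `sse_counts` (least squares on the counts `N_i`). Ties on the grid are
#' broken deterministically by the lexicographically smallest
#' `(vertical, horizontal, other_trait, other_opposite)`.
#'
#' @param trait_table Single-polarity [parental_type_table()] (or the
#'   stacked output of [transmission_table()], from which both polarities
#'   are taken).
#' @param opposite_tbl The opposite-polarity table; derived via
#'   [opposite_table()] when omitted.
#' @param objective One of `"binomial_loglik"`, `"sse_proportions"`,
#'   `"sse_counts"`.
#' @param grid_resolution Grid step for all four biases (default 0.01).
#' @return Object of class `bias_estimate`: a list with `vertical`,
#'   `horizontal`, `other_trait`, `other_opposite`, `objective`,
#'   `objective_value` (achieved log-likelihood for `binomial_loglik`,
#'   achieved error otherwise), `grid_resolution`, `factor`.
#' @export
#' @examples
#' t9 <- example_environmentalism_counts()
#' estimate_biases(t9, objective = "sse_proportions")
estimate_biases <- function(trait_table, opposite_tbl = NULL,
                            objective = c("binomial_loglik",
                                          "sse_proportions", "sse_counts"),
                            grid_resolution = 0.01) {
  objective <- match.arg(objective)
  stopifnot(grid_resolution > 0, grid_resolution <= 0.5)
  if (is.null(opposite_tbl) && "polarity" %in% names(trait_table) &&
      all(c("trait", "opposite") %in% trait_table$polarity)) {
    opposite_tbl <- trait_table[trait_table$polarity == "opposite", ]
    trait_table <- trait_table[trait_table$polarity == "trait", ]
  }
  if (is.null(opposite_tbl)) opposite_tbl <- opposite_table(trait_table)
  ct <- polarity_cells(trait_table)
  co <- polarity_cells(opposite_tbl)
  g <- grid_resolution
  K <- floor(1 / g + 1e-9)
  vals <- seq(0, K) * g
  # all (v, h) with v + h <= 1, in lexicographic (v, h) order
  pairs <- tidyr::expand_grid(v = vals, h = vals)
  pairs <- pairs[pairs$v + pairs$h <= 1 + 1e-9, ]
  v <- pairs$v
  h <- pairs$h
  npair <- length(v)
  if (npair == 0) stop("empty feasible grid", call. = FALSE)
  eps <- 1e-12
  best <- function(cells) {
    best_f <- rep(Inf, npair)
    best_o <- rep(NA_real_, npair)
    for (o in vals) {            # ascending: first improvement = smallest o
      f <- polarity_objective(cells, v, h, o, objective)
      f[v + h > 1 - o + 1e-9] <- Inf
      upd <- f < best_f - eps
      best_f[upd] <- f[upd]
      best_o[upd] <- o
    }
    list(f = best_f, o = best_o)
  }
  bt <- best(ct)
  bo <- best(co)
  total <- bt$f + bo$f
  if (!any(is.finite(total))) stop("empty feasible grid", call. = FALSE)
  idx <- which(total < min(total) + eps)[1]
  value <- total[idx]
  structure(
    list(
      vertical = v[idx],
      horizontal = h[idx],
      other_trait = bt$o[idx],
      other_opposite = bo$o[idx],
      objective = objective,
      objective_value = if (objective == "binomial_loglik") -value else value,
      grid_resolution = g,
      factor = unique(c(trait_table$factor, opposite_tbl$factor))[1]
    ),
    class = "bias_estimate"
  )
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<bias estimate: %s>\n  vertical = %.3f  horizontal = %.3f\n",
      "  other (trait) = %.3f  other (opposite) = %.3f\n",
      "  objective %s = %.4f  (grid %.3g)\n"
    ),
    x$factor, x$vertical, x$horizontal, x$other_trait, x$other_opposite,
    x$objective, x$objective_value, x$grid_resolution
  ))
  invisible(x)
}

#' Barycentric triangle coordinates for bias estimates
#'
#' Normalises each polarity's `(vertical, horizontal, other)` triple to
#' sum 1 and maps it into the 2-simplex with corners Vertical = (0, 0),
#' Horizontal = (1, 0) and Other = (0.5, sqrt(3)/2), the conventional
#' triangle rendering of relative bias strength.
#'
#' @param estimates A `bias_estimate` or a list of them.
#' @return Tibble: `factor`, `polarity`, normalised weights `w_vertical`,
#'   `w_horizontal`, `w_other`, and plot coordinates `x`, `y`.
#' @export
triangle_coords <- function(estimates) {
  if (inherits(estimates, "bias_estimate")) estimates <- list(estimates)
  purrr::map_dfr(estimates, function(e) {
    purrr::map_dfr(c("trait", "opposite"), function(pol) {
      o <- if (pol == "trait") e$other_trait else e$other_opposite
      s <- e$vertical + e$horizontal + o
      w <- if (s > 0) c(e$vertical, e$horizontal, o) / s else rep(1 / 3, 3)
      tibble::tibble(
        factor = e$factor, polarity = pol,
        w_vertical = w[1], w_horizontal = w[2], w_other = w[3],
        x = w[2] * 1 + w[3] * 0.5,
        y = w[3] * sqrt(3) / 2
      )
    })
  })
}
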