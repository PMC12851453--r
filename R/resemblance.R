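#' Pearson correlation for a paired score vector
#'
#' Thin, defensive wrapper over the product-moment correlation used
#' throughout the resemblance stage: it refuses degenerate input (fewer
#' than 3 pairs, zero variance) instead of propagating `NA`.
#'
#' @param x,y Equal-length numeric vectors, paired by network.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' pearson_pair(c(1, 2, 3, 4), c(2, 1, 4, 3)) # 0.6
pearson_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must be paired (equal length)", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("need at least 3 complete pairs, got ", length(x), call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pearson_pair() expects complete pairs; drop or impute NAs first",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the paired vectors", call. = FALSE)
  }
  stats::cor(x, y)
}

# aligned complete score pairs for one (role_a, role_b, factor)
aligned_pair_scores <- function(table, role_a, role_b, factor) {
  a <- table[table$role == role_a & table$factor == factor, ]
  b <- table[table$role == role_b & table$factor == factor, ]
  ids <- intersect(a$network_id, b$network_id)
  x <- a$score[match(ids, a$network_id)]
  y <- b$score[match(ids, b$network_id)]
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], network_id = ids[ok])
}

#' Monte-Carlo permutation Resemblance z-score
#'
#' Measures whether two roles' scores are more alike within networks than
#' across them. The veridical Pearson correlation between the aligned
#' pairs is located in a null distribution built by scrambling the pairing:
#' the second role's scores are permuted across networks `n_perm` times
#' (marginals preserved, pairing destroyed) and
#' `z = (r - mean(null)) / sd(null)`. A two-sided Monte-Carlo p-value is
#' reported with the add-one correction
#' `(#\{|null| >= |r|\} + 1) / (n_perm + 1)`, so it can never be exactly
#' zero.
#'
#' @param table A [network_table()].
#' @param pair Character vector of two roles, e.g.
#'   `c("student", "mother")`.
#' @param factor Factor label.
#' @param n_perm Number of scrambled pairings (default 10,000).
#' @param seed Integer seed; results are reproducible given it.
#' @return A one-row tibble: `role_a`, `role_b`, `factor`, `r_veridical`,
#'   `z`, `p_mc`, `n_pairs`, `n_perm`.
#' @export
resemblance_z <- function(table, pair, factor, n_perm = 10000, seed = 1L) {
  stopifnot(length(pair) == 2, n_perm >= 100)
  ap <- aligned_pair_scores(table, pair[1], pair[2], factor)
  n <- length(ap$x)
  if (n < 3) {
    stop("fewer than 3 complete (", pair[1], ", ", pair[2], ") pairs for ",
         factor, " (", n, ")", call. = FALSE)
  }
  r <- pearson_pair(ap$x, ap$y)
  xs <- as.vector(scale(ap$x))
  ys <- as.vector(scale(ap$y))
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(j) {
    sum(xs * ys[sample.int(n)]) / (n - 1)
  }, numeric(1))
  z <- (r - mean(null_r)) / stats::sd(null_r)
  p_mc <- (sum(abs(null_r) >= abs(r)) + 1) / (n_perm + 1)
  tibble::tibble(
    role_a = pair[1], role_b = pair[2], factor = factor,
    r_veridical = r, z = z, p_mc = p_mc,
    n_pairs = n, n_perm = as.integer(n_perm)
  )
}

graph_role_pairs <- function() {
  main <- setdiff(cultnet_roles(), "student_t2")
  pairs <- utils::combn(main, 2, simplify = FALSE)
  c(pairs, list(c("student", "student_t2")))
}

#' Resemblance graph over all role pairs
#'
#' Computes [resemblance_z()] for every pair of roles and every factor,
#' grades each edge into significance tiers (`strong`: z > 3.3; `weak`:
#' 1.96 < z <= 3.3; `none` otherwise) and labels it with its social-tie
#' category (see [edge_category()]). The second questionnaire sitting
#' enters only through the (student, student_t2) reliability pair. Pairs
#' that cannot be tested (too few complete pairs, zero variance) are
#' skipped and logged, not errored.
#'
#' @param table A filtered, imputed [network_table()].
#' @param n_perm Permutations per edge.
#' @param seed Master seed; each edge uses its own derived sub-seed.
#' @param factors Factors to include (default: all in the table).
#' @return List with `edges` (tibble: role pair, factor, r, z, p_mc, tier,
#'   category, n_pairs) and `skipped` (tibble: role pair, factor, reason).
#' @export
resemblance_graph <- function(table, n_perm = 10000, seed = 1L,
                              factors = NULL) {
  factors <- factors %||% factor_labels_of(table)
  jobs <- tidyr::expand_grid(
    pair_idx = seq_along(graph_role_pairs()),
    factor = factors
  )
  pairs <- graph_role_pairs()
  seeds <- network_seeds(seed, nrow(jobs))
  edges <- vector("list", nrow(jobs))
  skipped <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    pr <- pairs[[jobs$pair_idx[i]]]
    res <- tryCatch(
      resemblance_z(table, pr, jobs$factor[i], n_perm = n_perm,
                    seed = seeds[i]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[i]] <- tibble::tibble(
        role_a = pr[1], role_b = pr[2], factor = jobs$factor[i], reason = res
      )
    } else {
      edges[[i]] <- res
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) > 0) {
    edges$tier <- dplyr::case_when(
      edges$z > 3.3 ~ "strong",
      edges$z > 1.96 ~ "weak",
      .default = "none"
    )
    edges$category <- mapply(edge_category, edges$role_a, edges$role_b,
                             USE.NAMES = FALSE)
  }
  list(edges = edges, skipped = dplyr::bind_rows(skipped))
}

#' Per-factor vertical and horizontal correlation summary
#'
#' The conventional two-number summary of dyadic similarity: per factor,
#' the mean of the mother-student and father-student correlations
#' (vertical) and the mean of the friend1-student and friend2-student
#' correlations (horizontal), each constituent computed on the networks
#' where that pair is complete. A constituent that cannot be computed is
#' skipped and logged.
#'
#' @param table A filtered [network_table()].
#' @param factors Factors to summarise (default: all in the table).
#' @return Tibble: `factor`, `vertical`, `horizontal`, plus the number of
#'   constituent correlations each mean is based on; attribute `log` lists
#'   skipped constituents.
#' @export
vertical_horizontal_summary <- function(table, factors = NULL) {
  factors <- factors %||% factor_labels_of(table)
  skipped <- list()
  one <- function(f, roles) {
    rs <- c()
    for (role in roles) {
      ap <- aligned_pair_scores(table, "student", role, f)
      r <- tryCatch(pearson_pair(ap$x, ap$y), error = function(e) {
        skipped[[length(skipped) + 1]] <<- tibble::tibble(
          factor = f, role = role, reason = conditionMessage(e)
        )
        NULL
      })
      if (!is.null(r)) rs <- c(rs, r)
    }
    rs
  }
  out <- purrr::map_dfr(factors, function(f) {
    v <- one(f, role_parents())
    h <- one(f, role_friends())
    tibble::tibble(
      factor = f,
      vertical = if (length(v)) mean(v) else NA_real_,
      horizontal = if (length(h)) mean(h) else NA_real_,
      n_vertical_pairs = length(v),
      n_horizontal_pairs = length(h)
    )
  })
  attr(out, "log") <- dplyr::bind_rows(skipped)
  out
}
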