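parental_type_levels <- function() c("VH", "Vh", "vH", "vh")

# inverse map used when switching polarity: VH <-> vh, Vh <-> vH
inverse_parental_type <- function(type) {
  c(VH = "vh", Vh = "vH", vH = "Vh", vh = "VH")[type]
}

#' Classify a network into a cultural parental type
#'
#' The joint trait status of the network's Vertical component (parents)
#' and Horizontal component (friends): `VH` both have the trait, `Vh` only
#' the parents, `vH` only the friends, `vh` neither.
#'
#' @param vertical_trait,horizontal_trait Binary 0/1 trait values of the
#'   two components (see [dichotomize()]). Vectorised.
#' @return Character vector of types in `c("VH", "Vh", "vH", "vh")`.
#' @export
#' @examples
#' classify_parental_type(1, 1) # "VH"
#' classify_parental_type(1, 0) # "Vh"
classify_parental_type <- function(vertical_trait, horizontal_trait) {
  if (anyNA(vertical_trait) || anyNA(horizontal_trait)) {
    stop("undefined component trait: filter networks to those with at ",
         "least one parent and one friend first", call. = FALSE)
  }
  stopifnot(
    all(vertical_trait %in% c(0, 1)),
    all(horizontal_trait %in% c(0, 1))
  )
  dplyr::case_when(
    vertical_trait == 1 & horizontal_trait == 1 ~ "VH",
    vertical_trait == 1 ~ "Vh",
    horizontal_trait == 1 ~ "vH",
    .default = "vh"
  )
}

#' Build a parental-type table from raw counts
#'
#' The elementary arithmetic of the additive transmission analysis: given
#' the number of networks of each parental type (`P`) and the number of
#' students with the trait in each (`N`), the transmission coefficient is
#' `B = N / P`, the proportion of students with the trait in that type.
#'
#' @param P Named (or `VH, Vh, vH, vh`-ordered) integer vector of network
#'   counts per type.
#' @param N Matching integer vector of students-with-trait counts.
#' @param factor,polarity Labels carried along in the output.
#' @return Tibble: `factor`, `polarity`, `type`, `P`, `N`, `B`. Types with
#'   `P = 0` carry `B = NA`.
#' @export
#' @examples
#' parental_type_table(P = c(156, 119, 122, 185), N = c(111, 61, 66, 71))
parental_type_table <- function(P, N, factor = "trait1",
                                polarity = c("trait", "opposite")) {
  polarity <- match.arg(polarity)
  lv <- parental_type_levels()
  if (is.null(names(P))) names(P) <- lv
  if (is.null(names(N))) names(N) <- lv
  stopifnot(setequal(names(P), lv), setequal(names(N), lv))
  P <- P[lv]; N <- N[lv]
  if (any(N > P) || any(N < 0) || any(P < 0)) {
    stop("need 0 <= N <= P for every parental type", call. = FALSE)
  }
  if (sum(P) == 0) stop("no included networks (all P are zero)", call. = FALSE)
  tibble::tibble(
    factor = factor, polarity = polarity, type = lv,
    P = as.integer(P), N = as.integer(N),
    B = ifelse(P > 0, N / P, NA_real_)
  )
}

# per-network parental type and student trait for one factor;
# requires the parent_and_friend composition
network_types <- function(table, factor, threshold = 0) {
  comp <- aggregate_components(table)
  comp <- comp[comp$factor == factor, ]
  usable <- !is.na(comp$vertical) & !is.na(comp$horizontal) &
    !is.na(comp$student)
  comp <- comp[usable, ]
  if (nrow(comp) == 0) {
    stop("no networks with student, parent and friend scores for ", factor,
         call. = FALSE)
  }
  tibble::tibble(
    network_id = comp$network_id,
    type = classify_parental_type(
      dichotomize(comp$vertical, threshold),
      dichotomize(comp$horizontal, threshold)
    ),
    student_trait = dichotomize(comp$student, threshold)
  )
}

counts_from_types <- function(types, factor) {
  lv <- parental_type_levels()
  P <- vapply(lv, function(t) sum(types$type == t), integer(1))
  N <- vapply(lv, function(t) {
    sum(types$student_trait[types$type == t])
  }, integer(1))
  parental_type_table(P, N, factor = factor, polarity = "trait")
}

#' Transmission coefficients by parental type
#'
#' Dichotomises the student, Vertical and Horizontal component scores of
#' every network with complete components, classifies the networks into
#' parental types, and tabulates `P_i`, `N_i` and `B_i = N_i / P_i` for
#' both the trait and the (complementary) opposite trait.
#'
#' @param table A [network_table()] filtered with the `parent_and_friend`
#'   rule and imputed (scores must be complete for the networks used).
#' @param factor Factor label to tabulate.
#' @param threshold Dichotomisation cut point (default 0, the factor-score
#'   mean).
#' @return Tibble of both polarities stacked (see
#'   [parental_type_table()]).
#' @export
transmission_table <- function(table, factor, threshold = 0) {
  types <- network_types(table, factor, threshold)
  trait <- counts_from_types(types, factor)
  dplyr::bind_rows(trait, opposite_table(trait))
}

#' Opposite-polarity parental-type table
#'
#' Switching polarity relabels everything by its complement: a network
#' whose parents lack the trait has parents with the opposite trait, so
#' type `i` maps to its inverse (`VH <-> vh`, `Vh <-> vH`) and the
#' coefficient to `1 - B`: `B'_VH = 1 - B_vh` with `P'_VH = P_vh`,
#' `N'_VH = P_vh - N_vh`, and so on. Applying the operation twice returns
#' the original table.
#'
#' @param t A single-polarity [parental_type_table()].
#' @return The complementary table of the other polarity.
#' @export
opposite_table <- function(t) {
  stopifnot(length(unique(t$polarity)) == 1)
  lv <- parental_type_levels()
  idx <- match(inverse_parental_type(lv), t$type)
  out <- parental_type_table(
    P = stats::setNames(t$P[idx], lv),
    N = stats::setNames(t$P[idx] - t$N[idx], lv),
    factor = unique(t$factor),
    polarity = if (unique(t$polarity) == "trait") "opposite" else "trait"
  )
  # bitwise-exact complementarity: B' = 1 - B of the inverse type
  out$B <- ifelse(is.na(t$B[idx]), NA_real_, 1 - t$B[idx])
  out
}

#' Bootstrap confidence intervals for transmission coefficients
#'
#' Resamples whole networks with replacement `n_boot` times, recomputes
#' the parental-type counts and coefficients in each resample, and takes
#' the 2.5th/97.5th percentiles of each `B_i` as its 95% interval. Types
#' empty in the original data get `NA` bounds and are flagged.
#'
#' @param table A [network_table()] (filtered, imputed).
#' @param factor Factor label.
#' @param n_boot Number of resamples (at least 200; default 10,000).
#' @param seed Integer seed; intervals are reproducible given it.
#' @param threshold Dichotomisation cut point.
#' @param level Confidence level (default 0.95).
#' @return [transmission_table()] output with `ci_low` and `ci_high`
#'   columns added.
#' @export
bootstrap_ci <- function(table, factor, n_boot = 10000, seed = 1L,
                         threshold = 0, level = 0.95) {
  stopifnot(n_boot >= 200)
  types <- network_types(table, factor, threshold)
  trait_obs <- counts_from_types(types, factor)
  observed <- dplyr::bind_rows(trait_obs, opposite_table(trait_obs))
  lv <- parental_type_levels()
  type_id <- match(types$type, lv)
  n <- nrow(types)
  set.seed(seed)
  # per resample and type: networks drawn (P*) and trait-holders drawn (N*)
  boot_b <- matrix(NA_real_, nrow = n_boot, ncol = 4)
  for (j in seq_len(n_boot)) {
    take <- sample.int(n, n, replace = TRUE)
    P <- tabulate(type_id[take], nbins = 4)
    Nn <- tabulate(type_id[take][types$student_trait[take] == 1L], nbins = 4)
    boot_b[j, ] <- ifelse(P > 0, Nn / P, NA_real_)
  }
  alpha <- (1 - level) / 2
  ci <- function(type, polarity) {
    k <- match(type, lv)
    b <- if (polarity == "trait") {
      boot_b[, k]
    } else {
      1 - boot_b[, match(inverse_parental_type(type), lv)]
    }
    if (observed$P[observed$type == type &
                   observed$polarity == polarity] == 0) {
      return(c(NA_real_, NA_real_))
    }
    stats::quantile(b, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  }
  bounds <- t(mapply(ci, observed$type, observed$polarity, USE.NAMES = FALSE))
  observed$ci_low <- unname(bounds[, 1])
  observed$ci_high <- unname(bounds[, 2])
  attr(observed, "n_boot") <- as.integer(n_boot)
  observed
}

#' Worked-example parental-type counts (environmentalism factor)
#'
#' A published worked example of the parental-type tabulation for an
#' environmentalism-attitudes factor in 582 student networks, used in the
#' package's tests and documentation: `P = (156, 119, 122, 185)` networks
#' and `N = (111, 61, 66, 71)` trait-holding students for types
#' `VH, Vh, vH, vh`, giving `B = (0.712, 0.513, 0.541, 0.384)`.
#'
#' @return Tibble of both polarities (see [parental_type_table()]).
#' @export
#' @examples
#' example_environmentalism_counts()
example_environmentalism_counts <- function() {
  trait <- parental_type_table(
    P = c(VH = 156L, Vh = 119L, vH = 122L, vh = 185L),
    N = c(VH = 111L, Vh = 61L, vH = 66L, vh = 71L),
    factor = "Environmentalism", polarity = "trait"
  )
  dplyr::bind_rows(trait, opposite_table(trait))
}
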