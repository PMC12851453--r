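#' Configuration for the synthetic network generator
#'
#' Collects every knob of the generator in one validated object. Defaults
#' describe a population resembling the kind of survey this pipeline is
#' designed for: ~half the networks contain a mother, fewer a father,
#' grandparent participation is sparse, both friends are recruited about
#' half the time, and roughly 2% of scores are missing.
#'
#' @param n_networks Number of networks to generate.
#' @param role_presence Named numeric vector of per-role inclusion
#'   probabilities; `student` must be 1. See [default_role_presence()].
#' @param biases Per-factor transmission biases used by
#'   [generate_binary_population()]: a named list of lists with elements
#'   `vertical`, `horizontal` (probability increments) and `other_trait`,
#'   `other_opposite` (baseline adoption probabilities). For every factor
#'   `other_trait + vertical + horizontal` and
#'   `other_opposite + vertical + horizontal` must lie in [0, 1].
#' @param trait_prevalence Length-2 numeric: marginal probability that the
#'   vertical resp. horizontal component has the trait. Default c(0.5, 0.5),
#'   matching dichotomisation of centred scores at their mean.
#' @param parent_friend_corr Phi coefficient between the vertical-component
#'   and horizontal-component trait indicators (the "clustered network"
#'   knob).
#' @param couple_concordance,friend_concordance Probability that the second
#'   member of a couple / friend pair carries the same trait value as the
#'   component it belongs to. 1 (the default) makes both members identical
#'   to the component; lower values add within-relationship noise and
#'   attenuate how cleanly the component trait can be read off the members.
#' @param corr_targets Square correlation matrix over [cultnet_roles()]
#'   used by [generate_continuous_population()]; see
#'   [default_corr_targets()].
#' @param missing_rate Fraction of generated scores set missing completely
#'   at random, in [0, 0.5).
#' @param factors Factor labels to generate.
#' @param seed Integer master seed. Each network draws from its own
#'   deterministic sub-stream, so enlarging `n_networks` leaves earlier
#'   networks unchanged.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_networks = 200,
                             role_presence = default_role_presence(),
                             biases = default_biases(),
                             trait_prevalence = c(0.5, 0.5),
                             parent_friend_corr = 0.2,
                             couple_concordance = 1,
                             friend_concordance = 1,
                             corr_targets = default_corr_targets(),
                             missing_rate = 0.02,
                             factors = cultnet_factors(),
                             seed = 1L) {
  stopifnot(
    is.numeric(n_networks), length(n_networks) == 1, n_networks >= 1,
    is.numeric(missing_rate), missing_rate >= 0, missing_rate < 0.5,
    is.numeric(seed), length(seed) == 1,
    length(trait_prevalence) == 2,
    all(trait_prevalence > 0), all(trait_prevalence < 1),
    parent_friend_corr >= -1, parent_friend_corr <= 1,
    couple_concordance >= 0, couple_concordance <= 1,
    friend_concordance >= 0, friend_concordance <= 1
  )
  roles <- cultnet_roles()
  if (!all(roles %in% names(role_presence))) {
    stop("role_presence must name every role", call. = FALSE)
  }
  if (role_presence[["student"]] != 1) {
    stop("role_presence['student'] must be 1", call. = FALSE)
  }
  if (any(role_presence < 0 | role_presence > 1)) {
    stop("role_presence values must be probabilities", call. = FALSE)
  }
  if (!all(factors %in% names(biases))) {
    stop("biases must be supplied for every factor", call. = FALSE)
  }
  for (f in factors) {
    b <- biases[[f]]
    need <- c("vertical", "horizontal", "other_trait", "other_opposite")
    if (!all(need %in% names(b))) {
      stop("biases[['", f, "']] must contain ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    vals <- unlist(b[need])
    if (any(vals < 0)) {
      stop("biases for '", f, "' must be non-negative", call. = FALSE)
    }
    if (b$other_trait + b$vertical + b$horizontal > 1 ||
        b$other_opposite + b$vertical + b$horizontal > 1) {
      stop("biases for '", f, "' imply an adoption probability above 1 ",
           "in parental type VH", call. = FALSE)
    }
  }
  # joint (v, h) Bernoulli table must be a valid distribution
  jt <- bernoulli_joint(trait_prevalence[1], trait_prevalence[2],
                        parent_friend_corr)
  if (any(jt < -1e-12)) {
    stop("parent_friend_corr = ", parent_friend_corr,
         " is infeasible for trait_prevalence (",
         paste(trait_prevalence, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.matrix(corr_targets) ||
      !identical(dim(corr_targets), c(length(roles), length(roles)))) {
    stop("corr_targets must be a ", length(roles), "x", length(roles),
         " matrix over cultnet_roles()", call. = FALSE)
  }
  dimnames(corr_targets) <- list(roles, roles)
  check_corr_feasible(corr_targets)
  structure(
    list(
      n_networks = as.integer(n_networks),
      role_presence = role_presence[roles],
      biases = biases,
      trait_prevalence = trait_prevalence,
      parent_friend_corr = parent_friend_corr,
      couple_concordance = couple_concordance,
      friend_concordance = friend_concordance,
      corr_targets = corr_targets,
      missing_rate = missing_rate,
      factors = factors,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Default role-inclusion probabilities
#'
#' Loosely calibrated to typical recruitment in student-centred network
#' surveys: mothers participate more often than fathers, friends are
#' recruited about half the time each, grandparents rarely, and most
#' students complete the questionnaire a second time.
#'
#' @return Named numeric vector over [cultnet_roles()].
#' @export
default_role_presence <- function() {
  c(
    student = 1, student_t2 = 0.8,
    mother = 0.45, father = 0.37,
    friend1 = 0.5, friend2 = 0.45,
    maternal_grandmother = 0.14, maternal_grandfather = 0.08,
    paternal_grandmother = 0.07, paternal_grandfather = 0.05
  )
}

#' Default per-factor generating biases
#'
#' Magnitudes span the range typically seen for strongly vertically
#' transmitted factors (religiosity-like: large vertical bias) down to
#' factors dominated by outside sources (music-like: large other bias).
#'
#' @return Named list over [cultnet_factors()].
#' @export
default_biases <- function() {
  mk <- function(v, h, ot, oo) {
    list(vertical = v, horizontal = h, other_trait = ot, other_opposite = oo)
  }
  list(
    Religiosity = mk(0.42, 0.18, 0.10, 0.30),
    Politics = mk(0.19, 0.21, 0.14, 0.46),
    Environmentalism = mk(0.22, 0.18, 0.33, 0.27),
    Health = mk(0.08, 0.21, 0.36, 0.35),
    Music = mk(0.07, 0.00, 0.70, 0.23),
    Reading = mk(0.08, 0.04, 0.36, 0.56),
    Screen = mk(0.09, 0.22, 0.45, 0.24),
    Social = mk(0.07, 0.15, 0.51, 0.27)
  )
}

#' Default role-pair correlation targets
#'
#' A positive-definite correlation structure over the ten roles with the
#' qualitative ordering such surveys show: highest for the student's two
#' sittings and within couples, strong parent-student and lineage
#' grandparent-parent ties, moderate friend-student ties, weak correlation
#' between agents with no direct social link.
#'
#' @return 10x10 symmetric correlation matrix over [cultnet_roles()].
#' @export
default_corr_targets <- function() {
  roles <- cultnet_roles()
  m <- matrix(0.10, length(roles), length(roles),
              dimnames = list(roles, roles))
  set <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set("student", "student_t2", 0.85)
  set("student", "mother", 0.35); set("student", "father", 0.35)
  set("student", "friend1", 0.30); set("student", "friend2", 0.30)
  for (gp in role_grandparents()) set("student", gp, 0.20)
  set("student_t2", "mother", 0.30); set("student_t2", "father", 0.30)
  set("student_t2", "friend1", 0.26); set("student_t2", "friend2", 0.26)
  for (gp in role_grandparents()) set("student_t2", gp, 0.17)
  set("mother", "father", 0.50)
  set("mother", "maternal_grandmother", 0.35)
  set("mother", "maternal_grandfather", 0.35)
  set("father", "paternal_grandmother", 0.35)
  set("father", "paternal_grandfather", 0.35)
  set("mother", "paternal_grandmother", 0.12)
  set("mother", "paternal_grandfather", 0.12)
  set("father", "maternal_grandmother", 0.12)
  set("father", "maternal_grandfather", 0.12)
  for (p in role_parents()) {
    set(p, "friend1", 0.15); set(p, "friend2", 0.15)
  }
  set("friend1", "friend2", 0.25)
  set("maternal_grandmother", "maternal_grandfather", 0.55)
  set("paternal_grandmother", "paternal_grandfather", 0.55)
  diag(m) <- 1
  m
}

# joint distribution of two Bernoullis with given marginals and phi
# coefficient; returns c(p00, p01, p10, p11) (v-major: p_vh)
bernoulli_joint <- function(p_v, p_h, phi) {
  p11 <- p_v * p_h + phi * sqrt(p_v * (1 - p_v) * p_h * (1 - p_h))
  c(
    p00 = 1 - p_v - p_h + p11,
    p01 = p_h - p11,
    p10 = p_v - p11,
    p11 = p11
  )
}

# error if the target correlation matrix is not positive semi-definite,
# naming the off-diagonal pair whose removal most restores feasibility
check_corr_feasible <- function(m) {
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev >= -1e-8) return(invisible(TRUE))
  roles <- rownames(m)
  best <- c(NA, NA)
  best_ev <- ev
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      m2 <- m
      m2[i, j] <- m2[j, i] <- 0
      e2 <- min(eigen(m2, symmetric = TRUE, only.values = TRUE)$values)
      if (e2 > best_ev) {
        best_ev <- e2
        best <- c(roles[i], roles[j])
      }
    }
  }
  stop("corr_targets is not positive semi-definite (min eigenvalue ",
       signif(ev, 3), "); the (", best[1], ", ", best[2],
       ") target is the most implausible entry", call. = FALSE)
}

# deterministic per-network sub-stream seeds (Lehmer-style spreading);
# stays within double precision and below 2^31
network_seeds <- function(seed, n) {
  m <- 2147483647
  base <- ((as.double(seed) %% m) + m) %% m
  s <- (base + seq_len(n)) %% m
  s <- (s * 48271) %% m
  as.integer((s %% (m - 1)) + 1)
}

draw_present_roles <- function(presence) {
  roles <- names(presence)
  u <- stats::runif(length(presence))
  roles[u < presence]
}

#' Generate a population of networks with binary trait values
#'
#' Forward-simulates the additive transmission process: per network and
#' factor, the vertical component (parents) carries the trait with
#' probability `trait_prevalence[1]` and the horizontal component (friends)
#' with probability `trait_prevalence[2]`, correlated at
#' `parent_friend_corr`; the student then adopts the trait with probability
#' `other_trait + vertical * v + horizontal * h`. Members of a couple /
#' friend pair copy their component's value with the configured
#' concordance; grandparents follow their lineage's parent value.
#'
#' Trait values are emitted as scores in \{-1, +1\} so that
#' [dichotomize()]ing at 0 recovers the trait exactly.
#'
#' @param config A [generator_config()].
#' @return List with `table` (a [network_table()]) and `truth` (the
#'   generating biases, prevalences and correlation, plus realised
#'   parental-type counts per factor).
#' @export
generate_binary_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  jt <- bernoulli_joint(config$trait_prevalence[1],
                        config$trait_prevalence[2],
                        config$parent_friend_corr)
  jt <- pmax(jt, 0)
  n <- config$n_networks
  seeds <- network_seeds(config$seed, n)
  factors <- config$factors
  nf <- length(factors)
  type_counts <- matrix(0L, nrow = nf, ncol = 4,
                        dimnames = list(factors, c("vh", "vH", "Vh", "VH")))
  # agents whose value is copied (with concordance noise) from v resp. h
  v_roles <- c("mother", "father", role_grandparents())
  h_roles <- role_friends()
  roles_out <- c("student", "student_t2", v_roles[1:2], h_roles, v_roles[-(1:2)])
  net_ids <- sprintf("net%05d", seq_len(n))
  slot_role <- vector("list", n * nf)
  slot_score <- vector("list", n * nf)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    present <- draw_present_roles(config$role_presence)
    for (k in seq_len(nf)) {
      b <- config$biases[[factors[k]]]
      cell <- sample.int(4L, 1L, prob = jt)        # 1=00, 2=01, 3=10, 4=11
      v <- as.integer(cell >= 3L)
      h <- as.integer(cell == 2L || cell == 4L)
      type_counts[k, 1L + h + 2L * v] <- type_counts[k, 1L + h + 2L * v] + 1L
      student <- stats::rbinom(1, 1, b$other_trait +
                                 b$vertical * v + b$horizontal * h)
      flips <- stats::runif(8) >= c(rep(config$couple_concordance, 2),
                                    rep(config$friend_concordance, 2),
                                    rep(config$couple_concordance, 4))
      base <- c(v, v, h, h, v, v, v, v)
      vals <- c(student, student, ifelse(flips, 1L - base, base))
      names(vals) <- roles_out
      use <- roles_out %in% present
      slot <- (i - 1L) * nf + k
      slot_role[[slot]] <- roles_out[use]
      slot_score[[slot]] <- 2 * as.double(vals[use]) - 1
    }
  }
  lens <- lengths(slot_role)
  table <- network_table(
    tibble::tibble(
      network_id = rep(rep(net_ids, each = nf), lens),
      role = unlist(slot_role, use.names = FALSE),
      factor = rep(rep(factors, times = n), lens),
      score = unlist(slot_score, use.names = FALSE)
    ),
    factor_labels = factors
  )
  truth <- list(
    kind = "binary",
    biases = config$biases[factors],
    trait_prevalence = config$trait_prevalence,
    parent_friend_corr = config$parent_friend_corr,
    couple_concordance = config$couple_concordance,
    friend_concordance = config$friend_concordance,
    parental_type_counts = type_counts,
    n_networks = config$n_networks,
    seed = config$seed
  )
  list(table = table, truth = truth)
}

#' Generate a population of networks with continuous factor scores
#'
#' Draws each network's role scores from a zero-mean, unit-variance
#' multivariate Gaussian whose pairwise correlations equal
#' `config$corr_targets` (a Gaussian-copula construction with normal
#' margins). Roles are then thinned according to `role_presence` and
#' scores knocked out completely at random at `missing_rate`.
#'
#' @param config A [generator_config()].
#' @return List with `table` (a [network_table()], possibly containing
#'   `NA` scores) and `truth` (the correlation targets and missingness
#'   rate).
#' @export
generate_continuous_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  roles <- cultnet_roles()
  m <- config$corr_targets
  ed <- eigen(m, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
  seeds <- network_seeds(config$seed, config$n_networks)
  factors <- config$factors
  rows <- vector("list", config$n_networks)
  for (i in seq_len(config$n_networks)) {
    set.seed(seeds[i])
    present <- draw_present_roles(config$role_presence)
    net <- sprintf("net%05d", i)
    z <- matrix(stats::rnorm(length(roles) * length(factors)),
                nrow = length(roles))
    scores <- L %*% z  # roles x factors, correlated within each factor
    rownames(scores) <- roles
    df <- tidyr::expand_grid(role = present, factor = factors)
    df$score <- scores[cbind(match(df$role, roles), match(df$factor, factors))]
    if (config$missing_rate > 0) {
      df$score[stats::runif(nrow(df)) < config$missing_rate] <- NA_real_
    }
    df$network_id <- net
    rows[[i]] <- df[, c("network_id", "role", "factor", "score")]
  }
  table <- network_table(dplyr::bind_rows(rows), factor_labels = factors)
  truth <- list(
    kind = "continuous",
    corr_targets = m,
    missing_rate = config$missing_rate,
    n_networks = config$n_networks,
    seed = config$seed
  )
  list(table = table, truth = truth)
}
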