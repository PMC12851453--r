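test_that("pearson_pair matches hand computations and rejects degenerate input", {
  expect_equal(pearson_pair(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_pair(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_pair(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_pair(1:2, 1:2), "at least 3")
  expect_error(pearson_pair(1:4, 2:4), "equal length")
  expect_error(pearson_pair(1:4, rep(1, 4)), "zero variance")
  expect_error(pearson_pair(c(1, NA, 3), c(1, 2, 3)), "complete")
})

test_that("resemblance_z is reproducible and pairs are aligned per network", {
  set.seed(5)
  tab <- paired_table(rnorm(40), rnorm(40))
  a <- resemblance_z(tab, c("student", "mother"), "Religiosity",
                     n_perm = 500, seed = 9)
  b <- resemblance_z(tab, c("student", "mother"), "Religiosity",
                     n_perm = 500, seed = 9)
  expect_identical(a, b)
  expect_equal(a$n_pairs, 40)
  expect_true(a$p_mc > 0 && a$p_mc <= 1)
})

test_that("resemblance_z errors on constant scores and on too few pairs", {
  tab <- paired_table(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_error(
    resemblance_z(tab, c("student", "mother"), "Religiosity", n_perm = 100),
    "zero variance"
  )
  small <- paired_table(c(1, 2), c(2, 1))
  expect_error(
    resemblance_z(small, c("student", "mother"), "Religiosity", n_perm = 100),
    "fewer than 3"
  )
})

test_that("z is invariant under positive affine transforms of either variable", {
  set.seed(6)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  z1 <- resemblance_z(paired_table(x, y), c("student", "mother"),
                      "Religiosity", n_perm = 2000, seed = 4)$z
  z2 <- resemblance_z(paired_table(2 * x + 1, y), c("student", "mother"),
                      "Religiosity", n_perm = 2000, seed = 4)$z
  z3 <- resemblance_z(paired_table(x, 10 * y - 3), c("student", "mother"),
                      "Religiosity", n_perm = 2000, seed = 4)$z
  expect_equal(z1, z2)
  expect_equal(z1, z3)
})

test_that("z is symmetric in the role pair up to permutation noise", {
  set.seed(7)
  x <- rnorm(120)
  y <- 0.4 * x + rnorm(120)
  tab <- paired_table(x, y)
  z_ab <- resemblance_z(tab, c("student", "mother"), "Religiosity",
                        n_perm = 4000, seed = 11)$z
  z_ba <- resemblance_z(tab, c("mother", "student"), "Religiosity",
                        n_perm = 4000, seed = 12)$z
  expect_lt(abs(z_ab - z_ba), 0.4)
})

test_that("Monte-Carlo z approaches the exhaustive-enumeration z", {
  set.seed(8)
  x <- rnorm(6)
  y <- rnorm(6)
  z_exact <- exact_resemblance_z(x, y)
  tab <- paired_table(x, y)
  for (s in 1:5) {
    z_mc <- resemblance_z(tab, c("student", "mother"), "Religiosity",
                          n_perm = 10000, seed = s)$z
    expect_lt(abs(z_mc - z_exact), 0.15)
  }
})

test_that("the resemblance graph grades tiers, categorises ties and logs skips", {
  rp <- default_role_presence()
  rp[c("mother", "father", "friend1", "friend2")] <- 1
  rp[c("maternal_grandmother", "maternal_grandfather",
       "paternal_grandmother", "paternal_grandfather")] <- 0
  m <- default_corr_targets()
  m["student", "mother"] <- m["mother", "student"] <- 0.6
  cfg <- generator_config(n_networks = 500, seed = 41,
                          factors = "Religiosity",
                          biases = default_biases()["Religiosity"],
                          corr_targets = m, missing_rate = 0,
                          role_presence = rp)
  pop <- generate_continuous_population(cfg)$table
  g <- resemblance_graph(pop, n_perm = 1000, seed = 3)
  sm <- g$edges[g$edges$role_a == "student" & g$edges$role_b == "mother", ]
  expect_equal(sm$tier, "strong")
  expect_equal(sm$category, "direct_vertical")
  expect_true(all(g$edges$tier[g$edges$z > 3.3] == "strong"))
  expect_true(all(g$edges$tier[g$edges$z <= 1.96] == "none"))
  # grandparents absent everywhere: those pairs are skipped with a reason
  expect_true(any(grepl("maternal_grandmother", g$skipped$role_a) |
                    grepl("maternal_grandmother", g$skipped$role_b)))
  expect_true(all(nchar(g$skipped$reason) > 0))
})

test_that("edge categories follow the social-tie taxonomy", {
  expect_equal(edge_category("student", "father"), "direct_vertical")
  expect_equal(edge_category("maternal_grandfather", "mother"),
               "direct_vertical")
  expect_equal(edge_category("paternal_grandmother", "student"),
               "indirect_vertical")
  expect_equal(edge_category("friend2", "student"), "horizontal")
  expect_equal(edge_category("mother", "father"), "horizontal")
  expect_equal(edge_category("paternal_grandmother", "paternal_grandfather"),
               "horizontal")
  # in-law and unlinked pairs
  expect_equal(edge_category("maternal_grandmother", "father"), "other")
  expect_equal(edge_category("friend1", "mother"), "other")
  expect_equal(edge_category("friend1", "friend2"), "other")
})

test_that("vertical/horizontal summary averages the constituent correlations", {
  set.seed(9)
  ids <- sprintf("n%03d", 1:60)
  x <- rnorm(60)
  tab <- network_table(dplyr::bind_rows(
    tibble::tibble(network_id = ids, role = "student",
                   factor = "Health", score = x),
    tibble::tibble(network_id = ids, role = "mother",
                   factor = "Health", score = 0.8 * x + rnorm(60, sd = 0.4)),
    tibble::tibble(network_id = ids, role = "father",
                   factor = "Health", score = 0.3 * x + rnorm(60)),
    tibble::tibble(network_id = ids, role = "friend1",
                   factor = "Health", score = 0.5 * x + rnorm(60))
  ))
  vh <- vertical_horizontal_summary(tab)
  r_m <- cor(x, tab$score[tab$role == "mother"])
  r_f <- cor(x, tab$score[tab$role == "father"])
  r_f1 <- cor(x, tab$score[tab$role == "friend1"])
  expect_equal(vh$vertical, (r_m + r_f) / 2)
  expect_equal(vh$horizontal, r_f1) # single available constituent
  expect_equal(vh$n_horizontal_pairs, 1)
  # absent friends entirely -> horizontal undefined and logged
  no_friends <- network_table(tab[tab$role != "friend1", ])
  vh2 <- vertical_horizontal_summary(no_friends)
  expect_true(is.na(vh2$horizontal))
  expect_gt(nrow(attr(vh2, "log")), 0)
})

test_that("horizontal summary recovers the generating friend-student correlation", {
  rp <- default_role_presence()
  rp[c("friend1", "friend2")] <- 1
  m <- default_corr_targets()
  for (fr in c("friend1", "friend2")) {
    m["student", fr] <- m[fr, "student"] <- 0.41
  }
  cfg <- generator_config(n_networks = 2500, seed = 43,
                          factors = "Religiosity",
                          biases = default_biases()["Religiosity"],
                          corr_targets = m, missing_rate = 0,
                          role_presence = rp)
  pop <- generate_continuous_population(cfg)$table
  vh <- vertical_horizontal_summary(pop)
  se <- 1 / sqrt(2500 - 3)
  expect_lt(abs(atanh(vh$horizontal) - atanh(0.41)), 3 * se)
})
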