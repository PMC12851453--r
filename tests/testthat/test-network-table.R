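test_that("CSV round-trip reproduces records exactly, including missing scores", {
  tab <- network_table(dplyr::bind_rows(
    net_rows("n1", c(student = 0.21, mother = -0.4)),
    net_rows("n1", c(student = 1.5, mother = NA), factor = "Politics"),
    net_rows("n2", c(student = -0.7, friend1 = 0.3))
  ))
  csv <- withr::local_tempfile(fileext = ".csv")
  sidecar <- withr::local_tempfile(fileext = ".json")
  write_network_table(tab, csv, sidecar = sidecar)
  back <- read_network_table(csv)
  expect_equal(
    as.data.frame(back[order(back$network_id, back$role, back$factor), ]),
    as.data.frame(tab[order(tab$network_id, tab$role, tab$factor), ]),
    ignore_attr = TRUE
  )
  info <- jsonlite::read_json(sidecar)
  expect_equal(info$n_records, 6)
  expect_equal(info$n_missing, 1)
})

test_that("unknown roles are dropped with a warning and counted", {
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(
    net_rows("n1", c(student = 0.2, mother = 0.1)),
    tibble::tibble(network_id = "n1", role = "aunt",
                   factor = "Religiosity", score = 0.5)
  ), csv)
  expect_warning(tab <- read_network_table(csv), "aunt")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "log")$n_dropped_unknown_role, 1)
})

test_that("duplicate keys and malformed rows are rejected with locations", {
  dup <- dplyr::bind_rows(
    net_rows("n1", c(student = 0.2, mother = 0.1)),
    net_rows("n1", c(mother = 0.9))
  )
  expect_error(network_table(dup), "duplicate.*mother.*Religiosity")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("network_id,role,factor,score",
               "n1,student,Religiosity,0.2",
               "n1,mother,Religiosity,abc"), csv)
  expect_error(read_network_table(csv), "malformed rows.*2")
})

test_that("a custom schema maps nonstandard column names", {
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(net = "n1", who = c("student", "father"),
                   dim = "Health", val = c(0.3, -0.1)),
    csv
  )
  tab <- read_network_table(csv, schema = c(network_id = "net", role = "who",
                                            factor = "dim", score = "val"))
  expect_equal(sort(tab$role), c("father", "student"))
})

test_that("networks without a student are rejected", {
  expect_error(network_table(net_rows("n1", c(mother = 0.5))), "student")
})

test_that("filter rules retain the right network compositions", {
  tab <- network_table(dplyr::bind_rows(
    net_rows("solo", c(student = 0.1)),
    net_rows("retest", c(student = 0.1, student_t2 = 0.2)),
    net_rows("pf", c(student = 0.1, mother = 0.2, friend1 = -0.3)),
    net_rows("p_only", c(student = 0.1, father = 0.2)),
    net_rows("pfg", c(student = 0.1, mother = 0.2, friend2 = 0.4,
                      maternal_grandmother = 0.6))
  ))
  any_rule <- filter_networks(tab, "student_plus_any")
  # a lone student, even with a second sitting, is excluded
  expect_setequal(unique(any_rule$network_id), c("pf", "p_only", "pfg"))
  expect_equal(attr(any_rule, "log")$n_excluded, 2)

  pf <- filter_networks(tab, "parent_and_friend")
  expect_setequal(unique(pf$network_id), c("pf", "pfg"))
  pfg <- filter_networks(tab, "parent_friend_and_grandparent")
  expect_equal(unique(pfg$network_id), "pfg")
  expect_error(filter_networks(tab, "everything"), "arg")
})

test_that("stricter filters select subsets of looser ones", {
  pop <- generate_continuous_population(
    generator_config(n_networks = 150, seed = 42)
  )$table
  ids <- function(rule) unique(filter_networks(pop, rule)$network_id)
  expect_true(all(ids("parent_and_friend") %in% ids("student_plus_any")))
  expect_true(all(ids("parent_friend_and_grandparent") %in%
                    ids("parent_and_friend")))
})

test_that("filtering an empty table returns an empty table with zero counts", {
  empty <- network_table(tibble::tibble(
    network_id = character(), role = character(),
    factor = character(), score = double()
  ))
  out <- filter_networks(empty, "student_plus_any")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "log")$n_retained, 0)
  expect_equal(attr(out, "log")$n_excluded, 0)
})

test_that("column-mean imputation fills gaps with the factor mean", {
  tab <- network_table(tibble::tibble(
    network_id = c("n1", "n1", "n1", "n2", "n2"),
    role = c("student", "mother", "friend1", "student", "mother"),
    factor = "Health",
    score = c(0.4, -0.2, NA, 0.8, 0.2)
  ))
  out <- impute_missing(tab)
  # hand-computed mean of the four observed scores
  expect_equal(out$score[3], (0.4 - 0.2 + 0.8 + 0.2) / 4)
  expect_equal(attr(out, "log")$n_imputed$Health, 2 - 1)
})

test_that("imputation is a no-op on complete tables and rejects hopeless ones", {
  complete <- network_table(net_rows("n1", c(student = 0.1, mother = 0.2)))
  expect_equal(as.data.frame(impute_missing(complete)),
               as.data.frame(complete), ignore_attr = TRUE)

  all_missing <- network_table(tibble::tibble(
    network_id = "n1", role = c("student", "mother"),
    factor = "Music", score = c(NA_real_, NA_real_)
  ))
  expect_error(impute_missing(all_missing), "no observed scores")

  half_missing <- network_table(tibble::tibble(
    network_id = c("n1", "n1", "n2", "n2"),
    role = c("student", "mother", "student", "mother"),
    factor = "Music", score = c(0.2, NA, NA, 0.4)
  ))
  expect_error(impute_missing(half_missing), "50%")
})

test_that("a custom imputer function is honoured", {
  tab <- network_table(tibble::tibble(
    network_id = c("n1", "n1", "n2"),
    role = c("student", "mother", "student"),
    factor = "Music", score = c(0.2, NA, 0.6)
  ))
  out <- impute_missing(tab, method = function(x, seed) {
    x[is.na(x)] <- -99
    x
  })
  expect_equal(out$score[2], -99)
})
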