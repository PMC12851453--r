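#' Build a validated network table
#'
#' The central data structure of the package: one row per
#' (network, role, factor) holding that agent's factor score. Networks are
#' ragged — most contain only a subset of the ten roles — and scores may be
#' missing (`NA`) before imputation.
#'
#' @param data Data frame with columns `network_id`, `role`, `factor`,
#'   `score`.
#' @param factor_labels Ordered character vector of factor labels; defaults
#'   to the factors present in `data` (or [cultnet_factors()] order where
#'   they match).
#' @return A tibble of class `cultnet_table` with columns
#'   `network_id` (character), `role` (character), `factor` (character),
#'   `score` (double).
#' @export
network_table <- function(data, factor_labels = NULL) {
  needed <- c("network_id", "role", "factor", "score")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("network table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    network_id = as.character(data$network_id),
    role = as.character(data$role),
    factor = as.character(data$factor),
    score = as.double(data$score)
  )
  bad_role <- !out$role %in% cultnet_roles()
  if (any(bad_role)) {
    stop("unknown roles: ", paste(unique(out$role[bad_role]), collapse = ", "),
         " (use read_network_table() to drop them with a warning)",
         call. = FALSE)
  }
  key <- paste(out$network_id, out$role, out$factor, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (network_id, role, factor) key: ",
         paste(utils::head(gsub("\r", ", ", key[dup]), 3), collapse = "; "),
         call. = FALSE)
  }
  no_student <- setdiff(out$network_id, out$network_id[out$role == "student"])
  if (length(no_student) > 0) {
    stop("networks without a student role: ",
         paste(utils::head(no_student, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(factor_labels)) {
    present <- unique(out$factor)
    canon <- cultnet_factors()
    factor_labels <- c(intersect(canon, present), setdiff(present, canon))
  }
  structure(out,
    factor_labels = factor_labels,
    class = c("cultnet_table", class(out))
  )
}

#' @export
print.cultnet_table <- function(x, ...) {
  cat(sprintf(
    "<cultnet network table> %d records, %d networks, %d factors\n",
    nrow(x), dplyr::n_distinct(x$network_id),
    length(attr(x, "factor_labels"))
  ))
  NextMethod()
}

factor_labels_of <- function(table) {
  fl <- attr(table, "factor_labels")
  if (is.null(fl)) {
    fl <- c(
      intersect(cultnet_factors(), unique(table$factor)),
      setdiff(unique(table$factor), cultnet_factors())
    )
  }
  fl
}

# reapply class/attributes after dplyr verbs strip them
as_cultnet_table <- function(data, factor_labels) {
  structure(
    tibble::as_tibble(data),
    factor_labels = factor_labels,
    class = c("cultnet_table", class(tibble::as_tibble(data)))
  )
}

#' Read a network table from long-format CSV
#'
#' Expects one score per row with columns `network_id,role,factor,score`
#' (remappable via `schema`). Rows whose role is not one of the ten
#' recognised roles — e.g. other relatives recruited alongside the network —
#' are dropped with a warning and counted in the attached log. Missing
#' scores are empty fields.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param schema Named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(score = "factor_score")`. Unmapped
#'   columns are assumed to carry their canonical names.
#' @return A [network_table()] with attribute `log`, a list with
#'   `n_read`, `n_dropped_unknown_role`, `dropped_roles`.
#' @export
read_network_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  cols <- c(network_id = "network_id", role = "role",
            factor = "factor", score = "score")
  if (!is.null(schema)) cols[names(schema)] <- unname(schema)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("cannot resolve columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    network_id = raw[[cols[["network_id"]]]],
    role = raw[[cols[["role"]]]],
    factor = raw[[cols[["factor"]]]],
    score_chr = raw[[cols[["score"]]]]
  )
  # malformed rows: missing key fields or non-numeric, non-empty score
  df$score <- suppressWarnings(as.double(df$score_chr))
  malformed <- is.na(df$network_id) | is.na(df$role) | is.na(df$factor) |
    (!is.na(df$score_chr) & df$score_chr != "" & is.na(df$score))
  if (any(malformed)) {
    stop("malformed rows at lines (1 = first data row): ",
         paste(utils::head(which(malformed), 10), collapse = ", "),
         call. = FALSE)
  }
  unknown <- !df$role %in% cultnet_roles()
  dropped_roles <- table(df$role[unknown])
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unrecognised roles dropped: ",
            paste(names(dropped_roles), collapse = ", "), call. = FALSE)
  }
  df <- df[!unknown, c("network_id", "role", "factor", "score")]
  out <- network_table(df)
  attr(out, "log") <- list(
    n_read = nrow(raw),
    n_dropped_unknown_role = sum(unknown),
    dropped_roles = as.list(dropped_roles)
  )
  out
}

#' Write a network table to CSV (with an optional JSON sidecar)
#'
#' @param table A [network_table()].
#' @param path Output CSV path. Missing scores become empty fields.
#' @param sidecar Optional path for a JSON sidecar recording counts
#'   (records, networks, missing scores) plus any filtering/imputation log
#'   attached to the table.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(table, path, sidecar = NULL) {
  readr::write_csv(table[, c("network_id", "role", "factor", "score")], path,
                   na = "")
  if (!is.null(sidecar)) {
    info <- list(
      n_records = nrow(table),
      n_networks = dplyr::n_distinct(table$network_id),
      n_missing = sum(is.na(table$score)),
      log = attr(table, "log") %||% list()
    )
    jsonlite::write_json(info, sidecar, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Filter networks by composition
#'
#' Analyses differ in how much of the network they require: the resemblance
#' stage uses any network where the student recruited at least one other
#' agent, while parental-type analyses require at least one parent and one
#' friend (and the grandparent-mediation variants additionally a
#' grandparent).
#'
#' @param table A [network_table()].
#' @param rule One of `"student_plus_any"` (student plus at least one
#'   family member or friend), `"parent_and_friend"`, or
#'   `"parent_friend_and_grandparent"`. The second sitting (`student_t2`)
#'   does not count as a family member or friend.
#' @return Filtered network table; attribute `log` holds
#'   `n_networks_in`, `n_retained`, `n_excluded` and the rule.
#' @export
filter_networks <- function(table,
                            rule = c("student_plus_any", "parent_and_friend",
                                     "parent_friend_and_grandparent")) {
  rule <- match.arg(rule)
  fl <- factor_labels_of(table)
  roles_by_net <- split(table$role, table$network_id)
  others <- c(role_parents(), role_friends(), role_grandparents())
  keep <- vapply(roles_by_net, function(r) {
    switch(rule,
      student_plus_any = any(r %in% others),
      parent_and_friend =
        any(r %in% role_parents()) && any(r %in% role_friends()),
      parent_friend_and_grandparent =
        any(r %in% role_parents()) && any(r %in% role_friends()) &&
          any(r %in% role_grandparents())
    )
  }, logical(1))
  retained_ids <- names(roles_by_net)[keep]
  out <- as_cultnet_table(table[table$network_id %in% retained_ids, ], fl)
  attr(out, "log") <- list(
    rule = rule,
    n_networks_in = length(roles_by_net),
    n_retained = sum(keep),
    n_excluded = sum(!keep)
  )
  out
}

#' Impute missing factor scores
#'
#' Replaces missing scores so downstream correlation and dichotomisation
#' stages see complete data. The default `column_mean` imputer substitutes
#' the factor's mean score over all agents; the interface accepts any
#' function `(scores, seed) -> scores` for alternative imputers.
#'
#' @param table A [network_table()].
#' @param method `"column_mean"` or a function taking a numeric vector
#'   (one factor's scores, with `NA`s) and a seed, returning the completed
#'   vector.
#' @param seed Integer seed; imputation is deterministic given it (the
#'   default imputer is deterministic regardless).
#' @return Completed table; attribute `log` holds `n_imputed` per factor.
#' @export
impute_missing <- function(table, method = "column_mean", seed = 1L) {
  fl <- factor_labels_of(table)
  fun <- if (is.function(method)) {
    method
  } else if (identical(method, "column_mean")) {
    function(x, seed) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    }
  } else {
    stop("unknown imputation method: ", method, call. = FALSE)
  }
  out <- table
  n_imputed <- integer(0)
  for (f in unique(out$factor)) {
    idx <- out$factor == f
    x <- out$score[idx]
    if (all(is.na(x))) {
      stop("factor '", f, "' has no observed scores; cannot impute",
           call. = FALSE)
    }
    if (mean(is.na(x)) >= 0.5) {
      stop("factor '", f, "' is >= 50% missing; refusing to impute",
           call. = FALSE)
    }
    n_imputed[f] <- sum(is.na(x))
    if (n_imputed[[f]] > 0) {
      out$score[idx] <- fun(x, seed)
    }
  }
  if (anyNA(out$score)) {
    stop("imputer left missing scores behind", call. = FALSE)
  }
  out <- as_cultnet_table(out, fl)
  attr(out, "log") <- list(n_imputed = as.list(n_imputed))
  out
}
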