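#' Social-agent roles
#'
#' Each network is built around one focal student and up to nine further
#' agents: the student's second questionnaire sitting (`student_t2`), two
#' parents, two friends and four grandparents. Every role appears at most
#' once per network.
#'
#' @return Character vector of the ten recognised role labels.
#' @export
#' @examples
#' cultnet_roles()
cultnet_roles <- function() {
  c(
    "student", "student_t2",
    "mother", "father",
    "friend1", "friend2",
    "maternal_grandmother", "maternal_grandfather",
    "paternal_grandmother", "paternal_grandfather"
  )
}

#' Default factor labels
#'
#' The eight latent attitude/behaviour dimensions the pipeline is usually
#' run over: religiosity, political orientation, environmentalism, health
#' habits, music, reading, screen use and social activity.
#'
#' @return Character vector of eight factor labels.
#' @export
cultnet_factors <- function() {
  c(
    "Religiosity", "Politics", "Environmentalism", "Health",
    "Music", "Reading", "Screen", "Social"
  )
}

role_parents <- function() c("mother", "father")
role_friends <- function() c("friend1", "friend2")
role_grandparents <- function() {
  c(
    "maternal_grandmother", "maternal_grandfather",
    "paternal_grandmother", "paternal_grandfather"
  )
}

# couple pairs used for "horizontal" edge classification
role_couples <- function() {
  list(
    c("mother", "father"),
    c("maternal_grandmother", "maternal_grandfather"),
    c("paternal_grandmother", "paternal_grandfather")
  )
}

# parent of each lineage: maternal grandparents are the mother's parents
grandparent_lineage_parent <- function(role) {
  ifelse(startsWith(role, "maternal_"), "mother", "father")
}

#' Classify a role pair into a resemblance edge category
#'
#' Edges in the resemblance graph are coloured by the kind of social tie
#' they represent: `direct_vertical` (parent-student, and grandparent to
#' the parent of the same lineage), `indirect_vertical`
#' (grandparent-student), `horizontal` (friend-student and within-couple
#' pairs) and `other` (all remaining ties, e.g. a friend with a parent).
#'
#' @param role_a,role_b Role labels (see [cultnet_roles()]).
#' @return One of `"direct_vertical"`, `"indirect_vertical"`,
#'   `"horizontal"`, `"other"`.
#' @export
#' @examples
#' edge_category("student", "mother")
#' edge_category("maternal_grandmother", "student")
#' edge_category("friend1", "friend2")
edge_category <- function(role_a, role_b) {
  stopifnot(length(role_a) == 1L, length(role_b) == 1L)
  pair <- sort(c(role_a, role_b))
  gps <- role_grandparents()
  if ("student" %in% pair) {
    partner <- setdiff(pair, "student")
    if (partner %in% role_parents()) return("direct_vertical")
    if (partner %in% gps) return("indirect_vertical")
    if (partner %in% role_friends()) return("horizontal")
    return("other")
  }
  for (cp in role_couples()) {
    if (setequal(pair, cp)) return("horizontal")
  }
  gp <- pair[pair %in% gps]
  pa <- pair[pair %in% role_parents()]
  if (length(gp) == 1L && length(pa) == 1L &&
      grandparent_lineage_parent(gp) == pa) {
    return("direct_vertical")
  }
  "other"
}
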