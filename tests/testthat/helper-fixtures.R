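# tiny network-table builders used across the suite

# one network from a named score vector, e.g. net_rows("n1", c(student = 0.2))
net_rows <- function(id, scores, factor = "Religiosity") {
  tibble::tibble(
    network_id = id,
    role = names(scores),
    factor = factor,
    score = unname(scores)
  )
}

# paired (student, partner) table across n networks from two score vectors
paired_table <- function(x, y, partner = "mother", factor = "Religiosity") {
  ids <- sprintf("n%04d", seq_along(x))
  network_table(dplyr::bind_rows(
    tibble::tibble(network_id = ids, role = "student", factor = factor,
                   score = x),
    tibble::tibble(network_id = ids, role = partner, factor = factor,
                   score = y)
  ))
}

# all permutations of 1..n (for the exhaustive resemblance oracle)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive-enumeration resemblance z over all n! pairings
exact_resemblance_z <- function(x, y) {
  r <- stats::cor(x, y)
  null_r <- vapply(all_perms(length(y)), function(p) stats::cor(x, y[p]),
                   numeric(1))
  (r - mean(null_r)) / stats::sd(null_r)
}

# independent naive grid-search oracle for the additive bias fit:
# plain 4-nested loops in lexicographic order, strict-improvement updates
naive_bias_oracle <- function(trait_tab, opp_tab, objective, g) {
  lv <- c("VH", "Vh", "vH", "vh")
  Pt <- trait_tab$P[match(lv, trait_tab$type)]
  Nt <- trait_tab$N[match(lv, trait_tab$type)]
  Po <- opp_tab$P[match(lv, opp_tab$type)]
  No <- opp_tab$N[match(lv, opp_tab$type)]
  obj1 <- function(P, N, p) {
    p <- min(max(p, 0), 1)
    switch(objective,
      binomial_loglik = {
        t <- 0
        if (N > 0) t <- t - N * log(p)
        if (P - N > 0) t <- t - (P - N) * log1p(-p)
        t
      },
      sse_proportions = if (P > 0) (N / P - p)^2 else 0,
      sse_counts = (N - P * p)^2
    )
  }
  cellsum <- function(P, N, v, h, o) {
    obj1(P[1], N[1], o + v + h) + obj1(P[2], N[2], o + v) +
      obj1(P[3], N[3], o + h) + obj1(P[4], N[4], o)
  }
  vals <- seq(0, 1, by = g)
  best <- Inf
  arg <- NULL
  for (v in vals) for (h in vals) {
    if (v + h > 1 + 1e-9) next
    for (ot in vals) {
      if (v + h + ot > 1 + 1e-9) next
      for (oo in vals) {
        if (v + h + oo > 1 + 1e-9) next
        f <- cellsum(Pt, Nt, v, h, ot) + cellsum(Po, No, v, h, oo)
        if (f < best - 1e-12) {
          best <- f
          arg <- c(vertical = v, horizontal = h,
                   other_trait = ot, other_opposite = oo)
        }
      }
    }
  }
  list(arg = arg, value = best)
}
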