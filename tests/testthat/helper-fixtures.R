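# Shared fixtures: tiny hand-built studies and networks, plus seeded random
# generators used by the property-style tests.

records <- function(...) {
  rows <- list(...)
  data.frame(sorter_id = vapply(rows, `[`, "", 1L),
             quote_id = vapply(rows, `[`, "", 2L),
             pile = vapply(rows, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

# smallest valid study: 1 sorter, 3 quotes, 2 piles
study_s1 <- function() {
  sorting_study(records(c("s1", "q1", "A"), c("s1", "q2", "A"),
                        c("s1", "q3", "B")))
}

# 9 sorters; exactly 2 of them co-pile (q1, q2)
study_two_of_nine <- function() {
  rows <- list(c("s1", "q1", "A"), c("s1", "q2", "A"),
               c("s2", "q1", "X"), c("s2", "q2", "X"))
  for (s in paste0("s", 3:9))
    rows <- c(rows, list(c(s, "q1", "L"), c(s, "q2", "R")))
  sorting_study(do.call(records, rows))
}

# hand-built networks (unit counts unless stated)
net_two_triangles <- function(count = 1L) {
  e <- data.frame(from = c("a", "a", "b", "d", "d", "e"),
                  to   = c("b", "c", "c", "e", "f", "f"),
                  count = count)
  cooccurrence_network(letters[1:6], e, n_sorters = max(count))
}

net_bridge <- function() {
  e <- data.frame(from = c("a", "a", "b", "c", "d", "d", "e"),
                  to   = c("b", "c", "c", "d", "e", "f", "f"),
                  count = 1L)
  cooccurrence_network(letters[1:6], e, n_sorters = 1L)
}

net_single_edge <- function() {
  cooccurrence_network(c("a", "b"),
                       data.frame(from = "a", to = "b", count = 1L),
                       n_sorters = 1L)
}

# random study: each sorter partitions the quotes into 2-4 random piles
random_study <- function(n_quotes, n_sorters, seed) {
  withr::with_seed(seed, {
    qid <- sprintf("q%02d", seq_len(n_quotes))
    recs <- do.call(rbind, lapply(seq_len(n_sorters), function(s) {
      k <- sample(2:4, 1L)
      data.frame(sorter_id = sprintf("s%d", s), quote_id = qid,
                 pile = sprintf("p%d", sample.int(k, n_quotes, replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
    sorting_study(recs)
  })
}

# independent brute-force co-sort counts: direct enumeration over every
# (sorter, pair) combination, no reuse of package internals
oracle_counts <- function(study) {
  qid <- study$quotes$quote_id
  out <- list()
  for (i in seq_along(qid)) for (j in seq_len(i - 1L)) {
    a <- qid[j]; b <- qid[i]
    n <- 0L
    for (s in study$sorters) {
      r <- study$records[study$records$sorter_id == s, ]
      pa <- r$pile[r$quote_id == a]; pb <- r$pile[r$quote_id == b]
      if (length(pa) == 1L && length(pb) == 1L && pa == pb) n <- n + 1L
    }
    if (n > 0L) out[[paste(a, b)]] <- n
  }
  out
}

# noise-free planted study: K disjoint uniform cliques of count S
clique_study <- function(n_quotes, n_themes, n_sorters, seed = 1L) {
  generate_pilesort(synthetic_spec(n_quotes = n_quotes, n_themes = n_themes,
                                   n_sorters = n_sorters, noise = 0,
                                   p_merge = 0, p_split = 0, seed = seed))
}

write_csv_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
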