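## Comparing and reconciling the two algorithms' partitions, plus the
## manual-reassignment provenance used in the facilitated discussion step.

align_partitions <- function(p1, p2) {
  n1 <- sort(names(p1)); n2 <- sort(names(p2))
  if (!identical(n1, n2))
    pte_stop_input("partitions are over different node sets")
  list(a = as.character(p1[n1]), b = as.character(p2[n1]), nodes = n1)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index computed from the contingency
#' table: 1 for identical partitions (up to label permutation), about 0 for
#' independent partitions, possibly negative for systematic disagreement.
#'
#' @param p1,p2 named vectors over the same node set.
#' @return ARI in `[-1, 1]`; symmetric in its arguments.
#' @export
adjusted_rand <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalised mutual information between two partitions
#'
#' Mutual information of the group labels normalised by the arithmetic mean
#' of the two label entropies; 1 iff the partitions are identical up to
#' labels, 0 for independent labels. Two identical trivial partitions (both
#' all-in-one or both all-singletons) are defined to agree perfectly (NMI 1).
#'
#' @param p1,p2 named vectors over the same node set.
#' @return NMI in `[0, 1]`.
#' @export
norm_mutual_info <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha == 0 && hb == 0) return(1)   # both trivial single-group
  if (ha == 0 || hb == 0) {
    # one side trivial: identical iff the other is too (handled above)
    same <- adjusted_rand(p1, p2) == 1
    return(if (same) 1 else 0)
  }
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Compare two partitions of the quote set
#'
#' @param p1,p2 named vectors over the same node set.
#' @return A `partition_comparison`: list with `ari`, `nmi` and
#'   `contingency` (group-by-group count table, rows = `p1` groups).
#' @export
compare_partitions <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  structure(list(ari = adjusted_rand(p1, p2),
                 nmi = norm_mutual_info(p1, p2),
                 contingency = table(al$a, al$b, dnn = c("p1", "p2"))),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("Partition agreement: ARI = ", sprintf("%.4f", x$ari),
      ", NMI = ", sprintf("%.4f", x$nmi), "\n", sep = "")
  print(x$contingency)
  invisible(x)
}

#' Reconcile the two algorithms' merge histories into a final grouping
#'
#' Takes whichever history attains the higher maximum modularity (both
#' algorithms pursue Q, so Q arbitrates), keeps the other algorithm's best
#' partition and the cross-algorithm ARI/NMI in the result so disagreement
#' stays visible. If the maxima tie and the best partitions are identical up
#' to labels, the source is `"consensus"`; a tie with different partitions
#' falls to the alphabetically first algorithm name.
#'
#' @param hA,hB `merge_history` objects over the same network.
#' @return A `final_grouping`: list with `partition` (current), `base`
#'   (the partition before any manual edits), `source`, `edits` (empty),
#'   `q` (max-Q of the chosen history), `other` (name, partition, max-Q of
#'   the runner-up) and `comparison` ([compare_partitions()] of the two).
#' @export
select_final <- function(hA, hB) {
  stopifnot(inherits(hA, "merge_history"), inherits(hB, "merge_history"))
  pA <- best_partition(hA); pB <- best_partition(hB)
  align_partitions(pA, pB)  # node-set mismatch -> error
  qA <- max(hA$q, na.rm = TRUE); qB <- max(hB$q, na.rm = TRUE)
  cmp <- compare_partitions(pA, pB)
  tie <- abs(qA - qB) <= 1e-12
  identical_parts <- cmp$ari == 1
  if (tie && identical_parts) {
    chosen <- pA; source <- "consensus"; q <- qA
    other <- list(algorithm = hB$algorithm, partition = pB, q = qB)
  } else if (qA > qB || (tie && hA$algorithm <= hB$algorithm)) {
    chosen <- pA; source <- hA$algorithm; q <- qA
    other <- list(algorithm = hB$algorithm, partition = pB, q = qB)
  } else {
    chosen <- pB; source <- hB$algorithm; q <- qB
    other <- list(algorithm = hA$algorithm, partition = pA, q = qA)
  }
  structure(list(partition = chosen, base = chosen, source = source,
                 edits = list(), q = q, other = other, comparison = cmp),
            class = "final_grouping")
}

#' Wrap a single partition as a final grouping
#' @param partition named vector (quote -> group label).
#' @param source free-text provenance (e.g. an algorithm name).
#' @return A `final_grouping` with an empty edit log.
#' @export
final_grouping <- function(partition, source = "manual") {
  structure(list(partition = partition, base = partition, source = source,
                 edits = list(), q = NA_real_, other = NULL,
                 comparison = NULL),
            class = "final_grouping")
}

#' @export
print.final_grouping <- function(x, ...) {
  cat("<final_grouping> source = ", x$source, ", ",
      length(unique(x$partition)), " group(s), ",
      length(x$edits), " manual edit(s)\n", sep = "")
  invisible(x)
}

#' Manually move a quote to another group (with provenance)
#'
#' Mirrors the facilitated-discussion practice of co-researchers overriding
#' the algorithmic grouping: the move is applied and appended to an
#' append-only edit log, so the algorithmic partition is always recoverable
#' and the final grouping is replayable.
#'
#' @param grouping a `final_grouping`.
#' @param quote_id quote to move (must exist in the partition).
#' @param target_group existing or newly named group label.
#' @param note free-text rationale recorded with the edit.
#' @return The updated `final_grouping`.
#' @export
reassign <- function(grouping, quote_id, target_group, note = "") {
  stopifnot(inherits(grouping, "final_grouping"))
  if (!quote_id %in% names(grouping$partition))
    pte_stop_input("unknown quote: ", quote_id)
  from <- unname(grouping$partition[[quote_id]])
  grouping$partition[[quote_id]] <- target_group
  grouping$edits[[length(grouping$edits) + 1L]] <-
    list(quote_id = quote_id, from = from, to = target_group, note = note)
  grouping
}

#' Replay a grouping's edit log from its base partition
#'
#' @param grouping a `final_grouping`.
#' @return The partition obtained by applying every edit, in order, to the
#'   pre-edit base partition. Equals `grouping$partition` by construction.
#' @export
replay_edits <- function(grouping) {
  stopifnot(inherits(grouping, "final_grouping"))
  p <- grouping$base
  for (e in grouping$edits) p[[e$quote_id]] <- e$to
  p
}

#' Write / read a final grouping as JSON
#'
#' The JSON carries the base partition, the edit log, the source and the
#' runner-up partition, so serialize -> reload -> replay is bit-stable.
#'
#' @param grouping a `final_grouping`.
#' @param file path.
#' @return `file` invisibly (write); a `final_grouping` (read).
#' @export
write_final_grouping <- function(grouping, file) {
  stopifnot(inherits(grouping, "final_grouping"))
  x <- list(source = grouping$source,
            q = grouping$q,
            partition = as.list(grouping$partition),
            base = as.list(grouping$base),
            edits = grouping$edits,
            other = if (!is.null(grouping$other))
              list(algorithm = grouping$other$algorithm,
                   q = grouping$other$q,
                   partition = as.list(grouping$other$partition)),
            comparison = if (!is.null(grouping$comparison))
              list(ari = grouping$comparison$ari,
                   nmi = grouping$comparison$nmi))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_final_grouping
#' @export
read_final_grouping <- function(file) {
  if (!file.exists(file)) pte_stop_input("grouping file not found: ", file)
  x <- jsonlite::read_json(file)
  unlistp <- function(l) stats::setNames(vapply(l, as.character, character(1L)),
                                         names(l))
  g <- final_grouping(unlistp(x$partition), source = x$source)
  g$base <- unlistp(x$base)
  g$q <- x$q %||% NA_real_
  g$edits <- lapply(x$edits, function(e)
    list(quote_id = e$quote_id, from = e$from, to = e$to, note = e$note %||% ""))
  if (!is.null(x$other))
    g$other <- list(algorithm = x$other$algorithm, q = x$other$q,
                    partition = unlistp(x$other$partition))
  if (!is.null(x$comparison))
    g$comparison <- structure(list(ari = x$comparison$ari,
                                   nmi = x$comparison$nmi,
                                   contingency = NULL),
                              class = "partition_comparison")
  g
}

#' Write a partition to CSV (quote_id, group)
#' @param partition named vector.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_partition_csv <- function(partition, file) {
  ids <- sort(names(partition))
  utils::write.csv(data.frame(quote_id = ids,
                              group = as.character(partition[ids])),
                   file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Write a merge history (per-level partitions and Q) to JSON
#' @param history a `merge_history`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_merge_history <- function(history, file) {
  stopifnot(inherits(history, "merge_history"))
  x <- list(algorithm = history$algorithm, direction = history$direction,
            levels = lapply(seq_along(history$levels), function(i)
              list(q = history$q[i],
                   n_groups = length(unique(history$levels[[i]])),
                   partition = as.list(history$levels[[i]]))))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
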