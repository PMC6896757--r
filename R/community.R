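## Community detection on the co-occurrence network.
##
## Weight semantics, fixed once for the whole package: modularity and the
## greedy merging treat the co-sort COUNT c_ij as the similarity strength
## A_ij (more sorters agreeing = stronger tie), while shortest paths inside
## edge betweenness use the inverse weight w_ij = 1/c_ij as the edge LENGTH
## (more sorters agreeing = closer). This is the only reading under which
## inverse weighting helps rather than inverts the clustering.

# dense similarity matrix A (counts or 1s) over net$nodes, plus degrees and
# total strength; shared by modularity, greedy merging and the brute force.
strength_matrix <- function(net, weight_mode = c("similarity", "unweighted")) {
  weight_mode <- match.arg(weight_mode)
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    w <- if (weight_mode == "similarity") net$edges$count else
      rep(1, nrow(net$edges))
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Modularity of a partition of the co-occurrence network
#'
#' Computes Newman's modularity
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]\delta(c_i, c_j)}
#' where, in `"similarity"` mode, the strength \eqn{A_{ij}} of an edge is its
#' co-sort count \eqn{c_{ij}} (in `"unweighted"` mode every edge has strength
#' 1), \eqn{k_i} is the total strength at node i and \eqn{2m} the total
#' strength of the network. Q is 0 for the all-in-one-group partition by
#' construction and lies in `[-1, 1]`.
#'
#' @param net a [cooccurrence_network()] with at least one edge.
#' @param partition named character vector mapping every node to a group
#'   label.
#' @param weight_mode `"similarity"` (strength = co-sort count; default) or
#'   `"unweighted"`.
#' @return The modularity Q (scalar).
#' @export
modularity_q <- function(net, partition,
                         weight_mode = c("similarity", "unweighted")) {
  stopifnot(inherits(net, "cooc_network"))
  check_partition(partition, net$nodes)
  if (nrow(net$edges) == 0L)
    pte_stop_input("modularity is undefined for an edgeless network (m = 0)")
  A <- strength_matrix(net, weight_mode)
  q_from_membership(A, partition[net$nodes])
}

q_from_membership <- function(A, membership) {
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (idx in split(seq_along(membership), membership)) {
    q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

check_partition <- function(partition, nodes) {
  if (is.null(names(partition)) || any(!nzchar(names(partition))))
    pte_stop_input("partition must be a named vector (names = quote ids)")
  miss <- setdiff(nodes, names(partition))
  if (length(miss))
    pte_stop_input("partition is missing node(s): ",
                   paste(utils::head(sort(miss), 5L), collapse = ", "))
  extra <- setdiff(names(partition), nodes)
  if (length(extra))
    pte_stop_input("partition contains unknown node(s): ",
                   paste(utils::head(sort(extra), 5L), collapse = ", "))
  invisible(TRUE)
}

# canonical group labels: groups ordered by size (desc), ties by smallest
# member id; labelled G1, G2, ... Guarantees label-permutation-free output.
canonical_labels <- function(partition) {
  groups <- split(names(partition), as.character(partition))
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[`, character(1L), 1L))
  groups <- groups[ord]
  out <- character(length(partition))
  names(out) <- names(partition)
  for (g in seq_along(groups)) out[groups[[g]]] <- paste0("G", g)
  out[sort(names(out))]
}

new_merge_history <- function(levels, q, algorithm, direction) {
  structure(list(levels = levels, q = q, algorithm = algorithm,
                 direction = direction),
            class = "merge_history")
}

#' @export
print.merge_history <- function(x, ...) {
  cat("<merge_history> ", x$algorithm, " (", x$direction, "), ",
      length(x$levels), " level(s), max Q = ",
      sprintf("%.4f", max(x$q)), "\n", sep = "")
  invisible(x)
}

#' Divisive community detection by edge betweenness (Girvan-Newman)
#'
#' Repeatedly removes the edge with the highest betweenness, where shortest
#' paths are computed with the inverse-count weights `w_ij = 1/c_ij` as edge
#' lengths, so paths preferentially run through strongly co-sorted pairs and
#' the low-agreement bridges between candidate themes are removed first.
#' After each removal the connected-component partition is recorded (when it
#' changes) together with its modularity on the *original* network
#' (similarity mode). Ties in betweenness are broken toward the
#' lexicographically smallest node-id pair, making the run fully
#' deterministic.
#'
#' @param net a [cooccurrence_network()].
#' @return A `merge_history` running from the initial component partition to
#'   all singletons, with Q recorded at every level. Pass to
#'   [best_partition()] for the max-Q level.
#' @export
girvan_newman <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$edges) == 0L) {
    singl <- canonical_labels(stats::setNames(net$nodes, net$nodes))
    return(new_merge_history(list(singl), NA_real_, "girvan_newman",
                             "divisive"))
  }
  A <- strength_matrix(net, "similarity")
  g <- as_igraph(net)
  levels <- list()
  qs <- numeric()
  record <- function(membership) {
    p <- canonical_labels(stats::setNames(as.character(membership),
                                          igraph::V(g)$name))
    levels[[length(levels) + 1L]] <<- p
    qs[length(qs) + 1L] <<- q_from_membership(A, p[net$nodes])
  }
  comp <- igraph::components(g)$membership
  record(comp)
  n_comp <- max(comp)
  while (igraph::ecount(g) > 0L) {
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
    cand <- which(eb >= max(eb) - 1e-10)
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, cand)
      key <- paste(pmin(ends[, 1L], ends[, 2L]),
                   pmax(ends[, 1L], ends[, 2L]))
      cand <- cand[order(key)][1L]
    }
    g <- igraph::delete_edges(g, cand)
    comp <- igraph::components(g)$membership
    if (max(comp) > n_comp) {
      n_comp <- max(comp)
      record(comp)
    }
  }
  new_merge_history(levels, qs, "girvan_newman", "divisive")
}

#' Agglomerative greedy modularity maximisation
#'
#' Starts from singleton groups and repeatedly performs the merge with the
#' largest modularity gain \eqn{\Delta Q} (similarity mode: strengths are
#' the co-sort counts), recording every level until one group remains.
#' Isolated quotes (no co-sorts) are held out of the merging and attached to
#' every level as singleton groups; they have zero strength and cannot
#' change Q. Ties in \eqn{\Delta Q} are broken toward the merge whose groups
#' have the lexicographically smallest representative node ids.
#'
#' @param net a [cooccurrence_network()] with at least one edge.
#' @return A `merge_history` (agglomerative) with Q at every level.
#' @export
greedy_modularity <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$edges) == 0L)
    pte_stop_input("greedy modularity needs at least one edge")
  A_full <- strength_matrix(net, "similarity")
  active <- net$nodes[rowSums(A_full) > 0]
  iso <- setdiff(net$nodes, active)
  A <- A_full[active, active, drop = FALSE]
  m2 <- sum(A)
  n <- length(active)

  memb <- seq_len(n)                      # group index per active node
  reps <- active                          # lexicographic representative per group
  E_g <- A                                # group-by-group strength matrix
  k_g <- rowSums(A)                       # group total strengths

  with_iso <- function(p_active) {
    p <- c(p_active, stats::setNames(iso, iso))
    canonical_labels(p)
  }
  levels <- list(with_iso(stats::setNames(active, active)))
  qs <- q_from_membership(A_full, levels[[1L]][net$nodes])

  live <- rep(TRUE, n)
  n_groups <- n
  while (n_groups > 1L) {
    idx <- which(live)
    # dQ for merging groups a,b: 2 * (E_ab/m2 - k_a * k_b / m2^2)
    dq <- 2 * (E_g[idx, idx, drop = FALSE] / m2 -
                 outer(k_g[idx], k_g[idx]) / m2^2)
    diag(dq) <- -Inf
    best <- max(dq)
    hits <- which(dq >= best - 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    key <- paste(pmin(reps[idx[hits[, 1L]]], reps[idx[hits[, 2L]]]),
                 pmax(reps[idx[hits[, 1L]]], reps[idx[hits[, 2L]]]))
    pick <- hits[order(key)[1L], ]
    a <- idx[min(pick)]; b <- idx[max(pick)]
    # merge b into a
    E_g[a, ] <- E_g[a, ] + E_g[b, ]
    E_g[, a] <- E_g[, a] + E_g[, b]
    k_g[a] <- k_g[a] + k_g[b]
    live[b] <- FALSE
    reps[a] <- min(reps[a], reps[b])
    memb[memb == b] <- a
    n_groups <- n_groups - 1L

    p <- with_iso(stats::setNames(reps[memb], active))
    levels[[length(levels) + 1L]] <- p
    qs[length(qs) + 1L] <- q_from_membership(A_full, p[net$nodes])
  }
  new_merge_history(levels, qs, "greedy_modularity", "agglomerative")
}

#' Select the best level of a merge history
#'
#' Returns the partition with maximal modularity; ties are broken toward the
#' level with fewer groups, then toward the earliest such level.
#'
#' @param history a `merge_history` from [girvan_newman()] or
#'   [greedy_modularity()].
#' @return Named character vector: the max-Q partition, canonical labels.
#' @export
best_partition <- function(history) {
  stopifnot(inherits(history, "merge_history"))
  if (length(history$levels) == 0L) pte_stop_input("empty merge history")
  q <- history$q
  if (all(is.na(q))) return(history$levels[[1L]])
  best <- max(q, na.rm = TRUE)
  cand <- which(q >= best - 1e-12)
  sizes <- vapply(history$levels[cand],
                  function(p) length(unique(p)), integer(1L))
  history$levels[[cand[which.min(sizes)]]]
}

#' Exhaustive maximum-modularity partition (test oracle)
#'
#' Enumerates every set partition of the node set (restricted-growth-string
#' enumeration; Bell(10) = 115,975) and returns the one with maximal
#' modularity in similarity mode. Exponential: refuse above `max_nodes`.
#' Ties broken toward fewer groups, then enumeration order.
#'
#' @param net a [cooccurrence_network()] with at least one edge.
#' @param max_nodes refuse networks larger than this (default 10).
#' @return Named character vector: the globally optimal partition.
#' @export
brute_force_best_partition <- function(net, max_nodes = 10L) {
  stopifnot(inherits(net, "cooc_network"))
  n <- length(net$nodes)
  if (n > max_nodes)
    pte_stop_input("brute force limited to ", max_nodes, " nodes (got ", n, ")")
  if (nrow(net$edges) == 0L)
    pte_stop_input("modularity is undefined for an edgeless network")
  A <- strength_matrix(net, "similarity")
  m2 <- sum(A)
  k <- rowSums(A)
  best_q <- -Inf
  best_m <- NULL
  best_ng <- Inf
  memb <- integer(n)
  recurse <- function(i, max_lab) {
    if (i > n) {
      q <- 0
      for (g in seq_len(max_lab)) {
        idx <- which(memb == g)
        q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
      }
      if (q > best_q + 1e-12 ||
          (q > best_q - 1e-12 && max_lab < best_ng)) {
        best_q <<- q; best_m <<- memb; best_ng <<- max_lab
      }
      return(invisible())
    }
    for (lab in seq_len(max_lab + 1L)) {
      memb[i] <<- lab
      recurse(i + 1L, max(max_lab, lab))
    }
  }
  recurse(1L, 0L)
  canonical_labels(stats::setNames(as.character(best_m), net$nodes))
}
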