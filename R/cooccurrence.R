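#' Construct a co-occurrence network directly
#'
#' Low-level constructor used by [build_network()] and by tests that need a
#' hand-specified network. Nodes are quote ids; each edge carries the
#' co-sort count `c_ij` (number of sorters who placed the pair in one pile)
#' and the derived weight `w_ij = 1/c_ij`. Counts are the canonical stored
#' quantity; weights are recomputed from them so `w_ij * c_ij == 1` exactly.
#'
#' @param nodes character vector of quote ids.
#' @param edges data frame with columns `from`, `to`, `count` (may have zero
#'   rows). Pairs are unordered; stored with `from < to`.
#' @param n_sorters number of sorters in the source study (upper bound for
#'   any count).
#' @return An object of class `cooc_network`: list with `nodes`, `edges`
#'   (columns `from`, `to`, `count`, `weight`) and `n_sorters`.
#' @export
cooccurrence_network <- function(nodes, edges, n_sorters) {
  nodes <- sort(unique(as.character(nodes)))
  if (length(nodes) < 1L)
    pte_stop_input("a co-occurrence network needs at least 1 quote")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        count = integer(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    from <- as.character(edges$from); to <- as.character(edges$to)
    if (any(from == to)) pte_stop_input("self-loops are not allowed")
    if (!all(c(from, to) %in% nodes))
      pte_stop_input("edge endpoint not in node set")
    a <- pmin(from, to); b <- pmax(from, to)
    count <- as.integer(edges$count)
    if (any(count < 1L)) pte_stop_input("edge counts must be >= 1")
    if (any(count > n_sorters))
      pte_stop_input("edge count exceeds number of sorters")
    if (anyDuplicated(paste(a, b, sep = "\r")))
      pte_stop_input("duplicate edge in edge list")
    ord <- order(a, b)
    edges <- data.frame(from = a[ord], to = b[ord], count = count[ord],
                        weight = 1 / count[ord], stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 n_sorters = as.integer(n_sorters)),
            class = "cooc_network")
}

#' Count sorters who co-piled a pair of quotes
#'
#' @param study a [sorting_study()].
#' @param i,j distinct quote ids in the study.
#' @return Integer count in `[0, n_sorters]`; symmetric in `i`, `j`.
#' @export
cooccurrence_count <- function(study, i, j) {
  stopifnot(inherits(study, "sorting_study"))
  if (identical(i, j)) pte_stop_input("self-pair (i == j) is undefined")
  if (!all(c(i, j) %in% study$quotes$quote_id))
    pte_stop_input("unknown quote id: ",
                   paste(setdiff(c(i, j), study$quotes$quote_id), collapse = ", "))
  n <- 0L
  for (s in study$sorters) {
    p <- sorter_partition(study, s)
    if (i %in% names(p) && j %in% names(p) && p[[i]] == p[[j]]) n <- n + 1L
  }
  n
}

#' Build the quote co-occurrence network from a study
#'
#' One node per quote (quotes never co-piled with anything are kept as
#' isolated nodes); one edge for every pair of quotes some sorter placed in
#' the same pile, carrying the co-sort count and its inverse as the weight —
#' a pair co-piled by 2 of 9 sorters gets weight 1/2.
#'
#' @param study a [sorting_study()] with at least one sorter and two quotes.
#' @return A [cooccurrence_network()].
#' @examples
#' recs <- data.frame(sorter_id = rep(c("s1", "s2"), each = 2),
#'                    quote_id = c("q1", "q2", "q1", "q2"),
#'                    pile = c("A", "A", "X", "X"))
#' net <- build_network(sorting_study(recs))
#' net$edges  # one edge, count 2, weight 0.5
#' @export
build_network <- function(study) {
  stopifnot(inherits(study, "sorting_study"))
  if (nrow(study$quotes) < 2L)
    pte_stop_input("network construction needs at least 2 quotes")
  pairs <- list()
  for (s in study$sorters) {
    p <- sorter_partition(study, s)
    for (members in split(names(p), p)) {
      if (length(members) >= 2L) {
        members <- sort(members)
        pairs[[length(pairs) + 1L]] <- utils::combn(members, 2L)
      }
    }
  }
  if (length(pairs)) {
    all_pairs <- do.call(cbind, pairs)
    key <- paste(all_pairs[1L, ], all_pairs[2L, ], sep = "\r")
    cnt <- table(key)
    ab <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    edges <- data.frame(from = ab[, 1L], to = ab[, 2L],
                        count = as.integer(cnt), stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  cooccurrence_network(study$quotes$quote_id, edges,
                       n_sorters = length(study$sorters))
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Edge attributes `count` (co-sort count) and `weight` (`1/count`) are
#' attached; note igraph's own functions interpret `weight` as a *distance*
#' in shortest-path computations, which matches the inverse-count semantics
#' (strongly co-sorted pairs are close).
#'
#' @param net a [cooccurrence_network()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("<cooc_network> ", length(x$nodes), " quotes, ", nrow(x$edges),
      " edges, ", x$n_sorters, " sorter(s)\n", sep = "")
  if (nrow(x$edges))
    cat("  counts in [", min(x$edges$count), ", ", max(x$edges$count),
        "]; weights are 1/count\n", sep = "")
  invisible(x)
}

#' Export a co-occurrence network to file
#'
#' Every format carries the node ids and, per edge, both the co-sort count
#' and the inverse weight, and re-imports to an identical network.
#' `"csv"` writes an edge list (`source,target,count,weight`) in which
#' isolated nodes appear as rows with an empty `target`; the sorter count is
#' kept in a `# n_sorters=` comment line. `"graphml"` uses typed edge
#' attributes `count` (int) and `weight` (double) plus a graph attribute
#' `n_sorters`. `"json"` writes `{n_sorters, nodes, links}`.
#'
#' @param net a [cooccurrence_network()].
#' @param file output path.
#' @param format one of `"graphml"`, `"csv"`, `"json"`; default guessed
#'   from the file extension.
#' @return `file`, invisibly.
#' @export
export_network <- function(net, file,
                           format = c("auto", "graphml", "csv", "json")) {
  stopifnot(inherits(net, "cooc_network"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_net_format(file)
  if (format == "graphml") {
    g <- as_igraph(net)
    g <- igraph::set_graph_attr(g, "n_sorters", net$n_sorters)
    igraph::write_graph(g, file, format = "graphml")
  } else if (format == "csv") {
    con <- file(file, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# n_sorters=", net$n_sorters), con)
    writeLines("source,target,count,weight", con)
    deg_nodes <- unique(c(net$edges$from, net$edges$to))
    iso <- setdiff(net$nodes, deg_nodes)
    if (nrow(net$edges))
      writeLines(paste(net$edges$from, net$edges$to, net$edges$count,
                       format(net$edges$weight, digits = 17), sep = ","), con)
    if (length(iso)) writeLines(paste0(iso, ",,,"), con)
  } else {
    links <- if (nrow(net$edges))
      data.frame(source = net$edges$from, target = net$edges$to,
                 count = net$edges$count, weight = net$edges$weight)
    else list()
    jsonlite::write_json(list(n_sorters = net$n_sorters, nodes = net$nodes,
                              links = links),
                         file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Import a co-occurrence network written by [export_network()]
#' @param file path of an exported network.
#' @param format as in [export_network()].
#' @return A [cooccurrence_network()].
#' @export
import_network <- function(file, format = c("auto", "graphml", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_net_format(file)
  if (!file.exists(file)) pte_stop_input("network file not found: ", file)
  if (format == "graphml") {
    g <- igraph::read_graph(file, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- if (nrow(ed))
      data.frame(from = ed$from, to = ed$to, count = as.integer(ed$count))
    else NULL
    cooccurrence_network(igraph::V(g)$name, edges,
                         n_sorters = as.integer(igraph::graph_attr(g, "n_sorters")))
  } else if (format == "csv") {
    first <- readLines(file, n = 1L, warn = FALSE)
    if (!grepl("^# n_sorters=", first))
      pte_stop_input("not a pilesortr edge-list CSV: ", file)
    S <- as.integer(sub("^# n_sorters=", "", first))
    tab <- utils::read.csv(file, skip = 1L, colClasses = "character",
                           na.strings = character())
    is_edge <- nzchar(tab$target)
    edges <- if (any(is_edge))
      data.frame(from = tab$source[is_edge], to = tab$target[is_edge],
                 count = as.integer(tab$count[is_edge]))
    else NULL
    nodes <- unique(c(tab$source, tab$target[is_edge]))
    cooccurrence_network(nodes, edges, n_sorters = S)
  } else {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    edges <- if (length(x$links) && NROW(x$links) > 0)
      data.frame(from = x$links$source, to = x$links$target,
                 count = as.integer(x$links$count))
    else NULL
    cooccurrence_network(x$nodes, edges, n_sorters = as.integer(x$n_sorters))
  }
}

guess_net_format <- function(file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         graphml = "graphml", xml = "graphml",
         csv = "csv",
         json = "json",
         pte_stop_input("cannot guess network format from extension: ", file))
}
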