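## Diagram and group-listing artefacts for the facilitated discussion step.
## Rendering conventions: node colour = group, via a fixed six-colour
## palette applied to groups ordered by size (then label); edge display
## width proportional to the co-sort count (capped), so thick edges mean
## many sorters agreed.

#' Default six-colour group palette
#'
#' Light blue, green, pink, red, yellow, orange — the conventional ordering
#' for groups 1-6 in the network diagram. Cycled (with a warning) when a
#' partition has more groups than the palette.
#' @return Character vector of R colour names.
#' @export
default_palette <- function() {
  c("lightblue", "green", "pink", "red", "yellow", "orange")
}

#' Compute a force-directed layout for the diagram
#'
#' Kamada-Kawai layout with the inverse-count weights as target edge
#' lengths, so pairs co-sorted by many sorters are drawn close together.
#' Deterministic under the seed.
#'
#' @param net a [cooccurrence_network()].
#' @param seed layout seed.
#' @param palette colours for groups, in group order.
#' @param edge_base display width of a count-1 edge.
#' @param width_cap maximum edge width as a multiple of `edge_base`.
#' @return A `diagram_spec`: list with `coords` (matrix, rownames = quote
#'   ids), `palette`, `edge_base`, `width_cap`, `seed`.
#' @export
layout_network <- function(net, seed = 1L, palette = default_palette(),
                           edge_base = 1, width_cap = 8) {
  stopifnot(inherits(net, "cooc_network"))
  if (length(net$nodes) == 1L) {
    coords <- matrix(0, 1L, 2L, dimnames = list(net$nodes, c("x", "y")))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    g <- as_igraph(net)
    # KK per connected component (disconnected graphs otherwise overlap),
    # components then tiled on a grid in deterministic node order
    comp <- igraph::components(g)$membership
    blocks <- lapply(sort(unique(comp)), function(ci) {
      sub <- igraph::induced_subgraph(g, which(comp == ci))
      if (igraph::vcount(sub) == 1L) {
        xy <- matrix(0, 1L, 2L)
      } else {
        w <- if (igraph::ecount(sub) > 0L) igraph::E(sub)$weight else NULL
        xy <- igraph::layout_with_kk(sub, weights = w)
        xy <- scale(xy, scale = FALSE)                     # centre
        span <- max(abs(xy), 1e-9)
        xy <- xy / span                                    # fit [-1, 1]^2
      }
      rownames(xy) <- igraph::V(sub)$name
      xy
    })
    ncol_grid <- ceiling(sqrt(length(blocks)))
    coords <- do.call(rbind, lapply(seq_along(blocks), function(i) {
      row <- (i - 1L) %/% ncol_grid; col <- (i - 1L) %% ncol_grid
      sweep(blocks[[i]], 2L, c(3 * col, -3 * row), `+`)
    }))
    colnames(coords) <- c("x", "y")
    coords <- coords[net$nodes, , drop = FALSE]
  }
  structure(list(coords = coords, palette = palette, edge_base = edge_base,
                 width_cap = width_cap, seed = as.integer(seed)),
            class = "diagram_spec")
}

#' Export / import a diagram spec as JSON (for external editing)
#' @param spec a `diagram_spec`.
#' @param file path.
#' @return `file` invisibly (write); a `diagram_spec` (read).
#' @export
write_diagram_spec <- function(spec, file) {
  stopifnot(inherits(spec, "diagram_spec"))
  jsonlite::write_json(
    list(nodes = rownames(spec$coords),
         x = spec$coords[, 1L], y = spec$coords[, 2L],
         palette = spec$palette, edge_base = spec$edge_base,
         width_cap = spec$width_cap, seed = spec$seed),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_diagram_spec
#' @export
read_diagram_spec <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  coords <- cbind(x = x$x, y = x$y)
  rownames(coords) <- x$nodes
  structure(list(coords = coords, palette = x$palette,
                 edge_base = x$edge_base, width_cap = x$width_cap,
                 seed = as.integer(x$seed)),
            class = "diagram_spec")
}

# groups ordered by size (desc) then label: the palette-assignment order
group_order <- function(partition) {
  groups <- split(names(partition), as.character(partition))
  names(groups)[order(-lengths(groups), names(groups))]
}

# colour per group, cycling the palette with a warning when short
group_colours <- function(partition, palette) {
  labs <- group_order(partition)
  if (length(labs) > length(palette))
    warning("partition has ", length(labs), " groups but the palette has ",
            length(palette), " colours; cycling", call. = FALSE)
  stats::setNames(rep_len(palette, length(labs)), labs)
}

# display width for an edge of a given co-sort count
edge_widths <- function(count, edge_base = 1, width_cap = 8) {
  pmin(edge_base * count, width_cap * edge_base)
}

#' Render the group-coloured network diagram
#'
#' Draws the co-occurrence network with nodes filled by group colour (size
#' ordering, see [default_palette()]), edge widths proportional to the
#' co-sort count (capped at `width_cap` times the base width), and a legend
#' mapping colours to group labels. Output format (SVG or PNG) follows the
#' file extension.
#'
#' @param net a [cooccurrence_network()].
#' @param partition named vector covering the network's nodes.
#' @param spec optional `diagram_spec` from [layout_network()]; computed
#'   with defaults when omitted.
#' @param file output path ending in `.svg` or `.png`.
#' @return `file`, invisibly.
#' @export
render_network <- function(net, partition, file, spec = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  check_partition(partition, net$nodes)
  if (is.null(spec)) spec <- layout_network(net)
  ext <- tolower(tools::file_ext(file))
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  ok <- switch(ext,
               svg = tryCatch({grDevices::svg(file, width = 8, height = 8); TRUE},
                              error = function(e) FALSE),
               png = tryCatch({grDevices::png(file, width = 1600, height = 1600,
                                              res = 200); TRUE},
                              error = function(e) FALSE),
               pte_stop_input("unsupported figure format: .", ext))
  if (!ok) pte_stop_input("could not open graphics device for ", file)
  on.exit(grDevices::dev.off())

  cols <- group_colours(partition, spec$palette)
  xy <- spec$coords[net$nodes, , drop = FALSE]
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = grDevices::extendrange(xy[, 1L], f = 0.1),
                 ylim = grDevices::extendrange(xy[, 2L], f = 0.1),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Quote co-occurrence network")
  if (nrow(net$edges)) {
    w <- edge_widths(net$edges$count, spec$edge_base, spec$width_cap)
    graphics::segments(xy[net$edges$from, 1L], xy[net$edges$from, 2L],
                       xy[net$edges$to, 1L], xy[net$edges$to, 2L],
                       lwd = w, col = "grey55")
  }
  graphics::points(xy[, 1L], xy[, 2L], pch = 21, cex = 2.2,
                   bg = cols[as.character(partition[net$nodes])],
                   col = "grey20")
  graphics::text(xy[, 1L], xy[, 2L], labels = net$nodes, cex = 0.45, pos = 3)
  graphics::legend("topleft", legend = names(cols), pt.bg = cols, pch = 21,
                   bty = "n", title = "Group", cex = 0.8)
  invisible(file)
}

#' Write the per-group quote listing (markdown)
#'
#' Produces the document handed to the discussion panel: one section per
#' group, each listing its quotes verbatim (or id-only, with a warning, when
#' no text is available). Ordering is stable — groups by label, quotes by id
#' — and the body carries no timestamps, so regeneration on the same inputs
#' is byte-identical. When a [final_grouping()] with manual edits is given,
#' the listing reflects post-edit membership and appends the edit log.
#'
#' @param partition named vector (quote -> group), or a `final_grouping`.
#' @param quotes optional quote-text table (`quote_id`, `text`) or a
#'   [sorting_study()] whose quote table is used.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
group_report <- function(partition, quotes = NULL, file) {
  grouping <- NULL
  if (inherits(partition, "final_grouping")) {
    grouping <- partition
    partition <- grouping$partition
  }
  if (inherits(quotes, "sorting_study")) quotes <- quotes$quotes
  texts <- character(0)
  if (!is.null(quotes))
    texts <- stats::setNames(as.character(quotes$text), quotes$quote_id)

  lines <- c(paste0("<!-- pilesortr ", as.character(utils::packageVersion("pilesortr")),
                    " group report -->"),
             "# Quote groups", "")
  if (!is.null(grouping))
    lines <- c(lines, paste0("Source: ", grouping$source), "")
  missing_any <- FALSE
  for (lab in sort(unique(as.character(partition)))) {
    ids <- sort(names(partition)[partition == lab])
    lines <- c(lines, paste0("## ", lab, " (", length(ids), " quotes)"), "")
    for (id in ids) {
      txt <- texts[id]
      if (is.null(quotes) || is.na(txt)) {
        missing_any <- missing_any || !is.null(quotes)
        lines <- c(lines, paste0("- **", id, "**"))
      } else {
        lines <- c(lines, paste0("- **", id, "**: ", txt))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(grouping) && length(grouping$edits)) {
    lines <- c(lines, "## Manual reassignments", "")
    for (e in grouping$edits)
      lines <- c(lines, paste0("- ", e$quote_id, ": ", e$from, " -> ", e$to,
                               if (nzchar(e$note)) paste0(" (", e$note, ")")))
    lines <- c(lines, "")
  }
  if (missing_any)
    warning("some quotes have no text; listed by id only", call. = FALSE)
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}
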