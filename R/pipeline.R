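## End-to-end pipeline: sorting table in -> network, partitions, comparison,
## diagram, report out. These functions back the inst/cli/pte.R subcommands
## (simulate | build | detect | render | report | all); messages go to
## stderr via message(), artefacts to the output directory, and every run
## writes a machine-readable run log.

out_path <- function(out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(out_dir, paste0(...))
}

write_run_log <- function(out_dir, command, config, timings) {
  jsonlite::write_json(
    list(command = command,
         package = "pilesortr",
         version = as.character(utils::packageVersion("pilesortr")),
         r_version = R.version.string,
         config = config,
         timing_s = timings),
    out_path(out_dir, "run_log_", command, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Simulate a pile-sort study and write it as the standard sorting CSV
#'
#' @param out_dir output directory; receives `sorting.csv` (the standard
#'   three-column table) and `planted.csv` (the true themes).
#' @param n_quotes,n_themes,n_sorters,noise,p_merge,p_split,seed passed to
#'   [synthetic_spec()].
#' @return The `synthetic_study`, invisibly.
#' @export
pte_simulate <- function(out_dir, n_quotes = 49L, n_themes = 6L,
                         n_sorters = 9L, noise = 0.1, p_merge = 0.2,
                         p_split = 0.2, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  spec <- synthetic_spec(n_quotes, n_themes, n_sorters, noise, p_merge,
                         p_split, seed)
  sim <- generate_pilesort(spec)
  write_sort_table(sim$study, out_path(out_dir, "sorting.csv"))
  write_partition_csv(sim$planted, out_path(out_dir, "planted.csv"))
  message("simulate: wrote ", nrow(sim$study$records), " records for ",
          spec$n_sorters, " sorters x ", spec$n_quotes, " quotes")
  write_run_log(out_dir, "simulate", unclass(spec),
                proc.time()[["elapsed"]] - t0)
  invisible(sim)
}

#' Build and export the co-occurrence network from a sorting table
#'
#' @param input path of the sorting CSV/TSV.
#' @param out_dir output directory; receives `network.graphml`,
#'   `network_edges.csv` and `study_summary.json`.
#' @param sorter_col,quote_col,pile_col,quotes passed to
#'   [read_sort_table()].
#' @return The [cooccurrence_network()], invisibly.
#' @export
pte_build <- function(input, out_dir, sorter_col = "sorter_id",
                      quote_col = "quote_id", pile_col = "pile",
                      quotes = NULL) {
  t0 <- proc.time()[["elapsed"]]
  study <- read_sort_table(input, sorter_col, quote_col, pile_col,
                           quotes = quotes)
  s <- summary(study)
  message("build: ", s$n_sorters, " sorters, ", s$n_quotes, " quotes, piles ",
          min(s$piles_per_sorter), "-", max(s$piles_per_sorter))
  net <- build_network(study)
  export_network(net, out_path(out_dir, "network.graphml"))
  export_network(net, out_path(out_dir, "network_edges.csv"))
  jsonlite::write_json(list(n_sorters = s$n_sorters, n_quotes = s$n_quotes,
                            piles_per_sorter = as.list(s$piles_per_sorter),
                            coverage = as.list(s$coverage)),
                       out_path(out_dir, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("build: network with ", length(net$nodes), " nodes, ",
          nrow(net$edges), " edges")
  write_run_log(out_dir, "build", list(input = input),
                proc.time()[["elapsed"]] - t0)
  invisible(net)
}

#' Detect communities, reconcile, and write all partition artefacts
#'
#' Runs the selected algorithm(s) on the network, reconciles with
#' [select_final()] when both run, and writes per-algorithm partitions and
#' merge histories, the cross-algorithm comparison, and the final grouping.
#'
#' @param input sorting CSV path or a prebuilt network file
#'   (`.graphml`/`.json`/network edge CSV written by [export_network()]).
#' @param out_dir output directory.
#' @param algorithm `"both"` (default), `"greedy_modularity"` or
#'   `"girvan_newman"`.
#' @return The `final_grouping`, invisibly.
#' @export
pte_detect <- function(input, out_dir, algorithm = c("both",
                                                     "greedy_modularity",
                                                     "girvan_newman")) {
  t0 <- proc.time()[["elapsed"]]
  algorithm <- match.arg(algorithm)
  net <- load_network_or_study(input)
  runs <- list()
  if (algorithm %in% c("both", "greedy_modularity"))
    runs$greedy_modularity <- greedy_modularity(net)
  if (algorithm %in% c("both", "girvan_newman"))
    runs$girvan_newman <- girvan_newman(net)
  for (nm in names(runs)) {
    write_merge_history(runs[[nm]], out_path(out_dir, "history_", nm, ".json"))
    write_partition_csv(best_partition(runs[[nm]]),
                        out_path(out_dir, "partition_", nm, ".csv"))
    message("detect: ", nm, " max Q = ",
            sprintf("%.4f", max(runs[[nm]]$q, na.rm = TRUE)), " with ",
            length(unique(best_partition(runs[[nm]]))), " groups")
  }
  if (length(runs) == 2L) {
    final <- select_final(runs$greedy_modularity, runs$girvan_newman)
    cmp <- final$comparison
    writeLines(c("# Algorithm comparison", "",
                 sprintf("| metric | value |"),
                 sprintf("|---|---|"),
                 sprintf("| ARI | %.6f |", cmp$ari),
                 sprintf("| NMI | %.6f |", cmp$nmi),
                 sprintf("| selected | %s |", final$source),
                 sprintf("| Q (selected) | %.6f |", final$q)),
               out_path(out_dir, "comparison.md"))
    message("detect: selected ", final$source,
            " (cross-algorithm ARI = ", sprintf("%.3f", cmp$ari), ")")
  } else {
    final <- final_grouping(best_partition(runs[[1L]]),
                            source = names(runs)[1L])
    final$q <- max(runs[[1L]]$q, na.rm = TRUE)
  }
  write_final_grouping(final, out_path(out_dir, "final_grouping.json"))
  write_partition_csv(final$partition, out_path(out_dir, "partition_final.csv"))
  write_run_log(out_dir, "detect", list(input = input, algorithm = algorithm),
                proc.time()[["elapsed"]] - t0)
  invisible(final)
}

load_network_or_study <- function(input) {
  if (inherits(input, "cooc_network")) return(input)
  if (inherits(input, "sorting_study")) return(build_network(input))
  ext <- tolower(tools::file_ext(input))
  if (ext %in% c("graphml", "xml", "json")) return(import_network(input))
  if (ext == "csv") {
    first <- readLines(input, n = 1L, warn = FALSE)
    if (grepl("^# n_sorters=", first)) return(import_network(input))
    return(build_network(read_sort_table(input)))
  }
  pte_stop_input("cannot interpret input: ", input)
}

#' Render the diagram for a detected (or given) grouping
#'
#' @param input sorting CSV or network file.
#' @param out_dir output directory (expects `final_grouping.json` from
#'   [pte_detect()] unless `partition` is given); receives `network.svg`,
#'   `network.png` and `diagram_spec.json`.
#' @param partition optional named vector overriding the stored grouping.
#' @param seed layout seed.
#' @return Invisible path of the SVG.
#' @export
pte_render <- function(input, out_dir, partition = NULL, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  net <- load_network_or_study(input)
  if (is.null(partition)) {
    gf <- file.path(out_dir, "final_grouping.json")
    if (!file.exists(gf))
      pte_stop_input("no partition given and no final_grouping.json in ", out_dir)
    partition <- read_final_grouping(gf)$partition
  }
  spec <- layout_network(net, seed = seed)
  write_diagram_spec(spec, out_path(out_dir, "diagram_spec.json"))
  render_network(net, partition, out_path(out_dir, "network.svg"), spec)
  render_network(net, partition, out_path(out_dir, "network.png"), spec)
  message("render: wrote network.svg / network.png")
  write_run_log(out_dir, "render", list(input = input, seed = seed),
                proc.time()[["elapsed"]] - t0)
  invisible(file.path(out_dir, "network.svg"))
}

#' Write the per-group quote listing for a detected grouping
#'
#' @param out_dir output directory holding `final_grouping.json`; receives
#'   `group_report.md`.
#' @param quote_texts optional quote-text CSV path (`quote_id`, `text`); the
#'   report lists ids only (with a warning) when absent.
#' @return Invisible path of the report.
#' @export
pte_report <- function(out_dir, quote_texts = NULL) {
  t0 <- proc.time()[["elapsed"]]
  gf <- file.path(out_dir, "final_grouping.json")
  if (!file.exists(gf)) pte_stop_input("no final_grouping.json in ", out_dir)
  grouping <- read_final_grouping(gf)
  if (is.null(quote_texts))
    warning("no quote-text file supplied; report lists quote ids only",
            call. = FALSE)
  quotes <- if (!is.null(quote_texts)) read_quote_texts(quote_texts)
  group_report(grouping, quotes, file.path(out_dir, "group_report.md"))
  message("report: wrote group_report.md")
  write_run_log(out_dir, "report", list(quote_texts = quote_texts),
                proc.time()[["elapsed"]] - t0)
  invisible(file.path(out_dir, "group_report.md"))
}

#' Run the full pipeline: build, detect, render, report
#'
#' @param input sorting CSV path.
#' @param out_dir output directory for all artefacts.
#' @param quote_texts optional quote-text CSV.
#' @param seed layout seed.
#' @param algorithm as in [pte_detect()].
#' @return The `final_grouping`, invisibly.
#' @export
pte_all <- function(input, out_dir, quote_texts = NULL, seed = 1L,
                    algorithm = "both") {
  pte_build(input, out_dir, quotes = quote_texts)
  final <- pte_detect(input, out_dir, algorithm = algorithm)
  pte_render(input, out_dir, seed = seed)
  pte_report(out_dir, quote_texts = quote_texts)
  invisible(final)
}
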