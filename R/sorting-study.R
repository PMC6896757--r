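#' Construct a sorting study
#'
#' A sorting study is the full pile-sort dataset: the quote set, the sorter
#' set, and one record per (sorter, quote) assignment to a pile. Pile labels
#' are opaque strings scoped *per sorter*: the pile identity is the pair
#' (sorter, pile label), and identical labels used by different sorters imply
#' nothing.
#'
#' @param records data frame with character columns `sorter_id`, `quote_id`,
#'   `pile` (one row per assignment).
#' @param quotes optional explicit quote list: either a character vector of
#'   quote ids or a data frame with columns `quote_id` and (optionally)
#'   `text`. When omitted the quote set is the union of ids seen in
#'   `records`; when supplied, a record referencing an unknown quote is a
#'   hard error.
#' @return An object of class `sorting_study`: a list with elements
#'   `quotes` (data frame `quote_id`, `text`), `sorters` (character vector)
#'   and `records` (data frame, canonically ordered by sorter then quote).
#' @examples
#' recs <- data.frame(sorter_id = "s1", quote_id = c("q1", "q2", "q3"),
#'                    pile = c("A", "A", "B"))
#' study <- sorting_study(recs)
#' summary(study)
#' @export
sorting_study <- function(records, quotes = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    pte_stop_input("a sorting study needs at least one sort record")
  need <- c("sorter_id", "quote_id", "pile")
  if (!all(need %in% names(records)))
    pte_stop_input("records must have columns: ", paste(need, collapse = ", "))
  records <- data.frame(lapply(records[need], as.character),
                        stringsAsFactors = FALSE)
  if (any(!nzchar(records$sorter_id)) || any(!nzchar(records$quote_id)) ||
      any(!nzchar(records$pile)))
    pte_stop_input("empty sorter_id, quote_id or pile value in records")

  # exact duplicate rows are collapsed; same (sorter, quote) in two piles is
  # a contradiction and must be fatal
  records <- unique(records)
  key <- paste(records$sorter_id, records$quote_id, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    bad <- strsplit(dup[1L], "\r", fixed = TRUE)[[1L]]
    pte_stop_input("conflicting pile assignment for sorter '", bad[1L],
                   "', quote '", bad[2L], "'")
  }

  quote_df <- normalize_quotes(quotes, records$quote_id)
  unknown <- setdiff(records$quote_id, quote_df$quote_id)
  if (length(unknown))
    pte_stop_input("record references quote id(s) not in the supplied quote list: ",
                   paste(sort(unknown), collapse = ", "))

  ord <- order(records$sorter_id, records$quote_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(quotes = quote_df,
         sorters = sort(unique(records$sorter_id)),
         records = records),
    class = "sorting_study")
}

normalize_quotes <- function(quotes, seen_ids) {
  if (is.null(quotes)) {
    ids <- sort(unique(seen_ids))
    return(data.frame(quote_id = ids, text = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(quotes)) {
    if (!"quote_id" %in% names(quotes))
      pte_stop_input("quote table must have a 'quote_id' column")
    ids <- as.character(quotes$quote_id)
    txt <- if ("text" %in% names(quotes)) as.character(quotes$text)
           else NA_character_
  } else {
    ids <- as.character(quotes)
    txt <- NA_character_
  }
  if (any(!nzchar(ids))) pte_stop_input("empty quote id in quote list")
  if (anyDuplicated(ids))
    pte_stop_input("duplicate quote id(s) in quote list: ",
                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  data.frame(quote_id = ids[ord], text = rep_len(txt, length(ids))[ord],
             stringsAsFactors = FALSE)
}

#' Read a pile-sort table from delimited text
#'
#' Expects a UTF-8 CSV or TSV with a header row naming three columns: the
#' sorter's anonymised id, the quote id, and the pile number/label. The
#' delimiter is auto-detected from the header line (tab if present,
#' otherwise comma) unless given. Row order never affects the resulting
#' study.
#'
#' @param file path to the delimited file.
#' @param sorter_col,quote_col,pile_col column names (defaults
#'   `"sorter_id"`, `"quote_id"`, `"pile"`).
#' @param quotes optional explicit quote list as in [sorting_study()]; may
#'   also be the path of a quote-text CSV with columns `quote_id`, `text`.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param validate run [validate_sorting_study()] on the result (warnings
#'   for unusual pile counts and incomplete coverage).
#' @return A [sorting_study()].
#' @export
read_sort_table <- function(file, sorter_col = "sorter_id",
                            quote_col = "quote_id", pile_col = "pile",
                            quotes = NULL, sep = NULL, validate = TRUE) {
  if (!file.exists(file)) pte_stop_input("input file not found: ", file)
  header <- readLines(file, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header)))
    pte_stop_input("empty sorting table: ", file)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", strip.white = TRUE,
                           blank.lines.skip = TRUE, fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) pte_stop_input("sorting table has a header but no rows: ", file)
  miss <- setdiff(c(sorter_col, quote_col, pile_col), names(tab))
  if (length(miss))
    pte_stop_input("missing column(s) in ", file, ": ",
                   paste(miss, collapse = ", "))
  if (is.character(quotes) && length(quotes) == 1L && file.exists(quotes))
    quotes <- read_quote_texts(quotes)
  recs <- data.frame(sorter_id = tab[[sorter_col]],
                     quote_id = tab[[quote_col]],
                     pile = tab[[pile_col]], stringsAsFactors = FALSE)
  study <- sorting_study(recs, quotes = quotes)
  if (validate) validate_sorting_study(study)
  study
}

#' Read a quote-text table (quote_id, text)
#' @param file CSV path with columns `quote_id` and `text`.
#' @return data frame with columns `quote_id`, `text`.
#' @export
read_quote_texts <- function(file) {
  if (!file.exists(file)) pte_stop_input("quote-text file not found: ", file)
  tab <- utils::read.csv(file, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("quote_id", "text") %in% names(tab)))
    pte_stop_input("quote-text file must have columns quote_id, text")
  tab[c("quote_id", "text")]
}

#' Write a study back to canonical CSV
#'
#' Rows sorted by sorter then quote id, so repeated writes of the same study
#' are byte-identical and diffs are stable.
#'
#' @param study a [sorting_study()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sort_table <- function(study, file) {
  stopifnot(inherits(study, "sorting_study"))
  utils::write.csv(study$records, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Validate a sorting study (soft checks)
#'
#' Hard invariants (referential integrity, one pile per sorter-quote pair)
#' are enforced at construction. This validator raises *warnings* for the
#' soft expectations seen in practice: sorters typically produce between 3
#' and 12 piles, and typically sort every quote. Incomplete sorting is
#' allowed — co-occurrence counting simply omits unsorted quotes for that
#' sorter.
#'
#' @param study a [sorting_study()].
#' @param pile_range expected inclusive range of piles per sorter.
#' @return `study`, invisibly.
#' @export
validate_sorting_study <- function(study, pile_range = c(3L, 12L)) {
  stopifnot(inherits(study, "sorting_study"))
  s <- summary(study)
  out <- s$piles_per_sorter < pile_range[1L] | s$piles_per_sorter > pile_range[2L]
  if (any(out))
    warning("sorter(s) with pile counts outside [", pile_range[1L], ", ",
            pile_range[2L], "]: ",
            paste0(names(out)[out], " (", s$piles_per_sorter[out], ")",
                   collapse = ", "), call. = FALSE)
  inc <- s$coverage < 1
  if (any(inc))
    warning("sorter(s) did not sort every quote: ",
            paste0(names(inc)[inc], " (",
                   round(100 * s$coverage[inc]), "%)", collapse = ", "),
            call. = FALSE)
  invisible(study)
}

#' Extract one sorter's piles as a partition
#'
#' Returns the partition of the sorter's *sorted* quotes induced by pile
#' labels: a named character vector mapping quote id to pile label. Quotes
#' the sorter never placed are absent.
#'
#' @param study a [sorting_study()].
#' @param sorter_id sorter present in the study.
#' @return Named character vector (names = quote ids, values = pile labels).
#' @export
sorter_partition <- function(study, sorter_id) {
  stopifnot(inherits(study, "sorting_study"))
  if (!sorter_id %in% study$sorters)
    pte_stop_input("unknown sorter: ", sorter_id)
  r <- study$records[study$records$sorter_id == sorter_id, , drop = FALSE]
  stats::setNames(r$pile, r$quote_id)
}

#' Summarise a sorting study
#'
#' @param object a [sorting_study()].
#' @param ... unused.
#' @return A `study_summary`: list with `n_sorters`, `n_quotes`,
#'   `piles_per_sorter` (named integer) and `coverage` (named fraction of
#'   the quote set each sorter placed).
#' @export
summary.sorting_study <- function(object, ...) {
  nq <- nrow(object$quotes)
  per <- split(object$records, object$records$sorter_id)
  piles <- vapply(per, function(r) length(unique(r$pile)), integer(1L))
  cov <- vapply(per, function(r) length(unique(r$quote_id)) / nq, numeric(1L))
  structure(list(n_sorters = length(object$sorters), n_quotes = nq,
                 piles_per_sorter = piles[object$sorters],
                 coverage = cov[object$sorters]),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Pile-sort study: ", x$n_sorters, " sorter(s), ", x$n_quotes,
      " quote(s)\n", sep = "")
  cat("Piles per sorter: ",
      paste0(names(x$piles_per_sorter), "=", x$piles_per_sorter,
             collapse = ", "), "\n", sep = "")
  cat("Coverage: ",
      paste0(names(x$coverage), "=", sprintf("%.2f", x$coverage),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.sorting_study <- function(x, ...) {
  cat("<sorting_study> ", length(x$sorters), " sorter(s), ",
      nrow(x$quotes), " quote(s), ", nrow(x$records), " record(s)\n",
      sep = "")
  invisible(x)
}
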