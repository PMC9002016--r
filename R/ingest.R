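#' Default topic indicator set
#'
#' The eleven topic codes used throughout the package examples: six government
#' indicators (G1 epidemic prevention measures, G2 popular science answering,
#' G3 scientific research, G4 refuting rumors, G5 government's negligence,
#' G6 government image), two public-emotion indicators (P1 positive emotion,
#' P2 negative emotion) and three media indicators (M1 asking for help online,
#' M2 recordings of epidemic, M3 foreign comparisons). The topic set is
#' configuration: every function accepting `topic_set` works with any set of
#' two or more distinct codes.
#'
#' @return data.frame with columns `code`, `dimension`, `label`.
#' @export
#' @examples
#' default_topic_set()$code
default_topic_set <- function() {
  data.frame(
    code = c(paste0("G", 1:6), "P1", "P2", paste0("M", 1:3)),
    dimension = c(rep("government", 6), rep("public", 2), rep("media", 3)),
    label = c(
      "epidemic prevention measures", "popular science answering",
      "scientific research", "refuting rumors", "government's negligence",
      "government image", "positive emotion", "negative emotion",
      "asking for help online", "recordings of epidemic",
      "foreign comparisons"
    ),
    stringsAsFactors = FALSE
  )
}

#' Read labeled post records from a delimited file
#'
#' Reads a CSV or TSV file of post records with header columns `date`
#' (ISO-8601, YYYY-MM-DD), `topic`, and optionally `id`. Each data row becomes
#' one record; order is preserved.
#'
#' @param path path to a CSV (default) or TSV file; files ending in `.tsv`
#'   are read tab-separated.
#' @param topic_set character vector of admissible topic codes. Defaults to
#'   the eleven-code set of [default_topic_set()].
#' @return data.frame with columns `date` (Date), `topic` (character), `id`
#'   (character, `NA` when absent), one row per post, in file order.
#' @seealso [build_daily_proportions()]
#' @export
read_posts <- function(path, topic_set = default_topic_set()$code) {
  if (!file.exists(path)) stopf("posts file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0) stopf("posts file is empty: %s", path)
  if (!all(c("date", "topic") %in% names(df)))
    stopf("posts file must have header columns 'date' and 'topic'")
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stopf("unparseable date '%s' at data row %d", df$date[bad], bad)
  }
  unknown <- setdiff(unique(df$topic), topic_set)
  if (length(unknown) > 0)
    stopf("topic code(s) not in the configured topic set: %s",
          paste(unknown, collapse = ", "))
  data.frame(
    date = dates,
    topic = df$topic,
    id = if ("id" %in% names(df)) df$id else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Construct a topic_series object from count data
#'
#' Low-level constructor validating the day-by-topic count matrix and deriving
#' proportions. Most users will call [build_daily_proportions()] instead.
#'
#' @param counts n x p nonnegative integer matrix, rows named by ISO dates,
#'   columns by topic codes.
#' @return object of class `topic_series` with components `dates`, `topics`,
#'   `counts`, `proportions`, `daily_totals`.
#' @export
topic_series <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stopf("every retained day must have at least one post")
  out <- structure(list(
    dates = as.Date(rownames(counts)),
    topics = colnames(counts),
    counts = counts,
    proportions = counts / totals,
    daily_totals = as.integer(totals)
  ), class = "topic_series")
  out
}

#' Build the daily topic-proportion series from post records
#'
#' Tallies posts per (day, topic) cell and divides each day's counts by that
#' day's total, giving the day-by-topic proportion matrix that is the input to
#' network estimation. Days with no posts contribute no row (proportions are
#' undefined at a zero total); when an explicit `date_range` covers such days
#' a warning reports how many were dropped. Rows are ordered chronologically;
#' disjoint observation windows are simply concatenated, since the downstream
#' network model treats days as exchangeable observations.
#'
#' @param records data.frame of post records as returned by [read_posts()].
#' @param topic_set character vector of topic codes defining the columns.
#' @param date_range optional length-2 vector (coercible to Date); records
#'   outside it are ignored.
#' @return a [topic_series()] object.
#' @export
#' @examples
#' recs <- data.frame(date = as.Date("2020-01-23") + c(0, 0, 0, 1),
#'                    topic = c("P1", "P1", "P2", "M2"))
#' ts <- build_daily_proportions(recs, topic_set = c("P1", "P2", "M2"))
#' ts$proportions
build_daily_proportions <- function(records, topic_set = default_topic_set()$code,
                                    date_range = NULL) {
  if (nrow(records) == 0) stopf("no post records supplied")
  dates <- as.Date(records$date)
  keep <- rep(TRUE, length(dates))
  if (!is.null(date_range)) {
    dr <- as.Date(date_range)
    keep <- dates >= min(dr) & dates <= max(dr)
  }
  if (!any(keep)) stopf("all records fall outside the requested date range")
  records <- records[keep, , drop = FALSE]
  dates <- dates[keep]

  unknown <- setdiff(unique(records$topic), topic_set)
  if (length(unknown) > 0)
    stopf("topic code(s) not in the configured topic set: %s",
          paste(unknown, collapse = ", "))

  days <- sort(unique(dates))
  tab <- table(factor(as.character(dates), levels = as.character(days)),
               factor(records$topic, levels = topic_set))
  counts <- matrix(as.integer(tab), nrow = length(days),
                   dimnames = list(as.character(days), topic_set))
  if (!is.null(date_range)) {
    span <- seq(min(as.Date(date_range)), max(as.Date(date_range)), by = "day")
    n_empty <- length(span) - length(days)
    if (n_empty > 0)
      warnf("%d day(s) in the requested range had no posts and were dropped",
            n_empty)
  }
  topic_series(counts)
}

#' @export
print.topic_series <- function(x, ...) {
  cat(sprintf("topic_series: %d days x %d topics, %d posts\n",
              length(x$dates), length(x$topics), sum(x$counts)))
  cat(sprintf("  dates: %s .. %s\n", min(x$dates), max(x$dates)))
  cat(sprintf("  topics: %s\n", paste(x$topics, collapse = " ")))
  invisible(x)
}

#' Write / read a topic series as a pair of CSV files
#'
#' `write_topic_series` writes `<stem>_proportions.csv` and
#' `<stem>_counts.csv`, each with a `date` column plus one column per topic
#' code. `read_topic_series` rebuilds the object from the counts file alone
#' (proportions are re-derived, which guarantees row-stochasticity).
#'
#' @param series a [topic_series()] object.
#' @param stem path stem for the two files.
#' @return `write_topic_series` returns the two paths invisibly;
#'   `read_topic_series` returns a `topic_series`.
#' @export
write_topic_series <- function(series, stem) {
  pp <- paste0(stem, "_proportions.csv")
  pc <- paste0(stem, "_counts.csv")
  dfp <- data.frame(date = as.character(series$dates), series$proportions,
                    check.names = FALSE)
  dfc <- data.frame(date = as.character(series$dates), series$counts,
                    check.names = FALSE)
  write.csv(dfp, pp, row.names = FALSE)
  write.csv(dfc, pc, row.names = FALSE)
  invisible(c(proportions = pp, counts = pc))
}

#' @rdname write_topic_series
#' @export
read_topic_series <- function(stem) {
  pc <- paste0(stem, "_counts.csv")
  if (!file.exists(pc)) stopf("counts file not found: %s", pc)
  df <- read.csv(pc, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$date
  topic_series(counts)
}
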