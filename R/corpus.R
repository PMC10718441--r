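#' Construct a single scale record
#'
#' A scale record pairs society/region metadata with the scale's note
#' positions in cents from the tonic (strictly increasing, first element 0).
#'
#' @param scale_id Unique identifier string.
#' @param society_id Society identifier.
#' @param region Geographic region label.
#' @param country Country label.
#' @param kind One of `"theory"`, `"measured"`, `"octave"`. Octave scales
#'   must end exactly at 1200 cents (within `octave_tolerance`).
#' @param method One of `"instrument"`, `"song"`, `"theory"`.
#' @param tonic_known Logical; whether the tonic was identified in the source.
#' @param notes Numeric vector of note positions in cents, starting at 0.
#' @param octave_tolerance Tolerance (cents) on the final note of an octave
#'   scale (default 0, i.e. exact).
#' @return An object of class `scale_record`.
#' @export
scale_record <- function(scale_id, society_id, region, country,
                         kind = c("measured", "theory", "octave"),
                         method = c("instrument", "song", "theory"),
                         tonic_known = FALSE, notes,
                         octave_tolerance = 0) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  rec <- structure(list(scale_id = as.character(scale_id),
                        society_id = as.character(society_id),
                        region = as.character(region),
                        country = as.character(country),
                        kind = kind, method = method,
                        tonic_known = isTRUE(tonic_known),
                        notes = as.numeric(notes)),
                   class = "scale_record")
  problems <- validate_scale_record(rec, octave_tolerance)
  if (length(problems))
    stop("invalid scale record: ", paste(problems, collapse = "; "),
         call. = FALSE)
  rec
}

validate_scale_record <- function(rec, octave_tolerance = 0) {
  problems <- character(0)
  n <- rec$notes
  if (length(n) < 2L) problems <- c(problems, "fewer than 2 notes")
  if (anyNA(n) || any(!is.finite(n))) {
    problems <- c(problems, "non-numeric note")
    return(problems)
  }
  if (length(n) >= 1L && n[1L] != 0) problems <- c(problems, "first note not 0")
  if (length(n) >= 2L && any(diff(n) <= 0))
    problems <- c(problems, "notes not strictly increasing")
  if (identical(rec$kind, "octave") && length(n) >= 2L &&
      abs(n[length(n)] - 1200) > octave_tolerance)
    problems <- c(problems, "octave scale does not end at 1200 cents")
  if (!rec$kind %in% c("theory", "measured", "octave"))
    problems <- c(problems, "unknown kind")
  if (!rec$method %in% c("instrument", "song", "theory"))
    problems <- c(problems, "unknown method")
  problems
}

#' @export
print.scale_record <- function(x, ...) {
  cat(sprintf("<scale_record %s> %s / %s (%s, %s)\n", x$scale_id,
              x$society_id, x$region, x$kind, x$method))
  cat("  notes:", paste(formatC(x$notes, format = "f", digits = 1),
                        collapse = " "), "\n")
  invisible(x)
}

#' Construct a scale corpus
#'
#' A corpus is the unit all analyses consume: a list of [scale_record()]s
#' plus society and region indices (rebuilt automatically).
#'
#' @param records List of `scale_record` objects with unique `scale_id`s.
#' @return An object of class `scale_corpus`.
#' @export
scale_corpus <- function(records = list()) {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1), what = "scale_record")
  if (length(records) && !all(ok))
    stop("all records must be scale_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "scale_id")
  if (anyDuplicated(ids))
    stop("duplicate scale_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(records = records,
                 society_index = build_index(records, "society_id"),
                 region_index = build_index(records, "region")),
            class = "scale_corpus")
}

build_index <- function(records, field) {
  if (!length(records)) return(list())
  keys <- vapply(records, `[[`, character(1), field)
  split(seq_along(records), keys)
}

#' @export
length.scale_corpus <- function(x) length(x$records)

#' @export
`[.scale_corpus` <- function(x, i) scale_corpus(x$records[i])

#' @export
print.scale_corpus <- function(x, ...) {
  kinds <- table(vapply(x$records, `[[`, character(1), "kind"))
  cat(sprintf("<scale_corpus> %d scales, %d societies, %d regions\n",
              length(x), length(x$society_index), length(x$region_index)))
  if (length(kinds))
    cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn scale_corpus Flatten the metadata (and semicolon-joined notes)
#'   to a data frame, one row per scale.
#' @param x A `scale_corpus`.
#' @param row.names,optional,... Passed on conventions of [as.data.frame()].
#' @export
as.data.frame.scale_corpus <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  recs <- x$records
  data.frame(
    scale_id = vapply(recs, `[[`, character(1), "scale_id"),
    society_id = vapply(recs, `[[`, character(1), "society_id"),
    region = vapply(recs, `[[`, character(1), "region"),
    country = vapply(recs, `[[`, character(1), "country"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    method = vapply(recs, `[[`, character(1), "method"),
    tonic_known = vapply(recs, `[[`, logical(1), "tonic_known"),
    notes = vapply(recs, function(r) format_notes(r$notes), character(1)),
    stringsAsFactors = FALSE, row.names = row.names
  )
}

format_notes <- function(notes) {
  paste(formatC(notes, format = "f", digits = 3), collapse = ";")
}

corpus_schema <- c("scale_id", "society_id", "region", "country",
                   "kind", "method", "tonic_known", "notes")

#' Read a scale corpus from CSV
#'
#' Expects the schema `scale_id,society_id,region,country,kind,method,
#' tonic_known,notes` with the notes cell a semicolon-joined cents list
#' (e.g. `"0;204.000;702.000;1200.000"`). In strict mode the first invalid
#' row aborts; in lenient mode invalid rows are skipped with a warning and
#' the number of skipped rows is attached as attribute `"skipped"`.
#'
#' @param path CSV file path.
#' @param strict Abort on the first invalid row? Default `FALSE` (lenient).
#' @param octave_tolerance Tolerance on the final note of `kind == "octave"`
#'   rows (default 0).
#' @return A [scale_corpus()].
#' @export
read_corpus <- function(path, strict = FALSE, octave_tolerance = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(corpus_schema, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- list()
  skipped <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    notes <- suppressWarnings(as.numeric(strsplit(row$notes, ";",
                                                  fixed = TRUE)[[1]]))
    rec <- structure(list(scale_id = row$scale_id,
                          society_id = row$society_id,
                          region = row$region, country = row$country,
                          kind = row$kind, method = row$method,
                          tonic_known = tolower(row$tonic_known) %in%
                            c("true", "t", "1", "yes"),
                          notes = notes),
                     class = "scale_record")
    problems <- validate_scale_record(rec, octave_tolerance)
    if (row$scale_id %in% seen)
      problems <- c(problems, "duplicate scale_id")
    if (length(problems)) {
      msg <- sprintf("row %d (%s): %s", i, row$scale_id,
                     paste(problems, collapse = "; "))
      if (strict) stop(msg, call. = FALSE)
      warning("skipping ", msg, call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    seen <- c(seen, row$scale_id)
    records[[length(records) + 1L]] <- rec
  }
  out <- scale_corpus(records)
  attr(out, "skipped") <- skipped
  out
}

#' Write a scale corpus to CSV
#'
#' One row per record; notes serialized with 3 decimal places (lossless at
#' the >= 1 cent measurement error of the sources). UTF-8, LF line endings.
#'
#' @param corpus A [scale_corpus()].
#' @param path Output file path.
#' @return Invisibly, the number of rows written.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "scale_corpus"))
  df <- as.data.frame(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
            fileEncoding = "UTF-8")
  invisible(nrow(df))
}

#' Filter a corpus by scale kind and/or region
#'
#' Indices are rebuilt for the subset; an empty result is allowed.
#'
#' @param corpus A [scale_corpus()].
#' @param kind Optional kind (`"theory"`, `"measured"`, `"octave"`).
#' @param region Optional region label.
#' @return The filtered [scale_corpus()].
#' @export
filter_corpus <- function(corpus, kind = NULL, region = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  keep <- rep(TRUE, length(corpus))
  if (!is.null(kind))
    keep <- keep & vapply(corpus$records, `[[`, character(1), "kind") == kind
  if (!is.null(region))
    keep <- keep & vapply(corpus$records, `[[`, character(1), "region") == region
  scale_corpus(corpus$records[keep])
}

#' Layout of a corpus: notes per scale
#'
#' The layout (number of scales and note count of each) is what the null
#' models preserve when generating alternative corpora.
#'
#' @param corpus A [scale_corpus()].
#' @return Integer vector, one entry per scale.
#' @export
corpus_layout <- function(corpus) {
  stopifnot(inherits(corpus, "scale_corpus"))
  vapply(corpus$records, function(r) length(r$notes), integer(1))
}

#' Pooled step sizes of a corpus
#'
#' @param corpus A [scale_corpus()].
#' @return Numeric vector of all adjacent-note intervals (cents).
#' @export
corpus_steps <- function(corpus) {
  stopifnot(inherits(corpus, "scale_corpus"))
  unlist(lapply(corpus$records, function(r) diff(r$notes)), use.names = FALSE)
}

#' Pooled scale notes of a corpus
#'
#' @param corpus A [scale_corpus()].
#' @param drop_tonic Drop the 0-cent tonic of each scale (default `TRUE`;
#'   the tonic carries no interval information).
#' @return Numeric vector of note positions (cents).
#' @export
corpus_notes <- function(corpus, drop_tonic = TRUE) {
  stopifnot(inherits(corpus, "scale_corpus"))
  unlist(lapply(corpus$records, function(r) {
    if (drop_tonic) r$notes[-1L] else r$notes
  }), use.names = FALSE)
}
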