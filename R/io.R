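#' Read and write query logs
#'
#' Query logs are tab-separated text with columns `user_id`, `timestamp`
#' (ISO-8601 UTC), `text`, `age`, `gender`. TSV is the native format (query
#' text may contain commas); `read_query_log()` also accepts CSV with
#' proper quoting when the file extension is `.csv`. Records with empty
#' text after whitespace normalization are dropped with an informative
#' count, as are records whose timestamp cannot be parsed.
#'
#' @param path File path.
#' @param log A query-log tibble as produced by [generate_cohort()].
#' @return `read_query_log()` returns a tibble; `write_query_log()` returns
#'   `path` invisibly.
#' @export
read_query_log <- function(path) {
  if (!file.exists(path)) abort(paste0("Query log not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path,
    sep = sep, quote = "\"", stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE
  )
  need <- c("user_id", "timestamp", "text")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Query log lacks required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  ts <- as.POSIXct(df$timestamp,
    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
  )
  # tolerate plain "YYYY-MM-DD HH:MM:SS" and bare dates
  bad <- is.na(ts)
  if (any(bad)) {
    alt <- strptime(df$timestamp[bad], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    dateonly <- is.na(alt)
    alt[dateonly] <- strptime(df$timestamp[bad][dateonly], "%Y-%m-%d", tz = "UTC")
    ts[bad] <- as.POSIXct(alt, tz = "UTC")
  }
  txt_empty <- trimws(df$text) == "" | is.na(df$text)
  drop <- txt_empty | is.na(ts)
  if (any(drop)) {
    inform(sprintf(
      "Dropped %d record(s): %d empty text, %d unparseable timestamp.",
      sum(drop), sum(txt_empty), sum(is.na(ts) & !txt_empty)
    ))
  }
  age <- if ("age" %in% names(df)) {
    suppressWarnings(as.integer(df$age))
  } else {
    rep(NA_integer_, nrow(df))
  }
  gender <- if ("gender" %in% names(df)) df$gender else rep("unknown", nrow(df))
  out <- tibble(
    user_id = df$user_id, timestamp = ts, text = df$text,
    age = age, gender = gender
  )
  out[!drop, , drop = FALSE]
}

#' @rdname read_query_log
#' @export
write_query_log <- function(log, path) {
  df <- as.data.frame(log)
  df$timestamp <- format(log$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Read and write the ground-truth sidecar
#'
#' The sidecar is one row per cohort user in tab-separated text. Scenario
#' target values and the generation seed are preserved in `#`-prefixed
#' header comment lines, making the round trip lossless.
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param path File path.
#' @return `read_truth()` returns the tibble with its `scenario_targets`
#'   and `seed` attributes restored.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tg <- attr(truth, "scenario_targets")
  if (!is.null(tg)) {
    flat <- unlist(tg)
    for (nm in names(flat)) {
      writeLines(sprintf("#target %s=%s", nm, format(flat[[nm]], digits = 15)), con)
    }
  }
  sd <- attr(truth, "seed")
  if (!is.null(sd)) writeLines(sprintf("#seed %d", sd), con)
  df <- as.data.frame(truth)
  for (cl in names(df)) {
    if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]])
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) abort(paste0("Truth file not found: ", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  if (length(body) < 1) abort("Malformed truth file: no header row (line 1).")
  df <- tryCatch(
    read.delim(
      text = paste(body, collapse = "\n"), sep = "\t",
      stringsAsFactors = FALSE
    ),
    error = function(e) {
      abort(paste0("Malformed truth file near line ", sum(hdr) + 1, ": ", conditionMessage(e)))
    }
  )
  for (cl in c("index_date", "lmp", "conception_date")) {
    if (cl %in% names(df)) df[[cl]] <- as.Date(df[[cl]])
  }
  if ("age_band" %in% names(df)) {
    df$age_band <- factor(df$age_band,
      levels = c("<20", "20-24", "25-29", "30-34", "35-39", "40+")
    )
  }
  out <- as_tibble(df)
  tlines <- lines[grepl("^#target ", lines)]
  if (length(tlines) > 0) {
    kv <- sub("^#target ", "", tlines)
    keys <- sub("=.*$", "", kv)
    vals <- as.numeric(sub("^[^=]*=", "", kv))
    attr(out, "scenario_targets") <- as.list(setNames(vals, keys))
  }
  sline <- lines[grepl("^#seed ", lines)]
  if (length(sline) > 0) {
    attr(out, "seed") <- as.integer(sub("^#seed ", "", sline[1]))
  }
  out
}
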