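#' Session records: multichannel recordings from one monitoring session
#'
#' A session bundles the channels recorded by the wearable (ECG at 250 Hz,
#' red/infrared PPG at 50 Hz, skin temperature at 1 Hz by default) with the
#' subject identity, risk-group label and the clock correction that aligns
#' device time to reference time.
#'
#' @param channels List of [sampled_signal()] objects; labels must be unique.
#' @param subject_id Subject identifier.
#' @param risk_group One of `"high"`, `"low"`, `"unknown"`.
#' @param clock_offset_s Additive correction (seconds) aligning local device
#'   time to reference time.
#' @return An object of class `session_record`.
#' @export
session_record <- function(channels, subject_id = "unknown",
                           risk_group = c("unknown", "high", "low"),
                           clock_offset_s = 0) {
  risk_group <- match.arg(risk_group)
  stopifnot(is.list(channels),
            all(vapply(channels, inherits, logical(1), "sampled_signal")),
            is.numeric(clock_offset_s), length(clock_offset_s) == 1L,
            is.finite(clock_offset_s))
  labs <- vapply(channels, `[[`, character(1), "label")
  if (anyDuplicated(labs)) {
    stop("duplicate channel label: ", labs[duplicated(labs)][1], call. = FALSE)
  }
  names(channels) <- labs
  structure(
    list(subject_id = as.character(subject_id),
         risk_group = risk_group,
         channels = channels,
         clock_offset_s = as.numeric(clock_offset_s)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> subject %s (%s risk), %d channel(s), clock offset %g s\n",
              x$subject_id, x$risk_group, length(x$channels), x$clock_offset_s))
  for (ch in x$channels) {
    cat("  "); print(ch)
  }
  invisible(x)
}

#' Read and write session files
#'
#' Sessions are stored in a self-describing text format: a file header with
#' subject metadata, then one block per channel consisting of a header line
#' (label, rate, start time, units, sample count) followed by the samples,
#' whitespace-separated, with `NA` marking dropouts. The round trip
#' `read_session(write_session(x))` is lossless to stored precision.
#'
#' @param record A [session_record()].
#' @param path File path.
#' @param digits Significant digits used when writing samples.
#' @return `read_session()` returns a `session_record`; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(record, path, digits = 10) {
  stopifnot(inherits(record, "session_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#pulsegram-session v1",
    paste0("#subject: ", record$subject_id),
    paste0("#risk_group: ", record$risk_group),
    paste0("#clock_offset_s: ", format(record$clock_offset_s, digits = 17))
  ), con)
  for (ch in record$channels) {
    writeLines(sprintf("#channel label=%s rate_hz=%s start_time_s=%s units=%s n=%d",
                       ch$label,
                       format(ch$rate_hz, digits = 17),
                       format(ch$start_time_s, digits = 17),
                       ch$units, length(ch$samples)), con)
    if (length(ch$samples)) {
      txt <- format(ch$samples, digits = digits, trim = TRUE, scientific = TRUE)
      txt[is.na(ch$samples)] <- "NA"
      writeLines(paste(txt, collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "#pulsegram-session v1") {
    stop("parse error at line 1: not a pulsegram session file", call. = FALSE)
  }
  meta <- function(i, key) {
    pre <- paste0("#", key, ": ")
    if (i > length(lines) || !startsWith(lines[i], pre)) {
      stop(sprintf("parse error at line %d: expected '%s'", i, pre), call. = FALSE)
    }
    sub(pre, "", lines[i], fixed = TRUE)
  }
  subject <- meta(2, "subject")
  risk <- meta(3, "risk_group")
  offset <- as.numeric(meta(4, "clock_offset_s"))
  channels <- list()
  i <- 5L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "#channel ")) {
      stop(sprintf("parse error at line %d: expected channel header", i), call. = FALSE)
    }
    fields <- parse_kv(sub("^#channel ", "", ln), i)
    need <- c("label", "rate_hz", "start_time_s", "units", "n")
    if (!all(need %in% names(fields))) {
      stop(sprintf("parse error at line %d: channel header missing %s",
                   i, paste(setdiff(need, names(fields)), collapse = ", ")),
           call. = FALSE)
    }
    n <- as.integer(fields[["n"]])
    if (n > 0L) {
      i <- i + 1L
      if (i > length(lines)) {
        stop(sprintf("parse error at line %d: missing sample line", i), call. = FALSE)
      }
      samples <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(samples) != n) {
        stop(sprintf("parse error at line %d: expected %d samples, found %d",
                     i, n, length(samples)), call. = FALSE)
      }
    } else {
      samples <- numeric(0)
    }
    lab <- fields[["label"]]
    if (lab %in% vapply(channels, `[[`, character(1), "label")) {
      stop(sprintf("parse error at line %d: duplicate channel label '%s'", i, lab),
           call. = FALSE)
    }
    channels[[length(channels) + 1L]] <-
      sampled_signal(samples, as.numeric(fields[["rate_hz"]]),
                     as.numeric(fields[["start_time_s"]]),
                     lab, fields[["units"]])
    i <- i + 1L
  }
  session_record(channels, subject, risk, offset)
}

parse_kv <- function(s, line_no) {
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop(sprintf("parse error at line %d: malformed field '%s'",
                 line_no, parts[bad][1]), call. = FALSE)
  }
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}
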