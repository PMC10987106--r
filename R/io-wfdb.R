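#' Read a WFDB-style waveform record
#'
#' Reads the header + signal subset of the WFDB format used by archival
#' waveform databases (MIMIC-style): a `.hea` text header describing the
#' channels, and a multiplexed 16-bit little-endian signal file
#' (format 16). Digital values are converted to physical units via each
#' channel's gain and baseline; the format-16 invalid-sample sentinel
#' (-32768) becomes `NA`. Annotations, multi-segment records and other
#' signal formats are out of scope.
#'
#' @param path Record path without extension (a `.hea` file must exist at
#'   `<path>.hea`).
#' @param channel_names Character vector of channel descriptions to
#'   extract; `NULL` reads all channels.
#' @return Named list of [sampled_signal()] objects, one per requested
#'   channel.
#' @export
read_wfdb_record <- function(path, channel_names = NULL) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such record: ", hea, call. = FALSE)
  lines <- grep("^\\s*(#|$)", readLines(hea, warn = FALSE),
                value = TRUE, invert = TRUE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("malformed WFDB header: ", hea, call. = FALSE)
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (length(lines) < 1 + nsig) {
    stop("malformed WFDB header: expected ", nsig, " signal lines", call. = FALSE)
  }
  sig <- lapply(lines[1 + seq_len(nsig)], parse_wfdb_signal_line)
  files <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(files) != 1) {
    stop("only single-file multiplexed records are supported", call. = FALSE)
  }
  fmt <- unique(vapply(sig, `[[`, numeric(1), "format"))
  if (!identical(fmt, 16)) {
    stop("only WFDB signal format 16 is supported (got ", fmt, ")", call. = FALSE)
  }
  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop("missing signal file: ", dat, call. = FALSE)
  raw_n <- file.size(dat) / 2
  digital <- readBin(dat, "integer", n = raw_n, size = 2,
                     signed = TRUE, endian = "little")
  if (length(digital) %% nsig != 0) {
    stop("signal file length is not a multiple of the channel count", call. = FALSE)
  }
  mat <- matrix(digital, nrow = nsig)
  if (!is.na(nsamp) && ncol(mat) != nsamp) {
    stop("signal file sample count disagrees with header", call. = FALSE)
  }
  descs <- vapply(sig, `[[`, character(1), "description")
  if (is.null(channel_names)) channel_names <- descs
  missing <- setdiff(channel_names, descs)
  if (length(missing)) {
    stop("channel(s) not in record: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(channel_names, function(nm) {
    j <- match(nm, descs)
    d <- mat[j, ]
    d[d == -32768L] <- NA_integer_
    phys <- (d - sig[[j]]$baseline) / sig[[j]]$gain
    sampled_signal(phys, fs, 0, nm, sig[[j]]$units)
  })
  stats::setNames(out, channel_names)
}

# "filename format ADCgain(baseline)/units adcres adczero initval cksum blk desc..."
parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 2) stop("malformed WFDB signal line: ", line, call. = FALSE)
  gain <- 200; baseline <- 0; units <- "mV"
  if (length(tok) >= 3) {
    g <- tok[3]
    if (grepl("/", g)) {
      units <- sub("^[^/]*/", "", g)
      g <- sub("/.*$", "", g)
    }
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- as.numeric(g)
    if (!is.finite(gain) || gain == 0) gain <- 200
  }
  desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else tok[1]
  list(file = tok[1], format = as.numeric(sub("x.*|:.*|\\+.*", "", tok[2])),
       gain = gain, baseline = baseline, units = units, description = desc)
}

#' Write a WFDB-style record (format 16)
#'
#' Counterpart of [read_wfdb_record()] used to build fixtures and to export
#' synthetic records: all channels must share one sampling rate; samples
#' are quantised by each channel's gain/baseline into 16-bit integers and
#' multiplexed into a single `.dat` file. `NA` samples are stored as the
#' format-16 invalid sentinel.
#'
#' @param signals Named list of [sampled_signal()] objects at a common rate.
#' @param path Record path without extension.
#' @param gain ADC units per physical unit (one value, or per channel).
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(signals, path, gain = 200) {
  stopifnot(is.list(signals), length(signals) >= 1,
            all(vapply(signals, inherits, logical(1), "sampled_signal")))
  fs <- unique(vapply(signals, `[[`, numeric(1), "rate_hz"))
  if (length(fs) != 1) stop("all channels must share one sampling rate", call. = FALSE)
  ns <- unique(vapply(signals, function(s) length(s$samples), integer(1)))
  if (length(ns) != 1) stop("all channels must have equal length", call. = FALSE)
  gain <- rep_len(gain, length(signals))
  rec <- basename(path)
  digital <- vapply(seq_along(signals), function(j) {
    d <- as.integer(round(signals[[j]]$samples * gain[j]))
    d[is.na(signals[[j]]$samples)] <- -32768L
    if (any(d[!is.na(d)] > 32767 | (d[!is.na(d)] < -32767 & d[!is.na(d)] != -32768L))) {
      stop("channel ", j, " overflows 16-bit range at gain ", gain[j], call. = FALSE)
    }
    d
  }, integer(ns))
  writeBin(as.integer(t(digital)), paste0(path, ".dat"),
           size = 2, endian = "little")
  sig_lines <- vapply(seq_along(signals), function(j) {
    s <- signals[[j]]
    sprintf("%s.dat 16 %g(0)/%s 16 0 0 0 0 %s",
            rec, gain[j], s$units, s$label)
  }, character(1))
  writeLines(c(sprintf("%s %d %g %d", rec, length(signals), fs, ns), sig_lines),
             paste0(path, ".hea"))
  invisible(path)
}
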