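#' Read a PRAAT TextGrid
#'
#' Parses both the "full" (`ooTextFile` with `item []:` blocks) and the
#' "short" text formats. Only interval tiers are returned.
#'
#' @param path Path to a `.TextGrid` file.
#' @return Named list of interval tiers; each tier is a data.frame with
#'   columns `xmin`, `xmax` (seconds) and `label`.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))])))
    stop("not a PRAAT TextGrid: ", path)
  if (any(grepl("item\\s*\\[", lines))) .tg_parse_full(lines) else .tg_parse_short(lines)
}

.tg_num <- function(line) as.numeric(sub(".*=\\s*", "", line))
.tg_str <- function(line) {
  m <- regmatches(line, regexpr('"[^"]*"', line))
  if (length(m) == 0) "" else substr(m, 2, nchar(m) - 1)
}

.tg_parse_full <- function(lines) {
  tiers <- list()
  i <- 1
  cur_name <- NULL
  cur <- NULL
  is_interval <- FALSE
  flush <- function() {
    if (!is.null(cur_name) && is_interval)
      tiers[[cur_name]] <<- if (is.null(cur))
        data.frame(xmin = numeric(), xmax = numeric(), label = character()) else cur
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("class\\s*=", ln)) {
      flush()
      is_interval <- grepl("IntervalTier", ln)
      cur_name <- NULL; cur <- NULL
    } else if (grepl("^\\s*name\\s*=", ln)) {
      cur_name <- .tg_str(ln)
    } else if (grepl("intervals\\s*\\[", ln)) {
      xmin <- .tg_num(lines[i + 1])
      xmax <- .tg_num(lines[i + 2])
      lab  <- .tg_str(lines[i + 3])
      row <- data.frame(xmin = xmin, xmax = xmax, label = lab)
      cur <- if (is.null(cur)) row else rbind(cur, row)
      i <- i + 3
    }
    i <- i + 1
  }
  flush()
  tiers
}

.tg_parse_short <- function(lines) {
  # short format: bare values in fixed order after the 7-line header
  vals <- trimws(lines[nzchar(trimws(lines))])
  unq <- function(s) if (grepl('^".*"$', s)) substr(s, 2, nchar(s) - 1) else s
  p <- 7  # skip file type, object class, blank-stripped header xmin/xmax/<exists>/ntiers
  ntier <- as.integer(vals[p - 1])
  tiers <- list()
  for (k in seq_len(ntier)) {
    cls <- unq(vals[p]); name <- unq(vals[p + 1])
    p <- p + 4  # class, name, tier xmin, tier xmax
    n <- as.integer(vals[p]); p <- p + 1
    if (identical(cls, "IntervalTier")) {
      xmin <- numeric(n); xmax <- numeric(n); lab <- character(n)
      for (j in seq_len(n)) {
        xmin[j] <- as.numeric(vals[p]); xmax[j] <- as.numeric(vals[p + 1])
        lab[j] <- unq(vals[p + 2]); p <- p + 3
      }
      tiers[[name]] <- data.frame(xmin = xmin, xmax = xmax, label = lab)
    } else {
      p <- p + 2L * n  # point tier: time, mark
    }
  }
  tiers
}

#' Write a PRAAT TextGrid with a single interval tier
#'
#' @param intervals data.frame with columns `xmin`, `xmax` (seconds) and
#'   `label`. Gaps between labelled intervals are filled with empty-label
#'   intervals so the tier is contiguous, as PRAAT requires.
#' @param path Output path.
#' @param tier_name Name of the interval tier (default `"vowel"`).
#' @param xmax Total duration of the annotated audio; defaults to the last
#'   interval end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(intervals, path, tier_name = "vowel", xmax = NULL) {
  stopifnot(all(c("xmin", "xmax", "label") %in% names(intervals)))
  intervals <- intervals[order(intervals$xmin), , drop = FALSE]
  if (is.null(xmax)) xmax <- max(intervals$xmax)
  # fill gaps with silent intervals
  full <- NULL
  cursor <- 0
  for (i in seq_len(nrow(intervals))) {
    r <- intervals[i, ]
    if (r$xmin > cursor + 1e-9)
      full <- rbind(full, data.frame(xmin = cursor, xmax = r$xmin, label = ""))
    full <- rbind(full, r[, c("xmin", "xmax", "label")])
    cursor <- r$xmax
  }
  if (xmax > cursor + 1e-9)
    full <- rbind(full, data.frame(xmin = cursor, xmax = xmax, label = ""))
  n <- nrow(full)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %.10g", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    sprintf('        name = "%s"', tier_name),
    "        xmin = 0",
    sprintf("        xmax = %.10g", xmax),
    sprintf("        intervals: size = %d", n),
    unlist(lapply(seq_len(n), function(i) c(
      sprintf("        intervals [%d]:", i),
      sprintf("            xmin = %.10g", full$xmin[i]),
      sprintf("            xmax = %.10g", full$xmax[i]),
      sprintf('            text = "%s"', full$label[i])
    )))
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
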