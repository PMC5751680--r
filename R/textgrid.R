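#' Read a Praat TextGrid annotation file
#'
#' Reads a Praat TextGrid in either the long ("ooTextFile") or short text
#' dialect, encoded as UTF-8 or UTF-16 (Praat writes UTF-16 whenever a label
#' contains non-ASCII characters; the byte-order mark is auto-detected).
#' Binary TextGrids are not supported and raise an error.
#'
#' @param path Path to a `.TextGrid` file.
#' @return A tibble with one row per labelled interval and columns
#'   `tier` (tier name), `tier_xmin`, `tier_xmax` (tier time range, seconds),
#'   `label`, `onset`, `offset` (seconds from recording start). Point tiers
#'   present in the file are skipped with a warning. Times follow the Praat
#'   convention: seconds, zero-based, intervals half-open `[onset, offset)`.
#' @seealso [parse_textgrid()], [write_textgrid()], [select_calls()]
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("TextGrid file not found: ", path))
  }
  bom <- readBin(path, "raw", n = 2L)
  enc <- if (length(bom) == 2L && bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) {
    "UTF-16LE"
  } else if (length(bom) == 2L && bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)) {
    "UTF-16BE"
  } else {
    "UTF-8"
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # strip a UTF-8 BOM that survived decoding
  if (length(lines) > 0) lines[1] <- sub("^\ufeff", "", lines[1])
  parse_textgrid(lines)
}

#' Parse TextGrid text content
#'
#' Parses the text of a Praat TextGrid (long or short dialect) into the
#' tabular interval representation used throughout the package.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A tibble of intervals; see [read_textgrid()] for the columns.
#' @export
parse_textgrid <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\r?\n")[[1]]
  }
  toks <- tg_tokenize(text)
  if (length(toks$kind) < 2L ||
      !grepl("ooTextFile", toks$value[1], fixed = TRUE) ||
      !grepl("TextGrid", toks$value[2], fixed = TRUE)) {
    abort("malformed TextGrid header: expected 'ooTextFile' / 'TextGrid' in the first two entries")
  }
  cur <- list(i = 3L, toks = toks)

  num <- function(cur, what) {
    if (cur$i > length(cur$toks$kind)) {
      abort(paste0("truncated TextGrid: expected ", what, " after line ",
                   tail(cur$toks$line, 1)))
    }
    k <- cur$toks$kind[cur$i]
    v <- cur$toks$value[cur$i]
    ln <- cur$toks$line[cur$i]
    if (k != "num") {
      abort(paste0("expected a number (", what, ") at line ", ln, ", got: ", v))
    }
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) {
      abort(paste0("non-numeric value for ", what, " at line ", ln, ": ", v))
    }
    list(x = x, ln = ln, cur = list(i = cur$i + 1L, toks = cur$toks))
  }
  str <- function(cur, what) {
    if (cur$i > length(cur$toks$kind)) {
      abort(paste0("truncated TextGrid: expected ", what, " after line ",
                   tail(cur$toks$line, 1)))
    }
    k <- cur$toks$kind[cur$i]
    v <- cur$toks$value[cur$i]
    ln <- cur$toks$line[cur$i]
    if (k != "str") {
      abort(paste0("expected a quoted string (", what, ") at line ", ln))
    }
    list(x = v, ln = ln, cur = list(i = cur$i + 1L, toks = cur$toks))
  }

  r <- num(cur, "file xmin"); cur <- r$cur
  r <- num(cur, "file xmax"); cur <- r$cur
  # tiers? <exists> flag
  if (cur$i <= length(cur$toks$kind) && cur$toks$kind[cur$i] == "exists") {
    cur$i <- cur$i + 1L
  }
  r <- num(cur, "tier count"); cur <- r$cur
  n_tiers <- r$x

  rows <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    r <- str(cur, "tier class"); cur <- r$cur
    cls <- r$x
    r <- str(cur, "tier name"); cur <- r$cur
    tier_name <- r$x
    r <- num(cur, "tier xmin"); cur <- r$cur
    txmin <- r$x
    r <- num(cur, "tier xmax"); cur <- r$cur
    txmax <- r$x
    r <- num(cur, "interval count"); cur <- r$cur
    n_int <- r$x
    if (cls == "IntervalTier") {
      onset <- offset <- numeric(n_int)
      label <- character(n_int)
      for (j in seq_len(n_int)) {
        r <- num(cur, "interval xmin"); cur <- r$cur
        onset[j] <- r$x
        r <- num(cur, "interval xmax"); cur <- r$cur
        offset[j] <- r$x
        ln <- r$ln
        r <- str(cur, "interval text"); cur <- r$cur
        label[j] <- r$x
        if (offset[j] <= onset[j]) {
          abort(paste0("interval with offset <= onset near line ", ln,
                       " in tier '", tier_name, "' [", onset[j], ", ", offset[j], "]"))
        }
      }
      rows[[t]] <- tibble(
        tier = tier_name, tier_xmin = txmin, tier_xmax = txmax,
        label = label, onset = onset, offset = offset
      )
    } else if (cls == "TextTier") {
      warn(paste0("point tier '", tier_name, "' ignored (only interval tiers are analysed)"))
      for (j in seq_len(n_int)) {
        r <- num(cur, "point time"); cur <- r$cur
        r <- str(cur, "point mark"); cur <- r$cur
      }
      rows[[t]] <- NULL
    } else {
      abort(paste0("unknown tier class '", cls, "'"))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(tier = character(), tier_xmin = numeric(), tier_xmax = numeric(),
                  label = character(), onset = numeric(), offset = numeric())
  }
  out
}

# Tokenize TextGrid lines into (line number, kind, value) streams.
# kinds: "str" (quoted), "num" (bare value / after '='), "exists" (flag line).
tg_tokenize <- function(lines) {
  line_no <- integer(0); kind <- character(0); value <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    # long-format structural lines: item []: / item [1]: / intervals [1]: ...
    if (grepl("^\\w+\\s*\\[\\d*\\]\\s*:$", ln)) next
    if (grepl("<exists>", ln, fixed = TRUE) || grepl("<absent>", ln, fixed = TRUE)) {
      line_no <- c(line_no, i); kind <- c(kind, "exists"); value <- c(value, ln)
      next
    }
    # key-value lines ('xmin = 0', 'text = "a"') keep the text after the
    # first '='; bare short-dialect lines pass through unchanged
    v <- if (grepl("=", ln, fixed = TRUE) && !grepl("^\"", ln)) {
      trimws(sub("^[^=]*=", "", ln))
    } else {
      ln
    }
    if (grepl("^\".*\"$", v)) {
      s <- substr(v, 2L, nchar(v) - 1L)
      s <- gsub("\"\"", "\"", s, fixed = TRUE)
      line_no <- c(line_no, i); kind <- c(kind, "str"); value <- c(value, s)
    } else if (grepl("^\"", v)) {
      abort(paste0("unterminated or multi-line string at line ", i,
                   " (multi-line labels are not supported)"))
    } else {
      line_no <- c(line_no, i); kind <- c(kind, "num"); value <- c(value, v)
    }
  }
  list(line = line_no, kind = kind, value = value)
}

#' Write a TextGrid file (long dialect)
#'
#' Serializes an interval table back to Praat's long ("ooTextFile") dialect.
#' Gaps between consecutive intervals, and the margins out to the tier range,
#' are filled with empty-label intervals so the emitted tier tiles its time
#' range as Praat requires.
#'
#' @param tg Tibble of intervals as returned by [read_textgrid()]. The
#'   `tier_xmin`/`tier_xmax` columns are optional; when absent the tier range
#'   is taken from the interval extremes.
#' @param path Output path. When `NULL` the lines are returned invisibly
#'   instead of written.
#' @return Invisibly, the lines written (character vector).
#' @export
write_textgrid <- function(tg, path = NULL) {
  stopifnot(is.data.frame(tg), all(c("tier", "label", "onset", "offset") %in% names(tg)))
  if (nrow(tg) > 0 && any(tg$offset <= tg$onset)) {
    abort("every interval must have onset < offset")
  }
  tiers <- unique(tg$tier)
  fmt <- function(x) formatC(x, format = "fg", digits = 15)

  tier_blocks <- vector("list", length(tiers))
  gxmin <- Inf; gxmax <- -Inf
  for (t in seq_along(tiers)) {
    d <- tg[tg$tier == tiers[t], , drop = FALSE]
    d <- d[order(d$onset), , drop = FALSE]
    if (any(d$onset[-1] < d$offset[-nrow(d)])) {
      abort(paste0("overlapping intervals in tier '", tiers[t], "'"))
    }
    txmin <- if ("tier_xmin" %in% names(d)) d$tier_xmin[1] else min(d$onset)
    txmax <- if ("tier_xmax" %in% names(d)) d$tier_xmax[1] else max(d$offset)
    # tile the tier range with empty-label filler intervals
    on <- numeric(0); off <- numeric(0); lab <- character(0)
    cursor <- txmin
    for (j in seq_len(nrow(d))) {
      if (d$onset[j] > cursor) {
        on <- c(on, cursor); off <- c(off, d$onset[j]); lab <- c(lab, "")
      }
      on <- c(on, d$onset[j]); off <- c(off, d$offset[j]); lab <- c(lab, d$label[j])
      cursor <- d$offset[j]
    }
    if (cursor < txmax) {
      on <- c(on, cursor); off <- c(off, txmax); lab <- c(lab, "")
    }
    if (length(on) == 0L) {  # fully empty tier
      on <- txmin; off <- txmax; lab <- ""
    }
    esc <- gsub("\"", "\"\"", lab, fixed = TRUE)
    blk <- c(
      sprintf("    item [%d]:", t),
      "        class = \"IntervalTier\"",
      sprintf("        name = \"%s\"", gsub("\"", "\"\"", tiers[t], fixed = TRUE)),
      sprintf("        xmin = %s", fmt(txmin)),
      sprintf("        xmax = %s", fmt(txmax)),
      sprintf("        intervals: size = %d", length(on)),
      unlist(lapply(seq_along(on), function(j) c(
        sprintf("        intervals [%d]:", j),
        sprintf("            xmin = %s", fmt(on[j])),
        sprintf("            xmax = %s", fmt(off[j])),
        sprintf("            text = \"%s\"", esc[j])
      )))
    )
    tier_blocks[[t]] <- blk
    gxmin <- min(gxmin, txmin); gxmax <- max(gxmax, txmax)
  }
  if (length(tiers) == 0L) { gxmin <- 0; gxmax <- 0 }
  lines <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    sprintf("xmin = %s", fmt(gxmin)),
    sprintf("xmax = %s", fmt(gxmax)),
    "tiers? <exists>",
    sprintf("size = %d", length(tiers)),
    "item []:",
    unlist(tier_blocks)
  )
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = FALSE)
  }
  invisible(lines)
}

#' Select the calls retained for analysis
#'
#' Filters an annotation table down to the intervals whose label matches one
#' of the retained categories — typically the mother-attraction calls
#' (`"MAC"`), the only call type entering the temporal computations.
#' Matching is exact and case-sensitive; by default labels are
#' whitespace-stripped first, so `"MAC "` matches `"MAC"`. Silences (empty
#' labels) are never retained unless `""` is listed explicitly.
#'
#' @param tg Interval tibble from [read_textgrid()] / [parse_textgrid()].
#' @param labels Character vector of labels to retain. Must be non-empty.
#' @param tier Tier name to restrict to; `NULL` (default) uses all tiers
#'   present (errors if the named tier is absent).
#' @param strip Strip leading/trailing whitespace from labels before
#'   matching (default `TRUE`).
#' @return Tibble of retained calls (`label`, `onset`, `offset`, plus the
#'   tier columns), in temporal order.
#' @export
select_calls <- function(tg, labels = "MAC", tier = NULL, strip = TRUE) {
  stopifnot(is.data.frame(tg))
  if (length(labels) == 0L) abort("'labels' must name at least one category to retain")
  if (!is.null(tier)) {
    if (!tier %in% tg$tier) {
      abort(paste0("tier '", tier, "' not found; available: ",
                   paste(unique(tg$tier), collapse = ", ")))
    }
    tg <- tg[tg$tier == tier, , drop = FALSE]
  }
  lab <- if (strip) trimws(tg$label) else tg$label
  out <- tg[lab %in% labels, , drop = FALSE]
  out <- out[order(out$onset), , drop = FALSE]
  tibble::as_tibble(out)
}
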