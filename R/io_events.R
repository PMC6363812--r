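# Event-table file IO.  The primary on-disk form is a documented CSV
# dialect: comma separator, dot decimal, UTF-8, required header, one event
# per row, columns fl3, ssc and (optionally) true_label.  A minimal FCS 3.1
# list-mode adapter (float32, channels FL3/SSC) is provided for
# interoperability with instrument exports.

fl_synonyms <- c("fl3", "fl3-a", "fl3.a", "fl3_a", "fl3-h", "fl3.h",
                 "fluorescence", "fl", "pi")
ssc_synonyms <- c("ssc", "ssc-a", "ssc.a", "ssc_a", "ssc-h", "ssc.h",
                  "side_scatter", "side scatter", "sidescatter")

match_channel <- function(headers, synonyms, label) {
  i <- which(tolower(trimws(headers)) %in% synonyms)
  if (!length(i))
    stop_fmt("required channel '%s' not found (columns: %s)",
             label, paste(headers, collapse = ", "))
  i[1L]
}

#' Read a listmode event table
#'
#' Reads the documented CSV dialect (or, for `.fcs` files, a minimal FCS
#' 3.0/3.1 list-mode subset).  Channel headers are matched
#' case-insensitively against FL3/SSC and common synonyms (`FL3-A`,
#' `SSC-A`, ...).  Rows with non-positive or non-finite fluorescence are
#' dropped; the count of dropped rows is reported via a message and the
#' `"dropped"` attribute.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @return An [event_table()]; attribute `"dropped"` holds the number of
#'   invalid rows removed.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  raw <- if (format == "fcs") read_fcs_table(path) else read_csv_table(path)
  keep <- is.finite(raw$fl3) & raw$fl3 > 0 & is.finite(raw$ssc) & raw$ssc >= 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("read_events: dropped %d row(s) with non-positive or non-finite values", dropped))
  out <- event_table(raw$fl3[keep], raw$ssc[keep],
                     if (!is.null(raw$true_label)) raw$true_label[keep])
  attr(out, "dropped") <- dropped
  out
}

read_csv_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop_fmt("empty input: %s contains no events", path)
  fi <- match_channel(names(df), fl_synonyms, "FL3")
  si <- match_channel(names(df), ssc_synonyms, "SSC")
  out <- data.frame(fl3 = as.numeric(df[[fi]]), ssc = as.numeric(df[[si]]))
  li <- which(tolower(names(df)) == "true_label")
  if (length(li)) out$true_label <- as.character(df[[li[1L]]])
  out
}

#' Write a listmode event table
#'
#' Writes the documented CSV dialect with deterministic column order
#' (`fl3`, `ssc`, then `true_label` if present), or a minimal FCS 3.1 file
#' with channels named FL3 and SSC (float32 list mode).
#'
#' @param table An [event_table()] (or data.frame with `fl3`/`ssc`).
#' @param path Output path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  table <- as_event_table(table)
  if (format == "fcs") return(write_fcs_table(table, path))
  cols <- intersect(c("fl3", "ssc", "true_label"), names(table))
  df <- as.data.frame(table)[, cols, drop = FALSE]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal FCS 3.1 adapter -------------------------------------------------

write_fcs_table <- function(table, path) {
  n <- nrow(table)
  dat <- as.numeric(t(as.matrix(as.data.frame(table)[, c("fl3", "ssc")])))
  rng <- function(v) format(ceiling(max(c(v, 1))), scientific = FALSE)
  make_text <- function(db, de) {
    paste0("/$BEGINANALYSIS/0/$ENDANALYSIS/0",
           sprintf("/$BEGINDATA/%010d/$ENDDATA/%010d", db, de),
           "/$BEGINSTEXT/0/$ENDSTEXT/0",
           "/$BYTEORD/1,2,3,4/$DATATYPE/F/$MODE/L/$NEXTDATA/0",
           sprintf("/$PAR/2/$TOT/%d", n),
           sprintf("/$P1N/FL3/$P1B/32/$P1E/0,0/$P1R/%s", rng(table$fl3)),
           sprintf("/$P2N/SSC/$P2B/32/$P2E/0,0/$P2R/%s/", rng(table$ssc)))
  }
  text_len <- nchar(make_text(0, 0))
  text_begin <- 58L
  text_end <- text_begin + text_len - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * length(dat) - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(make_text(data_begin, data_end)), con)
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs_table <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(bytes) < 58L) stop_fmt("not an FCS file: %s", path)
  hdr <- rawToChar(bytes[1:58])
  if (!grepl("^FCS3", hdr)) stop_fmt("unsupported FCS version in %s", path)
  off <- function(a, b) suppressWarnings(as.integer(trimws(substr(hdr, a, b))))
  tb <- off(11, 18); te <- off(19, 26)
  db <- off(27, 34); de <- off(35, 42)
  txt <- rawToChar(bytes[(tb + 1L):(te + 1L)])
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2L, length(parts), 2L)],
                 toupper(trimws(parts[seq(1L, length(parts), 2L)])))
  if (is.na(db) || db == 0L) db <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(de) || de == 0L) de <- as.integer(kw[["$ENDDATA"]])
  if (!identical(toupper(kw[["$DATATYPE"]]), "F"))
    stop_fmt("only float FCS data ($DATATYPE F) is supported")
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  npar <- as.integer(kw[["$PAR"]])
  tot <- as.integer(kw[["$TOT"]])
  con <- rawConnection(bytes[(db + 1L):(de + 1L)])
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = npar * tot, size = 4L,
                  endian = endian)
  m <- matrix(vals, ncol = npar, byrow = TRUE)
  pn <- vapply(seq_len(npar),
               function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i),
               character(1))
  if (tot == 0L) stop_fmt("empty input: %s contains no events", path)
  fi <- match_channel(pn, fl_synonyms, "FL3")
  si <- match_channel(pn, ssc_synonyms, "SSC")
  data.frame(fl3 = m[, fi], ssc = m[, si])
}
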