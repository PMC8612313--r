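#' Read a message table from CSV or JSON Lines
#'
#' A corpus is a table with one row per reported message and columns
#' `message_id`, `report_timestamp`, `user_hash`, `text`. Timestamps must be
#' ISO-8601 with a timezone offset (e.g. `2020-02-02T09:15:00+08:00`);
#' unparseable timestamps are an error naming the offending row.
#'
#' @param path Path to a UTF-8 CSV (RFC-4180) or JSON Lines file.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#' @return A tibble of messages in file order with columns `message_id`
#'   (character), `report_timestamp` (`POSIXct`), `user_hash` (character),
#'   `text` (character).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("message_id,report_timestamp,user_hash,text",
#'              "m1,2020-02-02T09:15:00+08:00,u1,hello"), f)
#' read_messages(f)
#' @export
read_messages <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      df <- data.frame(message_id = character(), report_timestamp = character(),
                       user_hash = character(), text = character())
    } else {
      recs <- lapply(lines, jsonlite::fromJSON)
      df <- do.call(rbind, lapply(recs, function(r)
        data.frame(lapply(r, function(v) as.character(v %||% NA_character_)),
                   stringsAsFactors = FALSE)))
    }
  }
  required <- c("message_id", "report_timestamp", "user_hash", "text")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("input is missing required column(s): ", paste(missing, collapse = ", "))
  }
  ts <- parse_iso8601(df$report_timestamp)
  bad <- which(is.na(ts) & !is.na(df$report_timestamp))
  if (length(bad) > 0) {
    stop("unparseable report_timestamp at row ", bad[1],
         ": \"", df$report_timestamp[bad[1]], "\"")
  }
  tibble::tibble(
    message_id = as.character(df$message_id),
    report_timestamp = ts,
    user_hash = as.character(df$user_hash),
    text = as.character(df$text)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 with offset; also accepts "Z" and a space separator.
parse_iso8601 <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  x <- sub("^(\\d{4}-\\d{2}-\\d{2}) ", "\\1T", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  # date-only fallback is deliberately not accepted: report times matter
  out
}

#' Write messages to CSV or JSON Lines
#'
#' Inverse of [read_messages()]; timestamps are serialized as ISO-8601 UTC+8
#' (the study timezone) unless `tz` says otherwise.
#'
#' @param messages Message tibble as returned by [read_messages()].
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param tz Timezone used to render timestamps.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path, format = c("csv", "jsonl"),
                           tz = "Etc/GMT-8") {
  format <- match.arg(format)
  out <- data.frame(
    message_id = messages$message_id,
    report_timestamp = strftime(messages$report_timestamp,
                                "%Y-%m-%dT%H:%M:%S%z", tz = tz),
    user_hash = messages$user_hash,
    text = messages$text,
    stringsAsFactors = FALSE
  )
  # restore the RFC-3339 colon in the offset
  out$report_timestamp <- sub("([+-]\\d{2})(\\d{2})$", "\\1:\\2",
                              out$report_timestamp)
  if (format == "csv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    write.csv(out, con, row.names = FALSE)
  } else {
    writeLines(vapply(seq_len(nrow(out)), function(i)
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE), character(1)),
      path, useBytes = TRUE)
  }
  invisible(path)
}

#' Strip characters outside a configured script
#'
#' The preprocessing pipeline keeps only Chinese text: every character that is
#' neither simplified nor traditional Chinese (both live in the CJK Unified
#' Ideographs blocks, including extensions) is removed. Synthetic corpora made
#' of latin word symbols use `keep = "none"` to skip the filter.
#'
#' @param text Character vector.
#' @param keep `"han"` (default) keeps CJK ideographs only; `"latin"` keeps
#'   ASCII letters, digits and whitespace; `"none"` returns the text
#'   unchanged; any other string is interpreted as a regex character class of
#'   characters to keep.
#' @return Character vector of filtered text.
#' @examples
#' filter_characters("武漢 COVID-19!!") # keeps only the ideographs
#' @export
filter_characters <- function(text, keep = "han") {
  if (identical(keep, "none")) return(text)
  cls <- switch(keep,
    han = "\\p{Han}",
    latin = "A-Za-z0-9\\s",
    keep
  )
  gsub(paste0("[^", cls, "]"), "", text, perl = TRUE)
}

#' Tokenizers
#'
#' Tokenization is pluggable: a tokenizer is any function mapping one string
#' to an ordered character vector of tokens. `tokenizer_whitespace()` splits
#' on runs of whitespace (the default for synthetic corpora).
#' `tokenizer_dictionary()` is a forward-maximum-matching segmenter for
#' Chinese driven by a plain-text word list (one word per line), falling back
#' to single characters; the packaged dictionary covers common words of the
#' pandemic-rumor domain and can be replaced wholesale.
#'
#' @param dict Character vector of dictionary words, or a path to a word-list
#'   file; defaults to the packaged dictionary.
#' @return A function `function(text) -> character vector` of tokens.
#' @examples
#' tok <- tokenizer_whitespace()
#' tok("a b  c")
#' @export
tokenizer_whitespace <- function() {
  function(text) {
    toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
    toks[nzchar(toks)]
  }
}

#' @rdname tokenizer_whitespace
#' @export
tokenizer_dictionary <- function(dict = NULL) {
  if (is.null(dict)) dict <- rm_extdata("segdict_zh.txt")
  if (length(dict) == 1 && file.exists(dict)) dict <- read_lexicon_file(dict)
  dict <- unique(dict[nzchar(dict)])
  words <- new.env(hash = TRUE, parent = emptyenv())
  for (w in dict) assign(w, TRUE, envir = words)
  max_len <- if (length(dict)) max(nchar(dict)) else 1L
  function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    n <- length(chars)
    toks <- character(0)
    i <- 1L
    while (i <= n) {
      matched <- 1L
      for (len in seq(min(max_len, n - i + 1L), 2L)) {
        if (len < 2L) break
        cand <- paste(chars[i:(i + len - 1L)], collapse = "")
        if (exists(cand, envir = words, inherits = FALSE)) {
          matched <- len
          break
        }
      }
      toks <- c(toks, paste(chars[i:(i + matched - 1L)], collapse = ""))
      i <- i + matched
    }
    toks
  }
}

#' Packaged Chinese stop-word list
#'
#' @return Character vector of stop words (one token each); the underlying
#'   file under `extdata/stopwords_zh.txt` is plain text and editable.
#' @export
stopwords_zh <- function() read_lexicon_file(rm_extdata("stopwords_zh.txt"))

#' Preprocess messages into tokenized documents
#'
#' Pipeline order: character filter, tokenize, drop stop-word tokens, drop
#' documents with fewer than `min_tokens` remaining tokens. Token counts are
#' therefore post-stop-word counts. The surviving documents keep corpus order,
#' and each carries its ordered token list plus the derived distinct-token
#' set (equivalent to a binary word vector).
#'
#' @param messages Message tibble from [read_messages()] (or any tibble with
#'   `message_id` and `text`).
#' @param tokenizer A tokenizer function; see [tokenizer_whitespace()].
#' @param stopwords Character vector of stop-word tokens to drop (may be
#'   empty).
#' @param min_tokens Minimum number of tokens (after stop-word removal) a
#'   document needs to be kept; default 20.
#' @param keep Script filter passed to [filter_characters()].
#' @return A tibble of tokenized documents: `message_id`, `tokens`
#'   (list-column of character vectors), `token_set` (list-column of distinct
#'   tokens), `n_tokens`.
#' @examples
#' msgs <- tibble::tibble(message_id = "m1", text = paste(letters[1:21], collapse = " "))
#' preprocess(msgs, tokenizer_whitespace(), character(), min_tokens = 20, keep = "none")
#' @export
preprocess <- function(messages, tokenizer = tokenizer_dictionary(),
                       stopwords = stopwords_zh(), min_tokens = 20,
                       keep = "han") {
  stopifnot(is.function(tokenizer), min_tokens >= 0)
  txt <- filter_characters(messages$text, keep = keep)
  toks <- lapply(txt, function(t) {
    tk <- tokenizer(t)
    if (length(stopwords)) tk <- tk[!(tk %in% stopwords)]
    tk
  })
  n <- lengths(toks)
  keep_doc <- n >= min_tokens
  tibble::tibble(
    message_id = as.character(messages$message_id)[keep_doc],
    tokens = toks[keep_doc],
    token_set = lapply(toks[keep_doc], unique),
    n_tokens = as.integer(n[keep_doc])
  )
}

#' Write tokenized documents as JSON Lines
#'
#' One object per line with fields `message_id` and `tokens`.
#'
#' @param docs Tokenized-document tibble from [preprocess()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tokenized <- function(docs, path) {
  writeLines(vapply(seq_len(nrow(docs)), function(i)
    jsonlite::toJSON(list(message_id = docs$message_id[i],
                          tokens = docs$tokens[[i]]),
                     auto_unbox = TRUE), character(1)),
    path, useBytes = TRUE)
  invisible(path)
}
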