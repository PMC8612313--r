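# Build a tokenized-document tibble directly from token vectors.
make_docs <- function(..., ids = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.character(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (is.null(ids)) ids <- sprintf("d%02d", seq_along(sets))
  tibble::tibble(
    message_id = ids,
    tokens = sets,
    token_set = lapply(sets, unique),
    n_tokens = lengths(sets)
  )
}

# Message tibble from texts and ISO timestamps (UTC+8 unless given).
make_messages <- function(text, timestamp = NULL, ids = NULL) {
  n <- length(text)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(n))
  if (is.null(timestamp)) timestamp <- rep("2020-02-01T12:00:00+08:00", n)
  ts <- as.POSIXct(sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", timestamp),
                   format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  tibble::tibble(message_id = ids, report_timestamp = ts,
                 user_hash = rep("u", n), text = text)
}

# Random token-set corpus over a small vocabulary (ties in distances are
# possible and welcome: the clustering must cope with them).
random_corpus <- function(n, vocab = letters, set_sizes = 3:8) {
  sets <- lapply(seq_len(n), function(i)
    sample(vocab, sample(set_sizes, 1)))
  make_docs(sets)
}
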