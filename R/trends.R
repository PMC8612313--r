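#' Daily report counts for one rumor group
#'
#' Messages are binned by calendar day in the configured timezone (default
#' UTC+8, the study region's local time); days with no reports between the
#' first and last observed date are zero-filled so resurfacing gaps are
#' visible.
#'
#' @param messages Message tibble (rows of one group) with a
#'   `report_timestamp` column.
#' @param tz Timezone for day binning; default `"Etc/GMT-8"` (UTC+8).
#' @return Tibble with `date` (consecutive `Date`s) and `count`; empty for an
#'   empty group. The counts sum to the group size.
#' @export
daily_counts <- function(messages, tz = "Etc/GMT-8") {
  if (nrow(messages) == 0) {
    return(tibble::tibble(date = as.Date(character()), count = integer()))
  }
  days <- as.Date(messages$report_timestamp, tz = tz)
  full <- seq(min(days), max(days), by = "day")
  counts <- tabulate(match(days, full), nbins = length(full))
  tibble::tibble(date = full, count = as.integer(counts))
}

#' Resurfacing peaks in a daily series
#'
#' A day is a peak when its count is at least `min_count` and strictly
#' exceeds the count of every other day within `window` days on either side.
#' The floor suppresses trickle noise; the strict local maximum means flat
#' stretches yield no peak. Both parameters are conventions of this package
#' and should be reported with any result.
#'
#' @param series Tibble from [daily_counts()].
#' @param window Half-width of the comparison window, in days; default 3.
#' @param min_count Minimum count for a day to qualify; default 10.
#' @return Tibble with `date` and `count` of each peak, chronological.
#' @export
find_peaks <- function(series, window = 3, min_count = 10) {
  n <- nrow(series)
  if (n == 0) return(tibble::tibble(date = as.Date(character()), count = integer()))
  counts <- series$count
  is_peak <- vapply(seq_len(n), function(i) {
    if (counts[i] < min_count) return(FALSE)
    nb <- seq(max(1, i - window), min(n, i + window))
    nb <- nb[nb != i]
    all(counts[i] > counts[nb])
  }, logical(1))
  series[is_peak, c("date", "count")]
}

#' Quoted-party attribution counts
#'
#' Rumors borrow credibility by (mis)quoting authorities; this counts, per
#' party, the messages naming any of the party's aliases as a substring. A
#' message naming several parties counts toward each of them.
#'
#' @param messages Message tibble (rows of one group) with `text` and, when
#'   `by_day`, `report_timestamp`.
#' @param lexicon Named list: party name -> character vector of aliases.
#' @param by_day When `TRUE`, counts are broken down by calendar day.
#' @param tz Timezone for day binning (only with `by_day`).
#' @return Tibble with `party`, `count` (and `date` when `by_day`).
#' @examples
#' msgs <- tibble::tibble(text = c("陳時中提醒", "鍾南山強調", "無人引述"))
#' attribution_counts(msgs, list(chen = "陳時中", zhong = c("鍾南山", "鐘南山")))
#' @export
attribution_counts <- function(messages, lexicon, by_day = FALSE,
                               tz = "Etc/GMT-8") {
  if (length(lexicon) == 0) {
    return(if (by_day)
      tibble::tibble(party = character(), date = as.Date(character()),
                     count = integer())
    else tibble::tibble(party = character(), count = integer()))
  }
  stopifnot(!is.null(names(lexicon)), all(nzchar(names(lexicon))))
  hit_party <- function(aliases) {
    hit <- rep(FALSE, nrow(messages))
    for (al in aliases) {
      miss <- !hit
      if (!any(miss)) break
      hit[miss] <- grepl(al, messages$text[miss], fixed = TRUE)
    }
    hit
  }
  hits <- lapply(lexicon, hit_party)
  if (!by_day) {
    return(tibble::tibble(party = names(lexicon),
                          count = unname(vapply(hits, sum, integer(1)))))
  }
  days <- as.Date(messages$report_timestamp, tz = tz)
  out <- lapply(names(lexicon), function(p) {
    h <- hits[[p]]
    if (!any(h)) return(NULL)
    tab <- table(days[h])
    tibble::tibble(party = p, date = as.Date(names(tab)),
                   count = as.integer(tab))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tibble::tibble(party = character(), date = as.Date(character()),
                          count = integer())
  }
  out[order(out$party, out$date), ]
}

#' Variant first-seen timeline for one rumor group
#'
#' Collapses messages to textual variants keyed by whitespace-normalized
#' text and reports when each variant was first reported and how often it
#' occurs — the quantitative scaffold for a manually curated change log of a
#' rumor's textual transformations.
#'
#' @param messages Message tibble (rows of one group) with `text` and
#'   `report_timestamp`.
#' @param tz Timezone for the first-seen date.
#' @return Tibble with `variant` (normalized text), `first_seen` (`Date`),
#'   `count`, sorted by `first_seen` then by first appearance.
#' @export
variant_timeline <- function(messages, tz = "Etc/GMT-8") {
  if (nrow(messages) == 0) {
    return(tibble::tibble(variant = character(),
                          first_seen = as.Date(character()),
                          count = integer()))
  }
  norm <- gsub("\\s+", " ", trimws(messages$text))
  days <- as.Date(messages$report_timestamp, tz = tz)
  key <- factor(norm, levels = unique(norm))
  first_seen <- as.Date(unname(tapply(days, key, min)), origin = "1970-01-01")
  out <- tibble::tibble(variant = levels(key),
                        first_seen = first_seen,
                        count = as.integer(table(key)))
  out[order(out$first_seen), ]
}

#' Join an event annotation table onto a daily series
#'
#' Societal events are supplied by the user as a CSV with columns `date` and
#' `label`; this merely left-joins them for display alongside counts (no
#' event detection is performed).
#'
#' @param series Tibble from [daily_counts()].
#' @param events Data frame with `date` (ISO date) and `label`.
#' @return `series` with an added `event` column (`NA` where none).
#' @export
join_events <- function(series, events) {
  ev <- stats::setNames(as.character(events$label), as.character(as.Date(events$date)))
  series$event <- unname(ev[as.character(series$date)])
  series
}
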