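#' Packaged COVID-19 keyword lexicon
#'
#' The 33 pandemic-related keywords (Chinese terms such as the city name at
#' the outbreak origin, quarantine and mask vocabulary, plus latin terms like
#' "covid" and "coronavirus") used to pre-screen rumor groups for
#' COVID-19-relatedness. Terms are matched case-insensitively as substrings
#' of the raw message text, before any character filtering, because the latin
#' terms would not survive the Chinese character filter.
#'
#' @param path Optional path to an alternative one-term-per-line UTF-8 file.
#' @return Character vector of lowercase terms.
#' @export
covid_keywords <- function(path = NULL) {
  if (is.null(path)) path <- rm_extdata("covid_keywords.txt")
  tolower(read_lexicon_file(path))
}

#' Does a message contain any lexicon keyword?
#'
#' Case-insensitive substring matching on the raw (unfiltered) text.
#'
#' @param text Character vector of raw message texts.
#' @param lexicon Character vector of terms; default [covid_keywords()].
#' @return Logical vector, one element per text.
#' @examples
#' message_has_keyword(c("hello COVID world", "nothing here"))
#' @export
message_has_keyword <- function(text, lexicon = covid_keywords()) {
  lt <- tolower(text)
  hit <- rep(FALSE, length(lt))
  for (term in tolower(lexicon)) {
    miss <- !hit
    if (!any(miss)) break
    hit[miss] <- grepl(term, lt[miss], fixed = TRUE)
  }
  hit & !is.na(text) & nzchar(text)
}

#' Flag candidate COVID-19-related rumor groups
#'
#' A group is a COVID-19 candidate when strictly more than
#' `threshold` (default 60%) of its messages contain a keyword. Candidates
#' require manual confirmation (the adjudication step is human by design);
#' once a group is confirmed, every member message inherits
#' COVID-19-relatedness regardless of its own keywords — see
#' [message_covid_status()].
#'
#' @param labeling Label vector (names are message ids).
#' @param text Character vector of raw texts aligned with `labeling`.
#' @param lexicon Keyword lexicon; default [covid_keywords()].
#' @param threshold Strict lower bound on the keyword fraction; default 0.60.
#' @return Tibble with `group_id`, `size`, `n_keyword`, `keyword_fraction`,
#'   `covid_candidate` (logical), `confirmed` (logical, `NA` until a human
#'   fills it in), sorted by size descending.
#' @export
flag_covid_groups <- function(labeling, text, lexicon = covid_keywords(),
                              threshold = 0.60) {
  stopifnot(length(labeling) == length(text))
  hits <- message_has_keyword(text, lexicon)
  gid <- as.integer(labeling)
  size <- tapply(hits, gid, length)
  n_kw <- tapply(hits, gid, sum)
  frac <- as.numeric(n_kw) / as.numeric(size)
  out <- tibble::tibble(
    group_id = as.integer(names(size)),
    size = as.integer(size),
    n_keyword = as.integer(n_kw),
    keyword_fraction = frac,
    covid_candidate = frac > threshold,
    confirmed = NA
  )
  out[order(-out$size, out$group_id), ]
}

#' Per-message COVID-19-relatedness after group confirmation
#'
#' @param labeling Label vector.
#' @param confirmed_group_ids Integer ids of groups confirmed as
#'   COVID-19-related.
#' @return Logical vector: `TRUE` for every member of a confirmed group.
#' @export
message_covid_status <- function(labeling, confirmed_group_ids) {
  as.integer(labeling) %in% as.integer(confirmed_group_ids)
}

#' Packaged simplified-script lexicon
#'
#' Characters whose simplified form differs from the traditional form (so
#' their presence in a traditional-script region signals probable
#' mainland-China origin), plus a small editable list of mainland-usage
#' phrases. Both ship as plain-text files under `extdata/` and can be
#' replaced.
#'
#' @param char_path,phrase_path Optional alternative files: a TSV with
#'   columns `simplified` and `traditional`, and a one-phrase-per-line list.
#' @return A list with `simplified_chars` (character vector of single
#'   codepoints) and `phrases`.
#' @export
script_lexicon <- function(char_path = NULL, phrase_path = NULL) {
  if (is.null(char_path)) char_path <- rm_extdata("simplified_traditional.tsv")
  if (is.null(phrase_path)) phrase_path <- rm_extdata("china_phrases.txt")
  map <- read.delim(char_path, fileEncoding = "UTF-8",
                    colClasses = "character")
  simp <- unique(map$simplified)
  trad <- unique(map$traditional)
  simp <- setdiff(simp, trad)  # keep only codepoints that are simplified-only
  list(simplified_chars = simp, phrases = read_lexicon_file(phrase_path))
}

#' Flag probable mainland-origin script in a message
#'
#' `TRUE` iff the text contains at least one simplified-only character or at
#' least one lexicon phrase.
#'
#' @param text Character vector of raw texts.
#' @param lexicon Script lexicon from [script_lexicon()].
#' @return Logical vector.
#' @examples
#' lex <- script_lexicon()
#' flag_script_origin(c("医师", "醫師"), lex) # TRUE, FALSE
#' @export
flag_script_origin <- function(text, lexicon = script_lexicon()) {
  char_class <- paste0("[", paste(lexicon$simplified_chars, collapse = ""), "]")
  hit <- grepl(char_class, text, perl = TRUE)
  for (ph in lexicon$phrases) {
    miss <- !hit
    if (!any(miss)) break
    hit[miss] <- grepl(ph, text[miss], fixed = TRUE)
  }
  hit & !is.na(text)
}

#' Build a 2x2 contingency table from two logical annotations
#'
#' Rows are `related` yes/no, columns `flagged` yes/no, in the order
#' (yes, no) on both margins.
#'
#' @param related,flagged Logical vectors of equal length (e.g. per-message
#'   COVID-19-relatedness and script-origin flags).
#' @return A 2x2 integer matrix with counts `a` = related & flagged,
#'   `b` = related & !flagged, `c` = !related & flagged, `d` = neither.
#' @export
contingency_2x2 <- function(related, flagged) {
  stopifnot(length(related) == length(flagged))
  m <- matrix(c(sum(related & flagged), sum(related & !flagged),
                sum(!related & flagged), sum(!related & !flagged)),
              nrow = 2, byrow = TRUE,
              dimnames = list(related = c("yes", "no"),
                              flagged = c("yes", "no")))
  m[] <- as.integer(m)
  m
}

#' Chi-square test of independence with Yates' continuity correction
#'
#' For a 2x2 table with cells a, b / c, d and total n, the statistic is
#' \deqn{\chi^2 = \frac{n\,(|ad - bc| - n/2)^2}{(a+b)(c+d)(a+c)(b+d)}}
#' clamped to 0 when `|ad - bc| <= n/2` (the correction subtracts n/2 from
#' `|ad - bc|` to reduce the upward bias of the uncorrected statistic at one
#' degree of freedom). The p-value comes from the chi-square distribution
#' with 1 df.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d); alternatively pass
#'   a 2x2 matrix as `a`.
#' @return A list of class `rumor_chisq`: `statistic`, `df` (1), `p_value`,
#'   `n`. All four margins must be positive.
#' @examples
#' chi_square_yates(20, 10, 10, 20) # statistic 5.4
#' @export
chi_square_yates <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all margins of the 2x2 table must be positive")
  delta <- abs(a * d - b * c)
  stat <- if (delta <= n / 2) 0 else n * (delta - n / 2)^2 / prod(margins)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n = n),
            class = "rumor_chisq")
}

#' @export
print.rumor_chisq <- function(x, ...) {
  cat(sprintf("Chi-square independence test, Yates-corrected: X2(1) = %.1f, n = %d, P %s\n",
              x$statistic, x$n, format_p(x$p_value)))
  invisible(x)
}

#' Format a p-value in reporting style
#'
#' Values below .001 are reported as `"<.001"`.
#'
#' @param p A p-value.
#' @return Character scalar, e.g. `"<.001"` or `"=.03"`.
#' @export
format_p <- function(p) {
  if (p < 0.001) "<.001" else paste0("=", sub("^0", "", sprintf("%.3f", p)))
}

#' Percentage of a whole, rounded half-up to one decimal
#'
#' @param part,whole Nonnegative counts; `whole` must be positive.
#' @return `100 * part / whole` rounded half-up to one decimal place (the
#'   convention used when percentages are reported alongside raw counts).
#' @examples
#' percent_of(396, 936) # 42.3
#' @export
percent_of <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be positive")
  x <- 100 * part / whole
  floor(x * 10 + 0.5) / 10
}

#' Summary statistics of rumor-group sizes
#'
#' Statistics over the multiset of group sizes at or above `min_size`;
#' quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param labeling Label vector.
#' @param min_size Only groups with at least this many messages enter the
#'   statistics.
#' @return One-row tibble: `min_size`, `n_groups`, `mean`, `sd`, `max`,
#'   `q1`, `median`, `q3`, `total` (sum of qualifying sizes). When no group
#'   qualifies, `n_groups` is 0 and the statistics are `NA`.
#' @export
group_size_stats <- function(labeling, min_size = 1) {
  sizes <- as.integer(table(as.integer(labeling)))
  sizes <- sizes[sizes >= min_size]
  if (length(sizes) == 0) {
    return(tibble::tibble(min_size = min_size, n_groups = 0L, mean = NA_real_,
                          sd = NA_real_, max = NA_integer_, q1 = NA_real_,
                          median = NA_real_, q3 = NA_real_, total = 0L))
  }
  q <- stats::quantile(sizes, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(min_size = min_size, n_groups = length(sizes),
                 mean = mean(sizes), sd = stats::sd(sizes),
                 max = max(sizes), q1 = q[1], median = q[2], q3 = q[3],
                 total = sum(sizes))
}
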