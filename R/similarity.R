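#' Token-set overlap distance between two documents
#'
#' The distance between messages A and B is
#' \deqn{d(A, B) = 1 - \frac{|tok(A) \cap tok(B)|}{\max(|tok(A)|, |tok(B)|)}}
#' where `tok()` is the set of distinct tokens of a message. Normalizing by
#' the larger set makes a short message that is wholly contained in a much
#' longer one still distant from it: the overlap must constitute the majority
#' of *both* messages for the pair to be close, which keeps combined rumors
#' (concatenations of two narratives) away from their parts. The distance is
#' 0 iff the sets are equal and 1 iff they are disjoint.
#'
#' @param a,b Character vectors of tokens (treated as sets), or single rows of
#'   a [preprocess()] tibble (lists with a `token_set` element).
#' @param normalizer Denominator choice; `"max"` is the package definition.
#'   `"min"` and `"union"` (plain Jaccard) are available for sensitivity
#'   analysis.
#' @return A distance in `[0, 1]`.
#' @examples
#' token_set_distance(c("a", "b", "c", "d"), letters[1:8]) # 0.5
#' @export
token_set_distance <- function(a, b, normalizer = c("max", "min", "union")) {
  normalizer <- match.arg(normalizer)
  a <- as_token_set(a)
  b <- as_token_set(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("token_set_distance requires non-empty token sets")
  }
  ov <- length(intersect(a, b))
  den <- switch(normalizer,
    max = max(length(a), length(b)),
    min = min(length(a), length(b)),
    union = length(a) + length(b) - ov
  )
  1 - ov / den
}

as_token_set <- function(x) {
  if (is.list(x) && !is.null(x$token_set)) {
    ts <- x$token_set
    if (is.list(ts)) ts <- ts[[1]]
    return(unique(as.character(ts)))
  }
  unique(as.character(x))
}

#' Build a sparse binary document-term matrix
#'
#' Rows are documents, columns distinct tokens, entries 1 where the token
#' occurs (the binary word vector of each message).
#'
#' @param docs Tokenized-document tibble from [preprocess()].
#' @return A `dgCMatrix` with `rownames` the message ids.
#' @export
doc_term_matrix <- function(docs) {
  sets <- docs$token_set
  vocab <- unique(unlist(sets, use.names = FALSE))
  n <- length(sets)
  X <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(sets)),
    j = match(unlist(sets, use.names = FALSE), vocab),
    x = 1,
    dims = c(n, length(vocab))
  )
  rownames(X) <- docs$message_id
  X
}

#' Pairwise distance matrix under the token-set distance
#'
#' Computes all pairwise distances via sparse binary intersection counts
#' (a cross-product of the document-term matrix), which agrees elementwise
#' with [token_set_distance()] but scales to tens of thousands of documents.
#'
#' @inheritParams token_set_distance
#' @param docs Tokenized-document tibble from [preprocess()]; all token sets
#'   must be non-empty.
#' @return A dense symmetric `n x n` matrix of class `rumor_dist` with zero
#'   diagonal, entries in `[0, 1]`, and `dimnames` the message ids.
#' @export
distance_matrix <- function(docs, normalizer = c("max", "min", "union")) {
  normalizer <- match.arg(normalizer)
  n <- nrow(docs)
  if (n == 0) {
    return(structure(matrix(numeric(0), 0, 0), class = c("rumor_dist", "matrix")))
  }
  if (any(lengths(docs$token_set) == 0)) {
    stop("distance_matrix requires non-empty token sets")
  }
  X <- doc_term_matrix(docs)
  sizes <- Matrix::rowSums(X)
  D <- as.matrix(Matrix::tcrossprod(X))
  # columnwise to avoid materializing an n x n denominator matrix
  for (j in seq_len(n)) {
    den <- switch(normalizer,
      max = pmax(sizes, sizes[j]),
      min = pmin(sizes, sizes[j]),
      union = sizes + sizes[j] - D[, j]
    )
    D[, j] <- 1 - D[, j] / den
  }
  dimnames(D) <- list(docs$message_id, docs$message_id)
  class(D) <- c("rumor_dist", "matrix")
  D
}

#' Cross distances between two document sets
#'
#' Distance from every document in `query` to every document in `ref`,
#' under the same token-set distance; used by the KNN stage.
#'
#' @inheritParams token_set_distance
#' @param query,ref Tokenized-document tibbles.
#' @return A `nrow(query) x nrow(ref)` matrix.
#' @export
cross_distance_matrix <- function(query, ref,
                                  normalizer = c("max", "min", "union")) {
  normalizer <- match.arg(normalizer)
  sets_q <- query$token_set
  sets_r <- ref$token_set
  vocab <- unique(c(unlist(sets_q, use.names = FALSE),
                    unlist(sets_r, use.names = FALSE)))
  mk <- function(sets) Matrix::sparseMatrix(
    i = rep.int(seq_along(sets), lengths(sets)),
    j = match(unlist(sets, use.names = FALSE), vocab),
    x = 1, dims = c(length(sets), length(vocab)))
  Xq <- mk(sets_q)
  Xr <- mk(sets_r)
  sq <- Matrix::rowSums(Xq)
  sr <- Matrix::rowSums(Xr)
  D <- as.matrix(Matrix::tcrossprod(Xq, Xr))
  for (j in seq_len(ncol(D))) {
    den <- switch(normalizer,
      max = pmax(sq, sr[j]),
      min = pmin(sq, sr[j]),
      union = sq + sr[j] - D[, j]
    )
    D[, j] <- 1 - D[, j] / den
  }
  dimnames(D) <- list(query$message_id, ref$message_id)
  D
}

#' @export
print.rumor_dist <- function(x, ...) {
  cat("Token-set distance matrix:", nrow(x), "documents\n")
  if (nrow(x) > 0) {
    off <- x[upper.tri(x)]
    if (length(off)) {
      cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f\n",
                  min(off), max(off), mean(off)))
    }
  }
  invisible(x)
}

#' Dump a distance matrix as dense CSV (debugging aid)
#'
#' @param D `rumor_dist` matrix.
#' @param path Output path; header row/column carry the message ids.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(D, path) {
  write.csv(as.data.frame(unclass(D)), path, row.names = TRUE)
  invisible(path)
}
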