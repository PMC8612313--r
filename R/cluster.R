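#' Threshold-stopped hierarchical agglomerative clustering
#'
#' Bottom-up merging on a precomputed distance matrix; merging stops once the
#' linkage distance between every pair of remaining clusters exceeds
#' `lambda`, so the number of groups is data-driven rather than prespecified.
#' Built on [stats::hclust()] with the tree cut at height `lambda`.
#'
#' @param D Symmetric distance matrix ([distance_matrix()] output, or any
#'   square matrix / `dist`).
#' @param lambda Distance threshold in `(0, 1]`; default 0.6.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An integer vector of group labels (1-based, consecutive), named by
#'   the matrix dimnames; documents in the same cluster share a label.
#' @examples
#' D <- matrix(c(0, .1, 1, .1, 0, 1, 1, 1, 0), 3, 3)
#' hac_cluster(D, lambda = 0.6)
#' @export
hac_cluster <- function(D, lambda = 0.6,
                        linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(lambda > 0, lambda <= 1)
  if (inherits(D, "dist")) {
    dd <- D
    n <- attr(D, "Size")
    ids <- attr(D, "Labels")
  } else {
    n <- nrow(D)
    ids <- rownames(D)
    dd <- stats::as.dist(D)
  }
  if (n == 0) return(integer(0))
  if (n == 1) return(stats::setNames(1L, ids))
  hc <- stats::hclust(dd, method = linkage)
  # average/complete linkage heights are monotone in exact arithmetic; undo
  # sub-1e-8 floating-point jitter so cutree accepts the tree
  dh <- diff(hc$height)
  if (any(dh < 0)) {
    if (min(dh) < -1e-8) stop("non-monotone merge heights beyond tolerance")
    hc$height <- cummax(hc$height)
  }
  labels <- stats::cutree(hc, h = lambda)
  stats::setNames(as.integer(labels), ids)
}

# majority vote over the k nearest training columns of a cross-distance
# matrix; ties in distance resolved by training order (stable), ties in the
# vote toward the smallest label id (the -1 sentinel counts as smallest)
knn_predict <- function(C, train_labels, k = 5) {
  k <- min(k, ncol(C))
  stopifnot(k >= 1)
  apply_rows <- function(i) {
    nn <- order(C[i, ])[seq_len(k)]
    votes <- train_labels[nn]
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)
  }
  vapply(seq_len(nrow(C)), apply_rows, integer(1))
}

#' Classification-based clustering (HAC + KNN)
#'
#' The full-corpus HAC is quadratic in memory and slow on large corpora, so
#' this routine clusters exactly only a random sample: (1) draw
#' `floor(u * n)` documents uniformly without replacement; (2-3) build their
#' distance matrix and run threshold HAC at `lambda`; (4) relabel sample
#' singletons with the sentinel -1; (5) train a k-nearest-neighbour
#' classifier on the sample (using the same token-set distance) and predict
#' the held-out documents, so a holdout document nearest to sample singletons
#' can itself be predicted -1; (6) combine; (7-8) collect every document
#' labeled -1 and re-run threshold HAC on that subset, with fresh labels
#' offset past all first-pass labels; (9) merge. Documents still alone after
#' the second pass keep their own fresh label (a group of size one). With
#' `u = 1` the procedure reduces exactly to [hac_cluster()] on the full
#' corpus.
#'
#' @param docs Tokenized-document tibble from [preprocess()].
#' @param lambda Distance threshold in `(0, 1]`; default 0.6.
#' @param u Train portion in `(0, 1]`: fraction of the corpus clustered
#'   exactly by HAC before KNN extrapolation.
#' @param k Number of neighbours for the KNN vote; default 5.
#' @param linkage Linkage criterion, as in [hac_cluster()].
#' @param seed Integer seed controlling the sample draw (the only source of
#'   randomness); identical inputs and seed give identical labelings.
#' @param normalizer Distance normalizer, as in [token_set_distance()].
#' @param dmat Optional precomputed full distance matrix (rows/cols in `docs`
#'   order); when supplied, sample/cross/leftover distances are taken from it
#'   instead of being recomputed, which is the economical choice when the
#'   same corpus is also clustered in full.
#' @return An integer label vector named by message id, with attributes
#'   `pass` (1 or 2 per document: which pass fixed its final label) and
#'   `params`; class `rumor_labeling`.
#' @export
hybrid_cluster <- function(docs, lambda = 0.6, u = 0.6, k = 5,
                           linkage = c("average", "complete", "single"),
                           seed = 1L,
                           normalizer = c("max", "min", "union"),
                           dmat = NULL) {
  linkage <- match.arg(linkage)
  normalizer <- match.arg(normalizer)
  stopifnot(u > 0, u <= 1, k >= 1)
  n <- nrow(docs)
  ids <- docs$message_id
  if (n == 0) {
    return(structure(integer(0), pass = integer(0), class = "rumor_labeling"))
  }
  n_u <- floor(u * n)
  if (n_u < 2) stop("train portion too small: u * n must be at least 2")
  # sorted: the draw decides membership only, keeping corpus order inside the
  # sample so u = 1 reproduces full HAC exactly even under tied distances
  idx_u <- sort(withr::with_seed(seed, sample.int(n, n_u)))
  idx_v <- setdiff(seq_len(n), idx_u)

  D_u <- if (is.null(dmat)) distance_matrix(docs[idx_u, ], normalizer)
         else dmat[idx_u, idx_u, drop = FALSE]
  L_u <- as.integer(hac_cluster(D_u, lambda, linkage))
  # sample singletons become the -1 sentinel
  sizes_u <- tabulate(L_u)
  L_u[sizes_u[L_u] == 1L] <- -1L

  labels <- integer(n)
  pass <- rep(1L, n)
  labels[idx_u] <- L_u
  if (length(idx_v) > 0) {
    if (all(L_u == -1L)) {
      # degenerate sample: no non-singleton cluster to learn from; everything
      # goes to the second HAC pass
      labels[idx_v] <- -1L
    } else {
      C <- if (is.null(dmat))
        cross_distance_matrix(docs[idx_v, ], docs[idx_u, ], normalizer)
      else dmat[idx_v, idx_u, drop = FALSE]
      labels[idx_v] <- knn_predict(C, L_u, k = k)
    }
  }

  idx_o <- which(labels == -1L)
  if (length(idx_o) > 0) {
    offset <- max(c(labels[labels >= 0L], 0L))
    if (length(idx_o) == 1L) {
      L_o <- 1L
    } else {
      D_o <- if (is.null(dmat)) distance_matrix(docs[idx_o, ], normalizer)
             else dmat[idx_o, idx_o, drop = FALSE]
      L_o <- as.integer(hac_cluster(D_o, lambda, linkage))
    }
    labels[idx_o] <- L_o + offset
    pass[idx_o] <- 2L
  }

  structure(stats::setNames(labels, ids), pass = pass,
            params = list(lambda = lambda, u = u, k = k, linkage = linkage,
                          seed = seed, normalizer = normalizer),
            class = "rumor_labeling")
}

#' @export
print.rumor_labeling <- function(x, ...) {
  sizes <- table(as.integer(x))
  cat("Rumor labeling:", length(x), "documents in", length(sizes), "groups\n")
  cat("  largest group:", if (length(sizes)) max(sizes) else 0,
      " singletons:", sum(sizes == 1), "\n")
  p <- attr(x, "pass")
  if (!is.null(p)) cat("  second-pass documents:", sum(p == 2L), "\n")
  invisible(x)
}

#' Summarize a labeling as a per-group table
#'
#' @param labeling Label vector ([hac_cluster()] / [hybrid_cluster()] output).
#' @param docs Tokenized-document tibble aligned with `labeling` (used for
#'   the exemplar: the longest member by token count).
#' @return Tibble with `group_id`, `size`, `member_ids` (list-column),
#'   `exemplar_id`; sorted by size descending, ties by smallest member id.
#' @export
group_table <- function(labeling, docs = NULL) {
  labels <- as.integer(labeling)
  ids <- names(labeling)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  if (length(labels) == 0) {
    return(tibble::tibble(group_id = integer(), size = integer(),
                          member_ids = list(), exemplar_id = character()))
  }
  by_group <- split(seq_along(labels), labels)
  gid <- as.integer(names(by_group))
  size <- lengths(by_group)
  member_ids <- unname(lapply(by_group, function(ix) ids[ix]))
  exemplar <- unname(vapply(by_group, function(ix) {
    if (!is.null(docs) && "n_tokens" %in% names(docs)) {
      ids[ix[which.max(docs$n_tokens[ix])]]
    } else {
      ids[ix[1]]
    }
  }, character(1)))
  min_id <- vapply(member_ids, min, character(1))
  ord <- order(-size, min_id)
  tibble::tibble(group_id = gid[ord], size = as.integer(size[ord]),
                 member_ids = member_ids[ord], exemplar_id = exemplar[ord])
}

#' Write cluster assignments to CSV
#'
#' Columns: `message_id`, `group_id`, `pass` (which pass of the hybrid
#' algorithm fixed the label; 1 for plain HAC labelings).
#'
#' @param labeling Label vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(labeling, path) {
  pass <- attr(labeling, "pass")
  if (is.null(pass)) pass <- rep(1L, length(labeling))
  write.csv(data.frame(message_id = names(labeling),
                       group_id = as.integer(labeling),
                       pass = pass),
            path, row.names = FALSE)
  invisible(path)
}

#' Read cluster assignments written by [write_assignments()]
#'
#' @param path Assignments CSV path.
#' @return A named integer label vector with a `pass` attribute.
#' @export
read_assignments <- function(path) {
  df <- read.csv(path, colClasses = c(message_id = "character"))
  structure(stats::setNames(as.integer(df$group_id), df$message_id),
            pass = as.integer(df$pass), class = "rumor_labeling")
}

# canonical form of a partition: labels renumbered by first appearance
canonical_partition <- function(labels) {
  labels <- as.integer(labels)
  match(labels, unique(labels))
}

#' Do two labelings induce the same partition?
#'
#' Group ids carry no meaning, so equality is up to relabeling.
#'
#' @param a,b Label vectors over the same documents in the same order.
#' @return `TRUE` or `FALSE`.
#' @export
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(canonical_partition(a), canonical_partition(b))
}
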