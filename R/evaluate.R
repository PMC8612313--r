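#' Pairwise precision, recall and F score of a clustering
#'
#' Clusterings are compared over unordered document pairs: a pair is a true
#' positive when both labelings put it in the same group. Precision is
#' TP / (pairs co-clustered in the prediction), recall is TP / (pairs
#' co-clustered in the gold standard), and F their harmonic mean. Recall thus
#' measures how completely gold groups are kept together and precision how
#' many foreign documents the predicted groups absorbed. Conventions: with no
#' predicted co-pair, precision is 1 if the gold has none either, else 0
#' (and symmetrically for recall); F is 0 when precision + recall is 0.
#'
#' @param pred,gold Label vectors over the same documents in the same order
#'   (names, when present on both, must agree).
#' @return A one-row tibble with `precision`, `recall`, `f_score`.
#' @examples
#' pairwise_prf(c(1, 1, 1), c(1, 1, 2)) # precision 1/3, recall 1, F 0.5
#' @export
pairwise_prf <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    stop("pred and gold must label the same documents")
  }
  if (!is.null(names(pred)) && !is.null(names(gold)) &&
      !identical(names(pred), names(gold))) {
    stop("pred and gold document ids differ")
  }
  tab <- table(as.integer(pred), as.integer(gold))
  pairs <- function(m) sum(choose(m, 2))
  tp <- pairs(tab)
  pred_pairs <- pairs(rowSums(tab))
  gold_pairs <- pairs(colSums(tab))
  precision <- if (pred_pairs == 0) as.numeric(gold_pairs == 0) else tp / pred_pairs
  recall <- if (gold_pairs == 0) as.numeric(pred_pairs == 0) else tp / gold_pairs
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f_score = f)
}

#' Fidelity of the hybrid clustering against full HAC
#'
#' Runs [hybrid_cluster()] repeatedly at each train portion `u`, scores every
#' run against [hac_cluster()] on the full corpus (the gold standard), and
#' reports the mean and a normal-approximation 95% interval of pairwise
#' precision, recall and F per `u`. Repetition seeds are derived
#' deterministically from `seed`, so the table is reproducible bit for bit.
#'
#' @param docs Tokenized-document tibble.
#' @param u_grid Numeric vector of train portions to evaluate.
#' @param n_reps Repetitions per `u` (>= 2).
#' @param seed Master seed.
#' @param lambda,k,linkage,normalizer Passed to the clustering routines.
#' @param dmat Optional precomputed full distance matrix; computed once here
#'   otherwise and shared by the gold run and all repetitions.
#' @return A tibble with one row per (`u`, metric-summary): columns `u`,
#'   `precision`, `recall`, `f_score` and their `*_lo` / `*_hi` 95% bounds,
#'   plus `n_reps`.
#' @export
fidelity_benchmark <- function(docs, u_grid = c(0.2, 0.4, 0.6, 0.8),
                               n_reps = 5, seed = 1L, lambda = 0.6, k = 5,
                               linkage = "average", normalizer = "max",
                               dmat = NULL) {
  stopifnot(n_reps >= 2)
  if (is.null(dmat)) dmat <- distance_matrix(docs, normalizer)
  gold <- hac_cluster(dmat, lambda, linkage)
  rep_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(u_grid) * n_reps))
  rows <- list()
  for (ui in seq_along(u_grid)) {
    u <- u_grid[ui]
    scores <- lapply(seq_len(n_reps), function(r) {
      s <- rep_seeds[(ui - 1L) * n_reps + r]
      pred <- hybrid_cluster(docs, lambda = lambda, u = u, k = k,
                             linkage = linkage, seed = s,
                             normalizer = normalizer, dmat = dmat)
      pairwise_prf(pred, gold)
    })
    scores <- do.call(rbind, scores)
    summ <- function(x) {
      m <- mean(x)
      half <- 1.96 * stats::sd(x) / sqrt(length(x))
      c(mean = unname(m), lo = unname(m - half), hi = unname(m + half))
    }
    p <- summ(scores$precision); r <- summ(scores$recall); f <- summ(scores$f_score)
    rows[[ui]] <- tibble::tibble(
      u = u, n_reps = n_reps,
      precision = unname(p["mean"]), precision_lo = unname(p["lo"]),
      precision_hi = unname(p["hi"]),
      recall = unname(r["mean"]), recall_lo = unname(r["lo"]),
      recall_hi = unname(r["hi"]),
      f_score = unname(f["mean"]), f_score_lo = unname(f["lo"]),
      f_score_hi = unname(f["hi"])
    )
  }
  do.call(rbind, rows)
}

#' Wall-clock comparison of full HAC vs the hybrid algorithm
#'
#' Hardware-dependent, so informational only: reports elapsed seconds per
#' configuration on the machine at hand.
#'
#' @inheritParams fidelity_benchmark
#' @return Tibble with `method`, `u`, `elapsed_s`.
#' @export
runtime_benchmark <- function(docs, u_grid = c(0.2, 0.4, 0.6, 0.8),
                              seed = 1L, lambda = 0.6, k = 5,
                              linkage = "average") {
  time_of <- function(expr) unname(system.time(expr)["elapsed"])
  rows <- list(tibble::tibble(
    method = "hac", u = NA_real_,
    elapsed_s = time_of(hac_cluster(distance_matrix(docs), lambda, linkage))))
  for (u in u_grid) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = "hac_knn", u = u,
      elapsed_s = time_of(hybrid_cluster(docs, lambda = lambda, u = u, k = k,
                                         linkage = linkage, seed = seed)))
  }
  do.call(rbind, rows)
}
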