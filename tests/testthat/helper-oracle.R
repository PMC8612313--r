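# Independent oracles, deliberately naive.

# Quadratic-memory agglomeration: recompute every inter-cluster linkage from
# the raw distance matrix at each step, merge the closest pair while its
# linkage distance does not exceed lambda.
oracle_hac <- function(D, lambda = 0.6, linkage = "average") {
  n <- nrow(D)
  if (n == 0) return(integer(0))
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        vals <- D[clusters[[i]], clusters[[j]]]
        d <- switch(linkage,
                    average = mean(vals),
                    complete = max(vals),
                    single = min(vals))
        if (d < bestd - 1e-12) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    if (bestd > lambda) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

# Pairwise precision/recall by explicit enumeration of all unordered pairs.
oracle_prf <- function(pred, gold) {
  n <- length(pred)
  tp <- fp <- fn <- 0
  co_pred <- co_gold <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p_same <- pred[i] == pred[j]
        g_same <- gold[i] == gold[j]
        co_pred <- co_pred + p_same
        co_gold <- co_gold + g_same
        tp <- tp + (p_same && g_same)
      }
    }
  }
  precision <- if (co_pred == 0) as.numeric(co_gold == 0) else tp / co_pred
  recall <- if (co_gold == 0) as.numeric(co_pred == 0) else tp / co_gold
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f_score = f)
}

# Naive elementwise distance matrix from two-set arithmetic.
oracle_distance_matrix <- function(docs, normalizer = "max") {
  n <- nrow(docs)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- token_set_distance(docs$token_set[[i]],
                                                 docs$token_set[[j]],
                                                 normalizer)
      }
    }
  }
  dimnames(D) <- list(docs$message_id, docs$message_id)
  D
}
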