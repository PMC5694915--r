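# Brute-force oracles, independent of the package's fast training path.
# Votes, weight decompositions and candidate enumeration are computed with
# plain loops; the trainer oracle enumerates the full cartesian product of
# per-bin (threshold, direction) choices for every feature.

oracle_bin <- function(age, edges) {
  i <- findInterval(age, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

oracle_vote1 <- function(x, threshold, direction) {
  if (is.na(x)) return(0)
  if (direction == "high_is_unstable") {
    if (x > threshold) 1 else -1
  } else {
    if (x < threshold) 1 else -1
  }
}

# midpoints of consecutive distinct values (cap never binds in fixtures)
oracle_thresholds <- function(x) {
  u <- sort(unique(x[!is.na(x)]))
  if (length(u) < 2) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

# per-bin candidate (threshold, direction) options with nearest-bin
# inheritance, ordered (threshold asc, high before low)
oracle_bin_options <- function(x, bins, nb) {
  thr <- lapply(seq_len(nb), function(b) oracle_thresholds(x[bins == b]))
  pop <- which(vapply(thr, length, integer(1)) > 0)
  if (!length(pop)) return(NULL)
  for (b in seq_len(nb)) if (!length(thr[[b]]))
    thr[[b]] <- thr[[pop[which.min(abs(pop - b))]]]
  lapply(thr, function(tt) {
    opts <- expand.grid(threshold = tt,
                        direction = c("high_is_unstable", "low_is_unstable"),
                        stringsAsFactors = FALSE)
    opts[order(opts$threshold, opts$direction != "high_is_unstable"), ,
         drop = FALSE]
  })
}

oracle_score <- function(x, bins, y, w, thresholds, directions) {
  Wp <- Wm <- W0 <- 0
  for (i in seq_along(y)) {
    v <- oracle_vote1(x[i], thresholds[bins[i]], directions[bins[i]])
    if (v == 0) W0 <- W0 + w[i]
    else if (v == y[i]) Wp <- Wp + w[i]
    else Wm <- Wm + w[i]
  }
  list(W_plus = Wp, W_minus = Wm, W_zero = W0, Z = W0 + 2 * sqrt(Wp * Wm))
}

# exhaustive min-Z stump over all features and all per-bin combinations.
# Within a feature, min-Z ties (which include the direction-mirrored stump,
# whose Z is identical) resolve to the larger correctly-voted weight — the
# majority-voting convention — and then to the earliest combination in the
# per-bin (threshold asc, high-first) lexicographic enumeration. Across
# features, Z ties keep the lowest feature index.
oracle_best_stump <- function(X, age, y, w, edges) {
  nb <- length(edges) - 1L
  bins <- oracle_bin(age, edges)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    opts <- oracle_bin_options(X[, j], bins, nb)
    if (is.null(opts)) next
    idx_grid <- expand.grid(rev(lapply(opts, function(o) seq_len(nrow(o)))))
    idx_grid <- idx_grid[, rev(seq_len(ncol(idx_grid))), drop = FALSE]
    fbest <- NULL
    for (r in seq_len(nrow(idx_grid))) {
      thr <- dir <- vector("list", nb)
      for (b in seq_len(nb)) {
        o <- opts[[b]][idx_grid[r, b], ]
        thr[[b]] <- o$threshold; dir[[b]] <- o$direction
      }
      thr <- unlist(thr); dir <- unlist(dir)
      sc <- oracle_score(X[, j], bins, y, w, thr, dir)
      if (is.null(fbest) || sc$Z < fbest$Z - 1e-12 ||
          (abs(sc$Z - fbest$Z) <= 1e-12 &&
           sc$W_plus > fbest$W_plus + 1e-12)) {
        fbest <- list(j = j, threshold = thr, direction = dir,
                      Z = sc$Z, W_plus = sc$W_plus, W_minus = sc$W_minus)
      }
    }
    if (!is.null(fbest) && (is.null(best) || fbest$Z < best$Z - 1e-12))
      best <- fbest
  }
  best
}

# full boosting oracle: T rounds of exhaustive search + reweighting
oracle_train <- function(X, age, y, n_rounds, edges = c(1 / 12, 20),
                         epsilon = NULL) {
  n <- length(y)
  if (is.null(epsilon)) epsilon <- 1 / (2 * n)
  w <- rep(1 / n, n)
  bins <- oracle_bin(age, edges)
  stumps <- list()
  for (t in seq_len(n_rounds)) {
    best <- oracle_best_stump(X, age, y, w, edges)
    if (is.null(best) || best$Z >= 1 - 1e-6) break
    alpha <- 0.5 * log((best$W_plus + epsilon) / (best$W_minus + epsilon))
    v <- vapply(seq_len(n), function(i)
      oracle_vote1(X[i, best$j], best$threshold[bins[i]],
                   best$direction[bins[i]]), numeric(1))
    w <- w * exp(-alpha * y * v)
    w <- w / sum(w)
    stopifnot(abs(sum(w) - 1) < 1e-12)
    stumps[[t]] <- list(feature = colnames(X)[best$j],
                        threshold = best$threshold,
                        direction = best$direction, alpha = alpha)
  }
  stumps
}

# all-pairs AUROC oracle
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
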