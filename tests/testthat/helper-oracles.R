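# Independent brute-force oracles used to cross-check the implementation.

# Pearson correlation by explicit double loop over column pairs.
pearson_bruteforce <- function(X) {
  p <- ncol(X)
  n <- nrow(X)
  r <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- X[, i] - sum(X[, i]) / n
      xj <- X[, j] - sum(X[, j]) / n
      r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  r
}

# Manhattan distance between two points, by explicit sum.
manhattan_pt <- function(a, b) sum(abs(a - b))

# O(n^3) complete-linkage agglomeration: returns the sequence of merge
# heights. Cluster distance = max pairwise point distance.
complete_linkage_bruteforce <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- max(outer(clusters[[a]], clusters[[b]],
                       Vectorize(function(i, j) manhattan_pt(X[i, ], X[j, ]))))
        if (d < best_d) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Goodness-of-fit metrics re-derived with explicit sums.
gof_bruteforce <- function(obs, pred, n_params) {
  N <- length(obs)
  e <- obs - pred
  m <- function(r) sum((e - sum(e) / N)^r) / N
  list(chi_sq = sum(e^2) / (N - n_params),
       RMSE = sqrt(sum(e^2) / N),
       MBE = sum(e) / N,
       MPE = 100 / N * sum(abs(e) / pred),
       SSE = sum(e^2),
       AARD = 100 / N * sum(abs(e / pred)),
       r2 = 1 - sum(e^2) / sum((obs - sum(obs) / N)^2),
       skewness = m(3) / m(2)^1.5,
       kurtosis = m(4) / m(2)^2 - 3)
}

# Fixture copy with one cell edited, for loader-validation tests.
corrupt_table1 <- function(row, col, value) {
  path <- tempfile(fileext = ".csv")
  d <- read.csv(system.file("extdata", "table1.csv", package = "osmodry"),
                colClasses = "character", check.names = FALSE)
  d[[col]][row] <- value
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}
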