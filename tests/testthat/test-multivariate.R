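test_that("pearson_matrix equals a brute-force oracle and cor.test", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rnorm(20), nrow = 5, ncol = 4,
                dimnames = list(NULL, letters[1:4]))
    tab <- data.frame(run = 1:5, X)
    res <- pearson_matrix(tab, columns = letters[1:4])
    expect_equal(unname(res$r), pearson_bruteforce(X), tolerance = 1e-12)
    ct <- cor.test(X[, 1], X[, 2])
    expect_equal(res$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p["a", "b"], ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation degenerate and identity cases behave", {
  tab <- data.frame(run = 1:3, x = c(1, 2, 3), y = c(6, 4, 2))
  res <- pearson_matrix(tab, columns = c("x", "y"))
  expect_equal(res$r["x", "x"], 1)
  expect_equal(res$r["x", "y"], -1)
  expect_equal(res$p["x", "y"], 0)
  tab$z <- 5
  expect_warning(res2 <- pearson_matrix(tab, columns = c("x", "y", "z")),
                 "constant")
  expect_true(is.na(res2$r["x", "z"]))
  expect_error(pearson_matrix(tab[1:2, ], columns = c("x", "y")), "at least 3")
  expect_error(pearson_matrix(tab, columns = "nope"), "unknown column")
})

test_that("complete-linkage city-block clustering matches hand agglomeration", {
  # 1-D points at 0, 1, 10: first merge at height 1, final at height 10
  tab <- data.frame(run = 1:3, x = c(0, 1, 10))
  cl <- cluster_runs(tab, columns = "x", k = 2)
  expect_equal(cl$heights, c(1, 10))
  expect_equal(unname(cl$labels), c(1, 1, 2))
  # identical runs merge at height zero
  tab2 <- data.frame(run = 1:3, x = c(2, 2, 7), y = c(1, 1, 3))
  cl2 <- cluster_runs(tab2, columns = c("x", "y"), k = 2)
  expect_equal(min(cl2$heights), 0)
  expect_equal(cl2$labels[[1]], cl2$labels[[2]])
  expect_error(cluster_runs(tab, columns = "x", k = 5), "exceeds")
})

test_that("clustering heights equal a brute-force O(n^3) oracle", {
  set.seed(31)
  for (rep in 1:3) {
    X <- matrix(rnorm(8 * 3), nrow = 8)
    tab <- data.frame(run = 1:8, X)
    cl <- cluster_runs(tab, columns = names(tab)[-1], k = 2)
    expect_equal(cl$heights, complete_linkage_bruteforce(X), tolerance = 1e-12)
    # complete linkage is monotone
    expect_true(all(diff(cl$heights) >= 0))
  }
})

test_that("flat cluster labels partition all runs", {
  d <- load_design_table("table1")
  cl <- cluster_runs(d, k = 4)
  expect_equal(sort(unname(unlist(cl$members))), d$run)
  expect_equal(length(cl$members), 4L)
  expect_true(all(diff(cl$heights) >= 0))
})

test_that("correlation-matrix PCA satisfies its spectral identities", {
  d <- load_design_table("table1")
  p <- pca_correlation(d)
  R <- cor(as.matrix(as.data.frame(d)[, od_response_names()]))
  # reconstruction: V Lambda V' = R
  expect_equal(p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings), R,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  expect_equal(sum(p$eigenvalues), 13, tolerance = 1e-9)
  expect_equal(unname(colSums(p$contributions)), rep(100, 13),
               tolerance = 1e-9)
  # sign convention: the largest-|loading| variable is positive
  for (j in 1:13) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("PCA degenerate cases: perfect correlation and constant columns", {
  tab <- data.frame(run = 1:4, x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  p <- pca_correlation(tab, columns = c("x", "y"))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p$percent_variance[1], 100, tolerance = 1e-12)
  tab$z <- 1
  expect_error(pca_correlation(tab, columns = c("x", "y", "z")),
               "constant column.*z")
})
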