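test_that("min-max normalization and its inverse are exact", {
  X <- matrix(c(20, 40, 60), ncol = 1, dimnames = list(NULL, "T"))
  b <- minmax_bounds(X)
  expect_equal(unname(minmax_normalize(X, b)), matrix(c(0, 0.5, 1)))
  set.seed(41)
  Y <- matrix(runif(30, -5, 5), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  bb <- minmax_bounds(Y)
  expect_equal(minmax_denormalize(minmax_normalize(Y, bb), bb), Y,
               tolerance = 1e-12)
  expect_warning(out <- minmax_normalize(matrix(70, ncol = 1), b), "outside")
  expect_gt(out[1], 1)
  expect_error(minmax_bounds(matrix(c(1, 1), ncol = 1,
                                    dimnames = list(NULL, "k"))),
               "degenerate.*k")
})

test_that("forward pass reproduces hand-computed layer compositions", {
  m <- mlp_model(W1 = matrix(c(1, 0, 0), nrow = 1), B1 = 0, W2 = 2, B2 = 1,
                 f_hidden = "identity", f_output = "identity")
  expect_equal(mlp_forward(m, c(0.5, 0.3, 0.9)), 2.0)
  m2 <- mlp_model(W1 = matrix(0, 2, 3), B1 = c(0, 0), W2 = c(0, 0), B2 = 0,
                  f_hidden = "identity", f_output = "logistic")
  expect_equal(mlp_forward(m2, c(1, 2, 3)), 0.5)
  m3 <- mlp_model(W1 = matrix(rnorm(6), 2, 3), B1 = c(0, 0), W2 = c(1, 1),
                  B2 = 0.7, f_hidden = "tanh", f_output = "identity")
  expect_equal(mlp_forward(m3, c(0, 0, 0)), 0.7)  # tanh(0) = 0
  expect_error(mlp_forward(m, c(1, 2)), "dimension mismatch")
})

test_that("split sizes follow the round-train, round-test, remainder rule", {
  expect_equal(unname(osmodry:::split_sizes(15, c(0.6, 0.2, 0.2))), c(9, 3, 3))
  expect_equal(unname(osmodry:::split_sizes(15, c(0.8, 0.1, 0.1))), c(12, 2, 1))
})

test_that("identity-activation H=1 training matches closed-form least squares", {
  specs <- list(surface_spec("y", beta0 = 10, linear = c(3, -2, 5), noise_sd = 0))
  tab <- simulate_responses(bbd_design(), specs, seed = 5)
  cfg <- train_config(hidden = 1L, restarts = 5L, maxit = 500L, seed = 17,
                      f_hidden = "identity", f_output = "identity")
  fit <- train_response(tab, "y", cfg)
  X <- as.matrix(as.data.frame(tab)[, c("T", "Conc", "t")])
  pred <- mlp_forward(fit$model, X)
  tr <- fit$split$train
  ols <- lm(y ~ T + Conc + t, data = as.data.frame(tab)[tr, ])
  ols_pred <- predict(ols, newdata = as.data.frame(tab))
  expect_equal(unname(pred[tr]), unname(ols_pred[tr]), tolerance = 1e-6)
  expect_gte(fit$r2[["train"]], 0.999)
  # linear surface, identity net: near-zero error on every run
  expect_lt(sqrt(mean((pred - tab$y)^2)), 1e-3)
})

test_that("training is invariant to affine rescaling of the inputs", {
  specs <- list(surface_spec("y", beta0 = 5, linear = c(2, 1, 3),
                             quadratic = c(0, 0, -1), noise_sd = 0.2))
  tab <- simulate_responses(bbd_design(), specs, seed = 9)
  cfg <- train_config(hidden = 3L, restarts = 5L, seed = 23)
  fit1 <- train_response(tab, "y", cfg)
  tab2 <- as.data.frame(tab)
  tab2$T <- tab2$T * 9 / 5 + 32     # different units, same information
  tab2$t <- tab2$t * 60
  fit2 <- train_response(tab2, "y", cfg)
  X1 <- as.matrix(as.data.frame(tab)[, c("T", "Conc", "t")])
  X2 <- as.matrix(tab2[, c("T", "Conc", "t")])
  expect_equal(mlp_forward(fit2$model, X2), mlp_forward(fit1$model, X1),
               tolerance = 1e-8)
})

test_that("a strong quadratic surface needs more than one hidden neuron", {
  specs <- list(surface_spec("y", beta0 = 2, linear = c(0.5, 0, 0),
                             quadratic = c(8, 0, 0), noise_sd = 0))
  tab <- simulate_responses(bbd_design(), specs, seed = 3)
  cfg <- train_config(hidden = 1:3, restarts = 10L, seed = 29)
  fit <- train_response(tab, "y", cfg)
  expect_gte(fit$H, 2)
  expect_gte(fit$r2[["train"]], 0.99)
})

test_that("topology search returns one named fit per response", {
  specs <- default_surface_specs(noise_scale = 0)[c("DMC", "WL")]
  tab <- simulate_responses(bbd_design(), specs, seed = 2)
  fits <- topology_search(tab, responses = c("DMC", "WL"),
                          cfg = train_config(hidden = 2:3, restarts = 3L, seed = 1))
  expect_named(fits, c("DMC", "WL"))
  sm <- summary(fits)
  expect_equal(nrow(sm), 2L)
  expect_true(all(grepl("^MLP 3-[23]-1$", sm$net)))
  expect_true(all(sm$r2_train <= 1))
  empty <- topology_search(tab, responses = character(0))
  expect_length(empty, 0L)
})
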