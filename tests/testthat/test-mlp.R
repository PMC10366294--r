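# Minimal hand-built network: one 2-unit hidden layer without batch norm,
# weights chosen for pencil-and-paper verification.
toy_net <- function() {
  list(layers = list(list(W = rbind(c(1, 2), c(3, 4)), b = c(0.5, -1))),
       cls = list(W = rbind(c(1, 0), c(0, 1), c(1, 1)), b = c(0, 0, 0)),
       reg = list(W = rbind(c(2, 0), c(0, 3)), b = c(0.1, 0.2)))
}

test_that("the forward pass reproduces hand-computed arithmetic", {
  # z = (1*0.2 + 2*(-0.3) + 0.5, 3*0.2 + 4*(-0.3) - 1) = (0.1, -1.6)
  # ReLU -> (0.1, 0); logits (0.1, 0, 0.1); reg (0.3, 0.2)
  out <- mlp_forward(toy_net(), c(0.2, -0.3))
  e <- exp(c(0.1, 0, 0.1) - 0.1)
  expect_equal(as.vector(out$logits), c(0.1, 0, 0.1), tolerance = 1e-12)
  expect_equal(as.vector(out$probs), e / sum(e), tolerance = 1e-12)
  expect_equal(as.vector(out$reg), c(0.3, 0.2), tolerance = 1e-12)
  expect_error(mlp_forward(toy_net(), c(1, 2, 3)), "input size")
})

test_that("softmax is symmetric at zero logits and matches closed forms", {
  net <- toy_net()
  net$layers[[1]]$W[] <- 0; net$layers[[1]]$b[] <- 0
  net$cls$W[] <- 0; net$reg$W[] <- 0; net$reg$b <- c(5, 7)
  out <- mlp_forward(net, c(3.2, -1.1))
  expect_equal(as.vector(out$probs), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(as.vector(out$reg), c(5, 7))
  # logits (ln 2, 0, 0) -> probabilities (1/2, 1/4, 1/4)
  p <- capmech:::softmax(matrix(c(log(2), 0, 0), 1))
  expect_equal(as.vector(p), c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # normalisation holds for extreme logits thanks to max subtraction
  pp <- capmech:::softmax(matrix(c(1000, -1000, 0, 3, 2, 1), 2,
                                 byrow = TRUE))
  expect_equal(rowSums(pp), c(1, 1), tolerance = 1e-12)
})

test_that("losses vanish at perfect predictions and match ln 3 when flat", {
  perfect <- capmech:::mlp_losses(matrix(c(1, 0, 0), 1), matrix(c(1, 2), 1),
                                  z_idx = 1L, y = matrix(c(1, 2), 1))
  expect_equal(perfect$cls, 0)
  expect_equal(perfect$reg, 0)
  flat <- capmech:::mlp_losses(matrix(1 / 3, 1, 3), matrix(0, 1, 2),
                               z_idx = 2L, y = matrix(c(1, -1), 1))
  expect_equal(flat$cls, log(3), tolerance = 1e-12)
  expect_equal(flat$reg, 2)
  # zero probability at the true class is floored, not infinite
  guarded <- capmech:::mlp_losses(matrix(c(0, 1, 0), 1), matrix(0, 1, 2),
                                  z_idx = 1L, y = matrix(0, 1, 2))
  expect_true(is.finite(guarded$cls))
})

test_that("training overfits a separable toy problem within 200 epochs", {
  toy <- toy_classification_set()
  fit <- capsule_mlp(toy, mlp_control(batch_size = 8, max_epochs = 200,
                                      hidden = c(32, 32), seed = 1))
  pred <- predict(fit, toy$x)
  expect_equal(mean(pred$kind == toy$kind), 1)
  h <- fit$history
  expect_lt(h$train_loss[fit$best_epoch], h$train_loss[1])
})

test_that("training is deterministic in its seed", {
  toy <- toy_classification_set()
  ctl <- mlp_control(batch_size = 8, max_epochs = 40, hidden = c(16, 16),
                     seed = 9)
  f1 <- capsule_mlp(toy, ctl)
  f2 <- capsule_mlp(toy, ctl)
  expect_identical(f1$val_loss, f2$val_loss)
  expect_identical(coef(f1), coef(f2))
  ctl$seed <- 10
  f3 <- capsule_mlp(toy, ctl)
  expect_false(identical(f1$val_loss, f3$val_loss))
})

test_that("training rejects datasets smaller than one mini-batch", {
  toy <- toy_classification_set()
  expect_error(capsule_mlp(toy, mlp_control(batch_size = 128)),
               "smaller than one mini-batch")
})

test_that("prediction is a pure function with unit-sum probabilities", {
  toy <- toy_classification_set()
  fit <- capsule_mlp(toy, mlp_control(batch_size = 8, max_epochs = 30,
                                      hidden = c(16, 16), seed = 2))
  X <- matrix(stats::rnorm(40), 20, 2)
  p1 <- predict(fit, X)
  p2 <- predict(fit, X)
  expect_identical(p1, p2)
  expect_equal(p1$prob_NH + p1$prob_SK + p1$prob_HK, rep(1, 20),
               tolerance = 1e-9)
  expect_true(all(p1$ca_ks > 0 & p1$ca_gs > 0))  # de-standardised, clamped
  expect_true(all(p1$kind %in% c("NH", "SK", "HK")))
  # argmax rule: the reported kind carries the largest probability
  pm <- as.matrix(p1[, c("prob_NH", "prob_SK", "prob_HK")])
  expect_identical(p1$kind,
                   c("NH", "SK", "HK")[max.col(pm, ties.method = "first")])
  expect_error(predict(fit, matrix(0, 2, 5)), "length")
})

test_that("a flow condition converts capillary numbers into moduli", {
  toy <- toy_classification_set()
  fit <- capsule_mlp(toy, mlp_control(batch_size = 8, max_epochs = 20,
                                      hidden = c(16, 16), seed = 3))
  fl <- flow_condition(mu = 1, U = 1e-3, R = 1e-3, a0 = 7e-4)
  pr <- predict(fit, toy$x[1:4, ], flow = fl)
  expect_equal(pr$Ks, 1e-3 / pr$ca_ks, tolerance = 1e-12)
  expect_equal(pr$Gs, 1e-3 / pr$ca_gs, tolerance = 1e-12)
})

test_that("fits round-trip through the JSON serialisation", {
  ds <- generate_dataset(n = 120, n_nodes = 16, seed = 4)
  fit <- capsule_mlp(ds, mlp_control(batch_size = 32, max_epochs = 30,
                                     hidden = c(24, 24), seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_capsule_mlp(fit, f)
  back <- read_capsule_mlp(f)
  probe <- generate_dataset(n = 6, n_nodes = 16, seed = 5)
  expect_equal(predict(back, probe), predict(fit, probe), tolerance = 1e-12)
})

test_that("the two-network variant trains and predicts like the shared one", {
  ds <- generate_dataset(n = 150, n_nodes = 16, seed = 6)
  fit <- capsule_mlp(ds, mlp_control(batch_size = 32, max_epochs = 40,
                                     hidden = c(24, 24), seed = 6,
                                     two_networks = TRUE))
  pr <- predict(fit, ds)
  expect_equal(pr$prob_NH + pr$prob_SK + pr$prob_HK, rep(1, 150),
               tolerance = 1e-9)
  truth <- as.data.frame(ds)
  expect_lt(mape(pr$ca_ks, truth$ca_ks), 25)
})
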