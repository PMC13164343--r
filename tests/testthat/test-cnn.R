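test_that("forward pass yields normalized softmax and finite outputs on degenerate input", {
  model <- build_pure_cnn(width = 8, input_size = 16, seed = 1)
  x <- array(stats::rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  probs <- predict_proba(model, x)
  expect_equal(dim(probs), c(2, 4))
  expect_equal(rowSums(probs), c(1, 1))
  expect_true(all(probs >= 0))
  # all-zero input stays finite
  z <- predict_proba(model, array(0, c(16, 16, 3, 1)))
  expect_true(all(is.finite(z)))
  expect_equal(sum(z), 1)
})

test_that("parameter count matches the analytic layer schedule", {
  # per layer: conv k*k*c_in*f + f bias; batch norm 2f; dense in*out + out
  analytic <- function(w) {
    conv1 <- 9 * 3 * w + w
    convn <- 9 * w * w + w
    bn <- 2 * w
    fc1 <- w * 512 + 512
    fc2 <- 512 * 4 + 4
    conv1 + 3 * convn + 4 * bn + fc1 + fc2
  }
  expect_equal(param_count(build_pure_cnn(width = 64, input_size = 16)), analytic(64))
  expect_equal(param_count(build_pure_cnn(width = 8, input_size = 16)), analytic(8))
  expect_error(build_pure_cnn(width = 4), ">= 8")
})

test_that("analytic gradients agree with central finite differences", {
  model <- build_pure_cnn(width = 8, input_size = 8, seed = 2)
  fdtaudit:::with_seed(3, x <- array(stats::rnorm(8 * 8 * 3 * 3, 0, 0.5), c(8, 8, 3, 3)))
  y <- c(1L, 3L, 4L)
  w <- c(1.2, 0.9, 1.0, 0.9)
  mask <- matrix(1, 3, 8)
  loss_of <- function(m) {
    fw <- fdtaudit:::cnn_forward(m, x, training = TRUE, dropout_mask = mask)
    probs <- fdtaudit:::softmax_rows(fw$logits)
    mean(-w[y] * log(probs[cbind(1:3, y)]))
  }
  fw <- fdtaudit:::cnn_forward(model, x, training = TRUE, dropout_mask = mask)
  probs <- fdtaudit:::softmax_rows(fw$logits)
  onehot <- matrix(0, 3, 4); onehot[cbind(1:3, y)] <- 1
  grads <- fdtaudit:::cnn_backward(model, fw$cache, (probs - onehot) * (w[y] / 3))
  gf <- fdtaudit:::flatten_params(grads)
  pf <- fdtaudit:::flatten_params(model$params)
  eps <- 1e-5
  # conv biases feed straight into batch norm, which cancels them; skip
  check_names <- setdiff(names(pf), c("b1", "b2", "b3", "b4"))
  fdtaudit:::with_seed(4, {
    for (nm in check_names) {
      for (r in 1:2) {
        i <- sample(length(pf[[nm]]), 1)
        fl <- pf; fl[[nm]][i] <- fl[[nm]][i] + eps
        m2 <- model; m2$params <- fdtaudit:::unflatten_params(fl, model$params)
        lp <- loss_of(m2)
        fl[[nm]][i] <- fl[[nm]][i] - 2 * eps
        m2$params <- fdtaudit:::unflatten_params(fl, model$params)
        lm <- loss_of(m2)
        num <- (lp - lm) / (2 * eps)
        ana <- gf[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  })
})

test_that("the training schedule halts after the early-stopping patience and halves the rate on plateaus", {
  # flat validation metric: improvement only at epoch 1, patience 5 ->
  # training halts at epoch 6 (the 5th consecutive non-improving epoch)
  sched <- training_schedule(rep(0.5, 8), lr0 = 3e-4)
  expect_equal(sched$stop_epoch, 6)
  expect_equal(sched$best_epoch, 1)
  # a 2-epoch plateau halves the learning rate for the following epoch
  sched2 <- training_schedule(c(0.6, 0.6, 0.6, 0.7), lr0 = 3e-4)
  expect_equal(sched2$lr, c(3e-4, 3e-4, 3e-4, 1.5e-4))
  expect_true(is.na(sched2$stop_epoch))
  # repeated plateaus keep halving
  sched3 <- training_schedule(c(0.6, rep(0.6, 6)), lr0 = 3e-4, es_patience = 10)
  expect_equal(sched3$lr, c(3e-4, 3e-4, 3e-4, 1.5e-4, 1.5e-4, 7.5e-5, 7.5e-5))
})

test_that("seeded training is reproducible and learns phantom classes above chance", {
  cohort <- generate_cohort(c(10, 11, 14, 15), image_size = 32, noise_sd = 0.02,
                            seed = 11)
  split <- stratified_split(cohort$labels, "holdout", fractions = c(0.8, 0.2, 0),
                            seed = 1)
  cfg <- train_config(max_epochs = 3, seed = 1)
  fit1 <- train_cnn(build_pure_cnn(width = 8, input_size = 32, seed = 1),
                    cohort, split, NULL, cfg)
  fit2 <- train_cnn(build_pure_cnn(width = 8, input_size = 32, seed = 1),
                    cohort, split, NULL, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$predictor$params, fit2$predictor$params)
  expect_equal(nrow(fit1$log), 3)
  expect_true(all(c("train_loss", "val_acc", "val_macro_f1", "lr") %in% names(fit1$log)))
})

test_that("trained predictors plug into the prediction interface used by the verifier", {
  model <- build_pure_cnn(width = 8, input_size = 32, seed = 5)
  img <- generate_phantom(phantom_spec("pituitary", 64, seed = 2))$image
  pred <- predict_slice(model, img)
  expect_s3_class(pred, "fdt_prediction")
  expect_equal(sum(pred$softmax), 1, tolerance = 1e-9)
  tr <- build_trace("p1", make_features(), pred, model$model_id)
  expect_s3_class(tr, "fdt_decision_trace")
})
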