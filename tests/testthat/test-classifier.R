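test_that("light backend learns the waist fixture and refits identically", {
  fx <- fixture()
  waist <- dplyr::filter(fx$windows, position == "s1")
  ev <- evaluate_model(fx$models$s1, waist)
  expect_gte(ev$accuracy, 0.90)
  refit <- fit_node_model(waist, model_spec("light"), seed = 42)
  expect_equal(coef(refit$fit), coef(fx$models$s1$fit), tolerance = 1e-10)
})

test_that("predictions are probability vectors with the winning class's
           weight, and are pure functions of their inputs", {
  fx <- fixture()
  waist <- dplyr::filter(fx$windows, position == "s1")[1:20, ]
  p <- predict(fx$models$s1, waist)
  wcols <- as.matrix(p[, paste0("w_", activity_levels())])
  expect_equal(unname(rowSums(wcols)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_equal(p$weight, apply(wcols, 1, max), tolerance = 1e-12)
  expect_equal(as.character(p$label),
               activity_levels()[apply(wcols, 1, which.max)])
  expect_identical(predict(fx$models$s1, waist), p)
  # clean static windows are the easy case: all predicted correctly
  lying <- dplyr::filter(fx$windows, position == "s1", activity == "lying",
                         split == "test")
  expect_true(all(predict(fx$models$s1, lying)$label == "lying"))
  # guard rails
  bad <- waist[1, ]
  bad$values[[1]][1, 1] <- NaN
  expect_error(predict(fx$models$s1, bad), class = "panhar_bad_argument")
  leg <- dplyr::filter(fx$windows, position == "s3")[1:2, ]
  expect_error(predict(fx$models$s1, leg), class = "panhar_bad_argument")
})

test_that("evaluation returns a conserved confusion matrix", {
  fx <- fixture()
  chest <- dplyr::filter(fx$windows, position == "s2")
  ev <- evaluate_model(fx$models$s2, chest)
  n_test <- sum(chest$split == "test")
  expect_equal(ev$n, n_test)
  expect_equal(sum(ev$confusion), n_test)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / n_test)
  # degenerate predictors through the same constructor
  perfect <- panhar:::confusion_eval(chest$activity[1:16], chest$activity[1:16])
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  constant <- panhar:::confusion_eval(rep(activity_levels(), 2),
                                      rep("walking", 16))
  expect_equal(constant$accuracy, 2 / 16)
  expect_true(all(constant$confusion[, -1] == 0))
  # tidiers
  expect_equal(glance(ev)$accuracy, ev$accuracy)
  td <- tidy(ev)
  expect_equal(sum(td$n), n_test)
})

test_that("model_spec enforces the recurrent defaults and epoch cap", {
  spec <- model_spec("rnn")
  expect_equal(spec$lstm_units, 60)
  expect_equal(spec$dropout_rate, 0.5)
  expect_equal(spec$dense_units, 60)
  expect_equal(spec$batch_size, 64)
  expect_equal(spec$max_epochs, 40L)
  expect_error(model_spec("rnn", max_epochs = 60),
               class = "panhar_bad_argument")
})

test_that("LSTM gradients match finite differences", {
  set.seed(1)
  B <- 3; T_ <- 5; D <- 2; U <- 4; H <- 3; C <- 3
  Xlist <- lapply(seq_len(T_), function(t) matrix(rnorm(B * D), B, D))
  y <- c(1L, 2L, 3L)
  params <- panhar:::lstm_init(D, U, H, C, seed = 7)
  fwd <- panhar:::lstm_forward(params, Xlist)
  bwd <- panhar:::lstm_backward(params, fwd, y)
  loss_at <- function(p) {
    f <- panhar:::lstm_forward(p, Xlist)
    -mean(log(f$probs[cbind(seq_len(B), y)]))
  }
  eps <- 1e-5
  set.seed(2)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (j in idx) {
      up <- params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
      numeric <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(bwd$grads[[nm]][j], numeric, tolerance = 1e-5,
                   info = paste("param", nm, "entry", j))
    }
  }
})

test_that("a 1-epoch recurrent run completes and predicts sum-to-one
           weights", {
  fx <- fixture()
  small <- dplyr::filter(fx$windows, position == "s1", split == "train") |>
    dplyr::group_by(activity) |>
    dplyr::slice(1:4) |>
    dplyr::ungroup()
  spec <- model_spec("rnn", max_epochs = 1)
  m <- fit_node_model(small, spec, seed = 42)
  expect_equal(nrow(m$training_log), 1L)
  p <- predict(m, small[1:6, ])
  wcols <- as.matrix(p[, paste0("w_", activity_levels())])
  expect_equal(unname(rowSums(wcols)), rep(1, 6), tolerance = 1e-6)
  expect_equal(p$weight, apply(wcols, 1, max), tolerance = 1e-12)
})
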