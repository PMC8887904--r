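test_that("strided-convolution output sizes follow the recurrence", {
  expect_equal(conv_out_dim(120, 20), 6)   # (120 - 20)/20 + 1
  expect_equal(conv_out_dim(64, 16), 4)
  expect_error(conv_out_dim(5, 10), "does not fit")

  # kernel chain 20 -> 10 -> 20 collapses on realistic inputs: a 160 x 160
  # image gives 8 x 8 after layer 1 and layer 2's 10 x 10 kernel cannot fit
  expect_error(build_cnn(cnn_spec(), input_dim = c(160, 160)),
               "does not fit")
  expect_error(build_cnn(cnn_spec(conv = list(c(4, 20), c(4, 10), c(4, 20))),
                         input_dim = c(100, 100)), "does not fit")

  # the recurrence holds at every layer of a buildable model
  m <- build_cnn(tiny_spec(), input_dim = c(64, 64))
  expect_equal(m$dims[[1]], c(4L, 4L))   # (64-16)/16+1
  expect_equal(m$dims[[2]], c(2L, 2L))
  expect_equal(m$dims[[3]], c(1L, 1L))
})

test_that("paper-default DAG architecture builds on a large enough input", {
  m <- build_dag_cnn(dag_spec(), input_dim = c(6750, 6750))
  expect_equal(m$dims[[1]], c(225L, 225L))  # (6750-30)/30+1
  expect_equal(m$dims[[2]], c(15L, 15L))
  expect_equal(m$dims[[3]], c(1L, 1L))
  expect_equal(dim(m$params$proj$W), c(10L, 20L))
})

test_that("parameter counts match the closed form", {
  sp <- tiny_spec()
  m <- build_cnn(sp, input_dim = c(64, 64))
  expected <- (16 * 16 * 1 * 8 + 8) + (2 * 2 * 8 * 8 + 8) +
    (2 * 2 * 8 * 8 + 8) + (2 * (1 * 1 * 8) + 2)
  expect_equal(n_parameters(m), expected)

  dm <- build_dag_cnn(tiny_dag_spec(), input_dim = c(64, 64))
  dexp <- (16 * 16 * 1 * 4 + 4) + (2 * 2 * 4 * 8 + 8) +
    (2 * 2 * 8 * 8 + 8) + (4 * 8 + 8) + (2 * 8 + 2)
  expect_equal(n_parameters(dm), dexp)
})

test_that("convolution forward/backward agree with a finite-difference check", {
  set.seed(1)
  ds <- array_dataset(array(runif(64 * 64 * 6, 0, 1), dim = c(64, 64, 6)),
                      c(1L, 0L, 1L, 0L, 1L, 0L))
  for (spec in list(tiny_spec(), tiny_dag_spec())) {
    model <- if (spec$type == "dag") build_dag_cnn(spec, c(64, 64), seed = 2)
             else build_cnn(spec, c(64, 64), seed = 2)
    x <- gmclass:::dataset_tensor(ds)
    y <- ds$records$label
    lg <- gmclass:::loss_and_grads(model, x, y)
    # probe a few scalar weights in each block
    probes <- list(c("conv", 1L), c("conv", 3L), c("fc", NA))
    if (spec$type == "dag") probes <- c(probes, list(c("proj", NA)))
    eps <- 1e-5
    for (pr in probes) {
      part <- pr[1]
      getW <- function(m) if (part == "conv") m$params$conv[[as.integer(pr[2])]]$W
                          else m$params[[part]]$W
      setW <- function(m, W) {
        if (part == "conv") m$params$conv[[as.integer(pr[2])]]$W <- W
        else m$params[[part]]$W <- W
        m
      }
      gW <- if (part == "conv") lg$grads$conv[[as.integer(pr[2])]]$W
            else lg$grads[[part]]$W
      idx <- which.max(abs(gW))
      Wp <- getW(model); Wp[idx] <- Wp[idx] + eps
      lp <- gmclass:::loss_and_grads(setW(model, Wp), x, y)$loss
      Wm <- getW(model); Wm[idx] <- Wm[idx] - eps
      lm <- gmclass:::loss_and_grads(setW(model, Wm), x, y)$loss
      expect_equal((lp - lm) / (2 * eps), gW[idx], tolerance = 1e-3)
    }
  }
})

test_that("training is deterministic and loss decreases on a separable fixture", {
  ds <- strong_cohort(seed = 3, n_tle = 12, n_hc = 12, effect = 0.5,
                      noise = 0)
  cfg <- tiny_train_cfg(seed = 5, epochs = 12)
  m1 <- train_model(tiny_spec(), ds, cfg = cfg)
  m2 <- train_model(tiny_spec(), ds, cfg = cfg)
  expect_identical(m1$params, m2$params)
  loss <- m1$history$loss$loss
  # non-increasing up to small SGD jitter, and clearly lower at the end
  expect_true(all(diff(loss) < 0.05))
  expect_lt(loss[length(loss)], loss[1])
  expect_error(train_model(tiny_spec(),
                           subset_dataset(ds, which(ds$records$label == 1L)),
                           cfg = cfg),
               "both classes")
})

test_that("a separable cohort trains to high validation accuracy; DAG reduces to CNN when the skip branch is zeroed", {
  ds <- strong_cohort(seed = 4, n_tle = 20, n_hc = 20, effect = 0.5)
  split <- stratified_split(ds, 0.25, seed = 1)
  m <- train_model(tiny_spec(), split$train_val, val_set = split$test,
                   cfg = tiny_train_cfg(seed = 1, epochs = 25))
  expect_gte(tail(m$history$validation$val_accuracy, 1), 0.95)

  dmod <- train_model(tiny_dag_spec(), split$train_val,
                      cfg = tiny_train_cfg(seed = 3, epochs = 5))
  scores_full <- predict_scores(dmod, split$test)
  # zero the skip projection: forward pass must equal the plain conv chain
  dzero <- dmod
  dzero$params$proj$W[] <- 0
  dzero$params$proj$b[] <- 0
  czero <- dzero
  czero$spec <- cnn_spec(conv = czero$spec$conv)
  expect_equal(predict_scores(dzero, split$test),
               predict_scores(czero, split$test), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(scores_full, predict_scores(dzero, split$test))))
})

test_that("predicted scores are two-class probabilities and stable", {
  ds <- strong_cohort(seed = 6, n_tle = 10, n_hc = 10)
  m <- train_model(tiny_spec(), ds, cfg = tiny_train_cfg(seed = 7, epochs = 8))
  s <- predict_scores(m, ds)
  expect_true(all(s >= 0 & s <= 1))
  # duplicated input gives identical scores
  expect_identical(predict_scores(m, ds$images[, , 1]),
                   predict_scores(m, ds$images[, , 1]))
  # TLE scores exceed HC scores on the separable fixture
  expect_gt(mean(s[ds$records$label == 1L]), mean(s[ds$records$label == 0L]))
  # complement probability: softmax columns sum to 1 by construction
  x <- gmclass:::dataset_tensor(ds)
  sm <- gmclass:::softmax_cols(gmclass:::forward_pass(m, x)$scores)
  expect_equal(colSums(sm), rep(1, n_subjects(ds)), tolerance = 1e-12)
  expect_error(predict_scores(m, matrix(0.5, 32, 32)), "does not match")
})

test_that("layer activations have the spec'd filter counts and spatial dims", {
  ds <- strong_cohort(seed = 8, n_tle = 8, n_hc = 8)
  m <- train_model(tiny_spec(), ds, cfg = tiny_train_cfg(seed = 9, epochs = 3))
  img <- ds$images[, , 1]
  for (l in 1:3) {
    a <- layer_activations(m, img, l)
    expect_equal(dim(a), c(m$dims[[l]], m$spec$conv[[l]][1]))
  }
  expect_error(layer_activations(m, img, 4), "layer must be")
  # zero input: maps are bias-constant, flagged as zero/flat after abs-norm
  z <- layer_activations(m, matrix(0, 64, 64), 1)
  expect_true(all(apply(z, 3, function(mm) diff(range(mm)) == 0)))
})

test_that("checkpoints round-trip through save/load", {
  ds <- strong_cohort(seed = 10, n_tle = 8, n_hc = 8)
  m <- train_model(tiny_spec(), ds, cfg = tiny_train_cfg(seed = 1, epochs = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(predict_scores(m2, ds), predict_scores(m, ds))
})
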