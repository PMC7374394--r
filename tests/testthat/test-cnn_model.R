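test_that("build_model derives shapes, rejects collapsing kernels, is deterministic", {
  hp <- hp_vector(ks = c(23, 17, 11), kc = c(56, 48, 102), dlnc = c(1762, 984))
  m <- build_model(hp, input_length = 200, n_classes = 5, seed = 1)
  expect_s3_class(m, "cnn_model")
  expect_identical(length(m$layers), 6L)   # 3 conv + 2 dense + output
  expect_identical(ncol(m$layers[[6]]$W), 5L)
  # feature lengths: valid conv then pool/2 at each block
  expect_identical(m$layers[[1]]$out_len, 178L)
  expect_identical(m$layers[[2]]$in_len, 89L)
  # kernel larger than the input fails with the offending layer named
  expect_error(build_model(hp_vector(201, 4, c(8, 8)), input_length = 200),
               "conv layer 1")
  # deep stack that collapses partway names the failing layer
  expect_error(
    build_model(hp_vector(ks = c(81, 81, 81), kc = c(4, 4, 4),
                          dlnc = c(16, 16)), input_length = 200),
    "conv layer")
  # parameter count is a pure function of (hp, input_length, n_classes)
  m2 <- build_model(hp, input_length = 200, n_classes = 5, seed = 99)
  expect_identical(m$n_parameters, m2$n_parameters)
})

test_that("pooling is skipped automatically when the feature map would collapse", {
  # block 1: 5 -> 3, pool -> 1; a second 3-wide kernel on 1 sample collapses
  hp <- hp_vector(ks = c(3, 3), kc = c(2, 2), dlnc = c(4, 4))
  expect_error(build_model(hp, input_length = 5, n_classes = 5, seed = 2),
               "conv layer 2")
  # with ks = 1 the block builds and its pooling is disabled
  hp_ok <- hp_vector(ks = c(3, 1), kc = c(2, 2), dlnc = c(4, 4))
  m_ok <- build_model(hp_ok, input_length = 5, n_classes = 5, seed = 2)
  expect_false(m_ok$layers[[2]]$pool)
  expect_identical(m_ok$flat_dim, 2L)
})

test_that("backpropagation matches central finite differences", {
  set.seed(3)
  hp <- hp_vector(ks = c(5, 3), kc = c(3, 4), dlnc = c(8, 6))
  m <- build_model(hp, input_length = 30, n_classes = 5, seed = 11)
  X <- matrix(rnorm(4 * 30), 4, 30)
  y <- factor(pattern_types()[c(1, 2, 3, 4)], levels = pattern_types())
  Y <- hscnn:::labels_to_onehot(y, 5)
  loss_of <- function(mm) {
    p <- hscnn:::cnn_forward(mm, X)$probs
    -mean(log(pmax(rowSums(p * Y), 1e-12)))
  }
  fwd <- hscnn:::cnn_forward(m, X, keep = TRUE)
  gr <- hscnn:::cnn_backward(m, X, Y, fwd)
  eps <- 1e-5
  for (li in seq_along(m$layers)) {
    W <- m$layers[[li]]$W
    for (t in 1:4) {
      i <- sample(length(W), 1)
      mp <- m; mp$layers[[li]]$W[i] <- W[i] + eps
      mm_ <- m; mm_$layers[[li]]$W[i] <- W[i] - eps
      num <- (loss_of(mp) - loss_of(mm_)) / (2 * eps)
      ana <- gr[[li]]$dW[i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-5)
    }
  }
})

test_that("training memorizes a single-class set and is seed-reproducible", {
  set.seed(4)
  X <- matrix(rnorm(10 * 40), 10, 40)
  y <- factor(rep("EUPNEA", 10), levels = pattern_types())
  hp <- hp_vector(ks = 5, kc = 4, dlnc = c(8, 8))
  cfg <- training_config(epochs = 10, batch_size = 5, seed = 42)
  m <- train_model(build_model(hp, 40, seed = 42), X, y, cfg)
  expect_false(m$diverged)
  expect_equal(evaluate_model(m, X, y)$rate, 100)
  # bit-reproducible loss curve under a fixed seed
  m2 <- train_model(build_model(hp, 40, seed = 42), X, y, cfg)
  expect_identical(m$loss_curve, m2$loss_curve)
})

test_that("the CNN learns separable low-noise synthetic data", {
  ds <- test_dataset()   # 150 pieces, noise 0.05; 90/30/30 split
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  cfg <- training_config(learning_rate = 0.05, epochs = 30, batch_size = 30,
                         seed = 7)
  hp <- hp_vector(ks = c(11, 5), kc = c(8, 12), dlnc = c(48, 24))
  m <- build_model(hp, input_length = ncol(tr$x), n_classes = 5,
                   seed = 7)
  m <- train_model(m, tr$x, tr$y, cfg)
  res <- evaluate_model(m, va$x, va$y)
  expect_gte(res$rate, 90)
})

test_that("evaluate_model computes rate = 100 * trace / total with row sums intact", {
  y <- factor(rep(pattern_types(), each = 8), levels = pattern_types())
  # perfect predictions
  perfect <- evaluate_model(y, NULL, y)
  expect_equal(perfect$rate, 100)
  # arbitrary predictions: identity between confusion trace and rate
  set.seed(5)
  preds <- factor(sample(pattern_types(), 40, replace = TRUE),
                  levels = pattern_types())
  res <- evaluate_model(preds, NULL, y)
  expect_equal(res$rate, 100 * sum(diag(res$confusion)) / res$n)
  expect_identical(unname(rowSums(res$confusion)), rep(8, 5))
  # uniform-random predictor on balanced classes scores ~20%
  n <- 5000
  yb <- factor(rep(pattern_types(), each = n / 5), levels = pattern_types())
  pu <- factor(sample(pattern_types(), n, replace = TRUE),
               levels = pattern_types())
  expect_lt(abs(evaluate_model(pu, NULL, yb)$rate / 100 - 0.2),
            5 * sqrt(0.2 * 0.8 / n))
  expect_error(evaluate_model(preds, NULL, factor(character(0))), "empty")
})

test_that("the objective is total, bounded and deterministic per tuple", {
  ds <- test_dataset()
  cfg <- training_config(epochs = 3, batch_size = 30)
  obj <- make_objective(ds, cfg, base_seed = 9)
  hp <- hp_vector(ks = c(7, 3), kc = c(4, 4), dlnc = c(16, 16))
  r1 <- obj(hp)
  expect_true(is.finite(r1) && r1 >= 0 && r1 <= 100)
  expect_identical(obj(hp), r1)
  # an architecture that cannot be built scores 0 with a warning
  bad <- hp_vector(ks = c(199, 199), kc = c(4, 4), dlnc = c(16, 16))
  expect_warning(r_bad <- obj(bad), "scoring 0")
  expect_identical(r_bad, 0)
})

test_that("recognition rate is invariant to evaluation piece order", {
  ds <- test_dataset()
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  cfg <- training_config(epochs = 4, batch_size = 30, seed = 10)
  m <- build_model(hp_vector(ks = c(9, 5), kc = c(6, 6), dlnc = c(24, 16)),
                   ncol(tr$x), seed = 10)
  m <- train_model(m, tr$x, tr$y, cfg)
  r1 <- evaluate_model(m, va$x, va$y)$rate
  set.seed(11)
  perm <- sample(length(va$y))
  r2 <- evaluate_model(m, va$x[perm, ], va$y[perm])$rate
  expect_equal(r1, r2)
})
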