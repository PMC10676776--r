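test_that("scaled dot-product attention matches hand-computed cases", {
  # single key/value row: softmax over one element is 1, output = v
  q <- matrix(rnorm(6), 3, 2)
  v <- matrix(c(2, 5), 1, 2)
  out <- scaled_dot_attention(q, matrix(c(1, 1), 1, 2), v)
  expect_equal(out, matrix(rep(c(2, 5), each = 3), 3, 2))

  # identical key rows: uniform softmax, each output row = column mean of V
  k <- matrix(1, 4, 2)
  v <- matrix(seq_len(8), 4, 2)
  out <- scaled_dot_attention(q, k, v)
  expect_equal(out, matrix(rep(colMeans(v), each = 3), 3, 2))

  # 2x2 identity, d_k = 2: softmax(I / sqrt(2)) row 1 = (e^r, 1)/(e^r + 1)
  out <- scaled_dot_attention(diag(2), diag(2), diag(2))
  r <- exp(1 / sqrt(2))
  expect_equal(out[1, ], c(r, 1) / (r + 1), tolerance = 1e-12)
  expect_equal(out[1, ], c(0.6698, 0.3302), tolerance = 1e-4)

  expect_error(scaled_dot_attention(q, matrix(1, 2, 3), v), "d_k")
})

test_that("attention softmax rows are simplex weights", {
  set.seed(51)
  for (i in 1:20) {
    s <- matrix(rnorm(30, sd = 5), 5, 6)
    a <- oriforge:::row_softmax(s)
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, 5), tolerance = 1e-6)
  }
})

test_that("ELU is exact, continuous and monotone", {
  expect_identical(elu(0), 0)
  expect_identical(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1)
  expect_equal(elu(-1), -0.6321, tolerance = 1e-4)

  grid <- seq(-10, 10, length.out = 1e4)
  y <- elu(grid, alpha = 1.3)
  expect_true(all(diff(y) >= 0))          # monotone non-decreasing
  expect_true(all(y >= -1.3))             # lower bound -alpha
  expect_lt(abs(elu(1e-9) - elu(-1e-9)), 1e-8)  # continuity at 0
})

test_that("BCE loss matches closed forms and is flip-invariant", {
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0, 0.5), log(2))
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5)  # perfect prediction

  set.seed(52)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50)
  expect_equal(bce_loss(y, p), bce_loss(1 - y, 1 - p))
  expect_gte(bce_loss(y, p), 0)
})

test_that("model building is seeded and architecture follows the config", {
  cfg <- classifier_config(input_dim = 60L)
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_model(cfg, seed = 8)$params))

  # default: exactly 3 structure blocks, each with attention and conv
  nm <- names(build_model(classifier_config(252L))$params)
  expect_identical(sum(grepl("^b\\d+\\.attn\\.Wq$", nm)), 3L)
  expect_identical(sum(grepl("^b\\d+\\.conv\\.b$", nm)), 3L)
  expect_false(any(grepl("^b4", nm)))

  # single-block and attention-free variants are valid
  small <- build_model(classifier_config(12L, n_blocks = 1L), seed = 1)
  expect_identical(sum(grepl("^b1\\.", names(small$params))), 7L)
  noatt <- build_model(classifier_config(12L, attention = FALSE), seed = 1)
  expect_false(any(grepl("attn", names(noatt$params))))

  expect_error(classifier_config(input_dim = 100L), "must be one of")
})

test_that("forward pass is deterministic, ordered and in [0, 1]", {
  cfg <- classifier_config(48L, n_blocks = 2L, conv_channels = 4L)
  m <- build_model(cfg, seed = 3)
  set.seed(53)
  x <- matrix(rnorm(10 * 48), 10, 48)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_length(p1, 10L)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batch order: row i scores equal to scoring row i alone
  expect_equal(p1[4], predict(m, x[4, ]))
  expect_error(predict(m, x[, 1:12]), "does not match")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- classifier_config(12L, n_blocks = 2L, conv_channels = 3L,
                           mlp_hidden = 4L)
  m <- build_model(cfg, seed = 11)
  set.seed(54)
  x <- matrix(rnorm(3 * 12), 3, 12)
  y <- c(1, 0, 1)
  fw <- oriforge:::model_forward(m$params, x, cfg, keep_cache = TRUE)
  gr <- oriforge:::model_backward(m$params, cfg, fw, y)
  loss_at <- function(p) bce_loss(y, oriforge:::model_forward(p, x, cfg)$prob)
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (i in seq_len(min(4L, length(m$params[[nm]])))) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gr[[nm]][i], numeric_grad, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training learns separable data and is seed-deterministic", {
  # tiny linearly separable Z-vector classes (shifted mono+di encodings)
  set.seed(55)
  make_xy <- function(n) {
    x <- matrix(rnorm(n * 12, sd = 0.3), n, 12)
    y <- rep(c(1, 0), length.out = n)
    x[y == 1, 1:4] <- x[y == 1, 1:4] + 1
    list(x = x, y = y)
  }
  tr <- make_xy(120); va <- make_xy(40)
  cfg <- classifier_config(12L, n_blocks = 1L, conv_channels = 4L,
                           mlp_hidden = 8L)
  tcf <- train_config(learning_rate = 5e-3, batch_size = 32L,
                      max_epochs = 15L, patience = 15L, seed = 2)
  for (seed in 1:3) {
    tcf$seed <- seed
    m <- train_classifier(tr$x, tr$y, va$x, va$y, cfg, tcf)
    h <- tidy(m)
    expect_lte(h$val_loss[m$best_epoch], h$val_loss[1])  # learning happened
  }
  m1 <- train_classifier(tr$x, tr$y, va$x, va$y, cfg, tcf)
  m2 <- train_classifier(tr$x, tr$y, va$x, va$y, cfg, tcf)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$params, m2$params)
  expect_gte(auc(va$y, predict(m1, va$x)), 0.9)

  expect_error(train_classifier(tr$x, rep(1, 120), va$x, va$y, cfg, tcf),
               "both classes")
})

test_that("checkpoints restore bit-identical forward outputs", {
  cfg <- classifier_config(12L, n_blocks = 1L, conv_channels = 3L)
  m <- build_model(cfg, seed = 5)
  m$zspace <- zspace(di = FALSE, tri = FALSE)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  set.seed(56)
  x <- matrix(rnorm(5 * 12), 5, 12)
  expect_identical(predict(back, x), predict(m, x))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(sidecar$input_dim, 12L)
})

test_that("glance and autoplot summarize a fitted model", {
  set.seed(57)
  x <- matrix(rnorm(60 * 12), 60, 12)
  y <- rep(c(1, 0), 30)
  x[y == 1, 1] <- x[y == 1, 1] + 2
  cfg <- classifier_config(12L, n_blocks = 1L, conv_channels = 3L,
                           mlp_hidden = 4L)
  m <- train_classifier(x[1:40, ], y[1:40], x[41:60, ], y[41:60], cfg,
                        train_config(max_epochs = 3L, seed = 1))
  g <- glance(m)
  expect_identical(nrow(g), 1L)
  expect_true(g$n_params > 0)
  expect_s3_class(autoplot(m), "ggplot")
})
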