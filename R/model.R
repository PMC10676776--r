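# The ORI classifier: stacked structure blocks (self-attention -> 1D
# convolution -> ELU -> average pooling -> up-sampling) followed by an MLP
# head with a sigmoid output. The Z-vector enters as a token sequence with
# one token per (family, phase, context) group and the three Z axes x/y/z as
# input channels, so every admissible input dimension D yields L = D/3 tokens.

ADMISSIBLE_DIMS <- c(12L, 48L, 60L, 192L, 204L, 240L, 252L)

#' Classifier architecture configuration
#'
#' @param input_dim Z-space dimension; one of 12, 48, 60, 192, 204, 240, 252.
#' @param n_blocks Number of stacked structure blocks (default 3).
#' @param conv_channels Channel width of convolution and attention value
#'   space (single attention head with `d_k = d_v = conv_channels`).
#' @param conv_kernel Odd convolution kernel width (default 3, same-padding).
#' @param pool_size Average-pooling width; the up-sampling factor equals it,
#'   so each block preserves the token-sequence length.
#' @param elu_alpha ELU negative-saturation scale (default 1).
#' @param mlp_hidden Hidden layer sizes of the MLP head (default c(64, 16)).
#' @param attention Include the self-attention layer in each block (set
#'   FALSE for the ablation variant).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(input_dim = 252L, n_blocks = 3L,
                              conv_channels = 8L, conv_kernel = 3L,
                              pool_size = 2L, elu_alpha = 1,
                              mlp_hidden = c(64L, 16L), attention = TRUE) {
  if (!(input_dim %in% ADMISSIBLE_DIMS)) {
    stop("`input_dim` must be one of ", paste(ADMISSIBLE_DIMS, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_blocks >= 1L, conv_channels >= 2L, conv_kernel %% 2L == 1L,
            pool_size >= 1L, elu_alpha > 0, all(mlp_hidden >= 1L))
  l <- input_dim %/% 3L
  if (l %% pool_size != 0L) {
    stop("token length ", l, " is not divisible by pool_size ", pool_size,
         call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim),
                 n_blocks = as.integer(n_blocks),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 upsample_factor = as.integer(pool_size),
                 elu_alpha = elu_alpha,
                 mlp_hidden = as.integer(mlp_hidden),
                 attention = isTRUE(attention)),
            class = "classifier_config")
}

#' Training configuration
#'
#' Defaults are the published optimization hyperparameters: Adam with
#' learning rate 0.0002 and batch size 64. Early stopping keeps the
#' parameters with the best validation loss.
#'
#' @param learning_rate Adam step size (default 0.0002).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Epoch budget (default 200).
#' @param patience Epochs without validation-loss improvement before
#'   stopping (default 10).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 64L,
                         max_epochs = 200L, patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

block_in_channels <- function(cfg, b) {
  if (b == 1L) 3L else cfg$conv_channels
}

#' Initialize classifier parameters
#'
#' Glorot-uniform initialization, reproducible from the seed. Parameters are
#' a flat named list of matrices/vectors (e.g. `b1.attn.Wq`, `b2.conv.W2`,
#' `mlp1.W`, `out.b`).
#'
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return Object of class `ori_model` with untrained parameters.
#' @export
build_model <- function(config = classifier_config(), seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  cc <- config$conv_channels
  l <- config$input_dim %/% 3L
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (b in seq_len(config$n_blocks)) {
      cin <- block_in_channels(config, b)
      if (config$attention) {
        p[[sprintf("b%d.attn.Wq", b)]] <- glorot(cin, cc)
        p[[sprintf("b%d.attn.Wk", b)]] <- glorot(cin, cc)
        p[[sprintf("b%d.attn.Wv", b)]] <- glorot(cin, cc)
        cin <- cc
      }
      for (j in seq_len(config$conv_kernel)) {
        p[[sprintf("b%d.conv.W%d", b, j)]] <-
          glorot(cin, cc, fan_in = cin * config$conv_kernel, fan_out = cc)
      }
      p[[sprintf("b%d.conv.b", b)]] <- numeric(cc)
    }
    sizes <- c(l * cc, config$mlp_hidden, 1L)
    for (h in seq_len(length(sizes) - 1L)) {
      nm <- if (h == length(sizes) - 1L) "out" else sprintf("mlp%d", h)
      p[[paste0(nm, ".W")]] <- glorot(sizes[h], sizes[h + 1L])
      p[[paste0(nm, ".b")]] <- numeric(sizes[h + 1L])
    }
    p
  })
  structure(list(params = params, config = config, history = NULL,
                 seed = as.integer(seed)),
            class = "ori_model")
}

#' @export
print.ori_model <- function(x, ...) {
  cfg <- x$config
  cat("<ori_model> ", cfg$n_blocks, " structure block(s)",
      if (cfg$attention) " with" else " without", " attention, input_dim = ",
      cfg$input_dim, ", channels = ", cfg$conv_channels, "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", nrow(x$history), " epoch(s); best epoch ",
        x$best_epoch, "\n", sep = "")
  }
  invisible(x)
}

# full forward pass; returns probabilities and (optionally) layer caches
model_forward <- function(params, x, cfg, keep_cache = FALSE) {
  n <- nrow(x)
  if (ncol(x) != cfg$input_dim) {
    stop("input has ", ncol(x), " columns but the model expects ",
         cfg$input_dim, call. = FALSE)
  }
  a <- tokens_from_features(x)
  caches <- if (keep_cache) vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    cb <- list()
    if (cfg$attention) {
      att <- attn_forward(a, params[[sprintf("b%d.attn.Wq", b)]],
                          params[[sprintf("b%d.attn.Wk", b)]],
                          params[[sprintf("b%d.attn.Wv", b)]])
      cb$attn <- if (keep_cache) att$cache
      a <- att$y
    }
    w <- lapply(seq_len(cfg$conv_kernel), function(j)
      params[[sprintf("b%d.conv.W%d", b, j)]])
    cv <- conv_forward(a, w, params[[sprintf("b%d.conv.b", b)]])
    z <- cv$y
    a <- elu(z, cfg$elu_alpha)
    if (keep_cache) {
      cb$conv <- cv$cache
      cb$elu_x <- z
      cb$elu_y <- a
    }
    a <- upsample_forward(pool_forward(a, cfg$pool_size), cfg$upsample_factor)
    if (keep_cache) caches[[b]] <- cb
  }
  h <- tensor_to_mat_flat(a)
  mlp_cache <- if (keep_cache) list()
  for (m in seq_along(cfg$mlp_hidden)) {
    zz <- dense_forward(h, params[[sprintf("mlp%d.W", m)]],
                        params[[sprintf("mlp%d.b", m)]])
    hh <- elu(zz, cfg$elu_alpha)
    if (keep_cache) mlp_cache[[m]] <- list(x = h, z = zz, y = hh)
    h <- hh
  }
  logit <- dense_forward(h, params[["out.W"]], params[["out.b"]])
  prob <- 1 / (1 + exp(-logit))
  list(prob = as.vector(prob),
       cache = if (keep_cache) list(blocks = caches, mlp = mlp_cache,
                                    mlp_in = h, n = n))
}

# (n, L, C) -> n x (L*C) matrix, column order (token, channel), token fastest
tensor_to_mat_flat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L], d[2L] * d[3L])
  a
}

dense_forward <- function(x, w, b) {
  y <- x %*% w
  y + rep(b, each = nrow(y))
}

# backward pass for mean BCE loss; returns flat gradient list matching params
model_backward <- function(params, cfg, fw, y) {
  n <- fw$cache$n
  grads <- list()
  # sigmoid + mean BCE
  dlogit <- matrix((fw$prob - y) / n, ncol = 1L)
  h <- fw$cache$mlp_in
  grads[["out.W"]] <- crossprod(h, dlogit)
  grads[["out.b"]] <- colSums(dlogit)
  dh <- tcrossprod(dlogit, params[["out.W"]])
  for (m in rev(seq_along(cfg$mlp_hidden))) {
    mc <- fw$cache$mlp[[m]]
    dz <- dh * elu_grad(mc$z, mc$y, cfg$elu_alpha)
    grads[[sprintf("mlp%d.W", m)]] <- crossprod(mc$x, dz)
    grads[[sprintf("mlp%d.b", m)]] <- colSums(dz)
    dh <- tcrossprod(dz, params[[sprintf("mlp%d.W", m)]])
  }
  l <- cfg$input_dim %/% 3L
  da <- array(dh, dim = c(n, l, cfg$conv_channels))
  for (b in rev(seq_len(cfg$n_blocks))) {
    cb <- fw$cache$blocks[[b]]
    da <- pool_backward(upsample_backward(da, cfg$upsample_factor),
                        cfg$pool_size)
    da <- da * elu_grad(cb$elu_x, cb$elu_y, cfg$elu_alpha)
    cv <- conv_backward(da, cb$conv)
    for (j in seq_len(cfg$conv_kernel)) {
      grads[[sprintf("b%d.conv.W%d", b, j)]] <- cv$dw[[j]]
    }
    grads[[sprintf("b%d.conv.b", b)]] <- cv$db
    da <- cv$dx
    if (cfg$attention) {
      at <- attn_backward(da, cb$attn)
      grads[[sprintf("b%d.attn.Wq", b)]] <- at$dwq
      grads[[sprintf("b%d.attn.Wk", b)]] <- at$dwk
      grads[[sprintf("b%d.attn.Wv", b)]] <- at$dwv
      da <- at$dx
    }
  }
  grads
}

#' Predict ORI probabilities
#'
#' @param object A trained or initialized `ori_model`.
#' @param newdata Numeric feature matrix (rows = sequences), an encoded
#'   tibble from [encode_sequences()], or a single numeric Z-vector.
#' @param batch_size Forward-pass chunk size (memory bound).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, in input row order.
#' @export
predict.ori_model <- function(object, newdata, batch_size = 256L, ...) {
  x <- as_feature_matrix(newdata, object$config$input_dim)
  n <- nrow(x)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  starts <- seq.int(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- model_forward(object$params, x[s:e, , drop = FALSE],
                              object$config)$prob
  }
  out
}

as_feature_matrix <- function(newdata, input_dim) {
  if (is.data.frame(newdata)) newdata <- z_matrix(newdata)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != input_dim) {
    stop("feature dimension ", ncol(newdata),
         " does not match model input_dim ", input_dim, call. = FALSE)
  }
  newdata
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

#' Train the classifier with Adam and early stopping
#'
#' Optimizes mean binary cross-entropy on minibatches; after each epoch the
#' validation loss is evaluated and the parameters with the best validation
#' loss are kept (early stopping after `patience` stagnant epochs). Fully
#' deterministic given the configs' seed.
#'
#' @param x_train,y_train Training feature matrix and 0/1 labels.
#' @param x_val,y_val Validation feature matrix and 0/1 labels.
#' @param cconfig A [classifier_config()] (its `input_dim` must match).
#' @param tconfig A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `ori_model` with a `history` tibble (epoch, train_loss,
#'   val_loss, val_auc) and `best_epoch`.
#' @export
train_classifier <- function(x_train, y_train, x_val, y_val,
                             cconfig = classifier_config(ncol(x_train)),
                             tconfig = train_config(), verbose = FALSE) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2L || length(unique(y_val)) < 2L) {
    stop("training and validation sets must both contain both classes",
         call. = FALSE)
  }
  model <- build_model(cconfig, seed = tconfig$seed)
  params <- model$params
  state <- adam_init(params)
  n <- nrow(x_train)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", tconfig$max_epochs)
  for (epoch in seq_len(tconfig$max_epochs)) {
    ord <- withr::with_seed(derive_seed(tconfig$seed, paste0("epoch", epoch)),
                            sample.int(n))
    starts <- seq.int(1L, n, by = tconfig$batch_size)
    tr_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + tconfig$batch_size - 1L, n)]
      xb <- x_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      fw <- model_forward(params, xb, cconfig, keep_cache = TRUE)
      tr_loss <- tr_loss + bce_loss(yb, fw$prob) * length(idx)
      grads <- model_backward(params, cconfig, fw, yb)
      upd <- adam_step(params, grads, state, tconfig$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    tr_loss <- tr_loss / n
    val_prob <- predict_with_params(params, x_val, cconfig)
    val_loss <- bce_loss(y_val, val_prob)
    val_auc <- auc(y_val, val_prob)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                    val_loss = val_loss, val_auc = val_auc)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  auc %.4f",
                      epoch, tr_loss, val_loss, val_auc))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tconfig$patience) break
    }
  }
  model$params <- best$params
  model$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model$train_config <- tconfig
  model
}

predict_with_params <- function(params, x, cfg, batch_size = 256L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq.int(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- model_forward(params, x[s:e, , drop = FALSE], cfg)$prob
  }
  out
}

#' Fit the ORI classifier straight from labelled sequences
#'
#' Convenience wrapper: encodes the sequences into the requested Z-space,
#' makes a stratified 90/10 train/validation split (seeded), and trains.
#'
#' @param data Labelled sequence tibble (`id`, `seq`, `label`).
#' @param zconfig A [zspace()] configuration.
#' @param cconfig,tconfig Model and training configurations; `cconfig`
#'   defaults to the dimension implied by `zconfig`.
#' @param val_fraction Fraction held out for validation (default 0.1).
#' @param ... Passed to [train_classifier()].
#' @return A trained `ori_model` carrying the `zspace` used for encoding.
#' @export
fit_ori_classifier <- function(data, zconfig = zspace(),
                               cconfig = classifier_config(zspace_dim(zconfig)),
                               tconfig = train_config(),
                               val_fraction = 0.1, ...) {
  enc <- encode_sequences(data, zconfig)
  x <- z_matrix(enc)
  y <- data$label
  idx_val <- stratified_holdout(y, val_fraction,
                                derive_seed(tconfig$seed, "valsplit"))
  model <- train_classifier(x[-idx_val, , drop = FALSE], y[-idx_val],
                            x[idx_val, , drop = FALSE], y[idx_val],
                            cconfig, tconfig, ...)
  model$zspace <- zconfig
  model
}

# stratified sample of indices for a holdout set (at least one per class)
stratified_holdout <- function(y, fraction, seed) {
  withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(length(idx) * fraction)))
    }), use.names = FALSE)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted classifier
#' @param x An `ori_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @export
tidy.ori_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric(), val_auc = numeric())
}

#' One-row summary of a fitted classifier
#' @param x An `ori_model`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, best epoch, best val loss/AUC.
#' @export
glance.ori_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    n_epochs = nrow(h),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_loss = if (nrow(h)) h$val_loss[h$epoch == x$best_epoch] else NA_real_,
    val_auc = if (nrow(h)) h$val_auc[h$epoch == x$best_epoch] else NA_real_,
    n_params = sum(vapply(x$params, length, integer(1)))
  )
}

#' Plot the training history
#' @param object An `ori_model`.
#' @param ... Unused.
#' @return A ggplot object (train/validation loss per epoch).
#' @export
autoplot.ori_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h[c("epoch", "train_loss", "val_loss")],
                              -"epoch", names_to = "series",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file; a plain-text JSON sidecar
#' (`<path>.json`) records the architecture for inspection. Loading restores
#' bit-identical forward outputs.
#'
#' @param model An `ori_model`.
#' @param path Checkpoint path (e.g. `model.ckpt`).
#' @return `path` (save) or the restored `ori_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ori_model"))
  saveRDS(model, path)
  sidecar <- model$config
  class(sidecar) <- NULL
  if (!is.null(model$zspace)) {
    sidecar$zspace <- unclass(model$zspace)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ori_model"))
  model
}
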