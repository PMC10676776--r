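# Benchmark-scale fixtures shared by the acceptance tests. The classifier is
# trained once per test run and memoized, since several criteria probe the
# same fitted model.

.bench_cache <- new.env(parent = emptyenv())

bench_spec <- function() fixture_spec(seed = 101L)  # 1250 + 1250, defaults

bench_tconfig <- function(seed = 7L, max_epochs = 30L) {
  train_config(max_epochs = max_epochs, patience = 10L, seed = seed)
}

# labelled dataset + encodings + fixed stratified 2000/500 split
bench_data <- function() {
  if (is.null(.bench_cache$data)) {
    data <- make_labeled_dataset(bench_spec())
    enc <- encode_sequences(data, zspace())
    x <- z_matrix(enc)
    y <- as.numeric(data$label)
    val <- oriforge:::stratified_holdout(y, 0.2,
                                         oriforge:::derive_seed(101L, "val"))
    .bench_cache$data <- list(data = data, x = x, y = y, val = val)
  }
  .bench_cache$data
}

# the attention model trained on the 2000/500 split (memoized)
bench_model <- function() {
  if (is.null(.bench_cache$model)) {
    d <- bench_data()
    m <- train_classifier(d$x[-d$val, , drop = FALSE], d$y[-d$val],
                          d$x[d$val, , drop = FALSE], d$y[d$val],
                          classifier_config(252L), bench_tconfig())
    m$zspace <- zspace()
    .bench_cache$model <- m
  }
  .bench_cache$model
}
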