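# Independent brute-force oracles used to pin the fast implementations.
# They share no code with the package internals: plain substring scans.

# count of one exact word among overlapping windows
oracle_count_word <- function(seq, word) {
  k <- nchar(word)
  n <- nchar(seq)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(seq, i, i + k - 1L) == word, logical(1)))
}

# phase subsequence by explicit position scan (1-based, every third base)
oracle_phase <- function(seq, i) {
  n <- nchar(seq)
  if (i > n) return("")
  paste(vapply(seq.int(i, n, by = 3L), function(p) substr(seq, p, p),
               character(1)), collapse = "")
}

# Z transform of a (sub)sequence for word length k, phase-free, by direct
# application of the x/y/z base-class contrasts to every (k-1)-context
oracle_z_block <- function(seq, k, normalize) {
  bases <- c("A", "C", "G", "T")
  contexts <- if (k == 1L) "" else {
    out <- bases
    if (k >= 3L) for (i in seq_len(k - 2L)) {
      out <- as.vector(outer(out, bases, paste0))
    }
    sort(out)
  }
  windows <- max(0L, nchar(seq) - k + 1L)
  unlist(lapply(contexts, function(cx) {
    f <- vapply(bases, function(b) oracle_count_word(seq, paste0(cx, b)),
                numeric(1))
    v <- c(x = (f[["A"]] + f[["G"]]) - (f[["C"]] + f[["T"]]),
           y = (f[["A"]] + f[["C"]]) - (f[["G"]] + f[["T"]]),
           z = (f[["A"]] + f[["T"]]) - (f[["G"]] + f[["C"]]))
    if (normalize && windows > 0L) v / windows else if (normalize) v * 0 else v
  }), use.names = FALSE)
}

# full encoding oracle: mono -> di -> tri, phase-free block then phases 1..3
oracle_encode <- function(seq, mono = TRUE, di = TRUE, tri = TRUE,
                          normalize = TRUE) {
  subs <- c(list(seq), lapply(1:3, function(i) oracle_phase(seq, i)))
  unlist(lapply(which(c(mono, di, tri)), function(k) {
    unlist(lapply(subs, oracle_z_block, k = k, normalize = normalize))
  }), use.names = FALSE)
}

# all-pairs AUC oracle with half-credit ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# confusion-matrix oracles
oracle_confusion <- function(labels, scores, threshold = 0.5) {
  pred <- ifelse(scores >= threshold, 1, 0)
  c(tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

oracle_accuracy <- function(labels, scores, threshold = 0.5) {
  cm <- oracle_confusion(labels, scores, threshold)
  (cm[["tp"]] + cm[["tn"]]) / length(labels)
}

oracle_mcc <- function(labels, scores, threshold = 0.5) {
  cm <- as.list(oracle_confusion(labels, scores, threshold))
  den <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  if (den == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(den)
}

random_dna <- function(n, min_len = 30L, max_len = 300L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample.int(max_len - min_len + 1L, 1L) + min_len - 1L,
                 replace = TRUE), collapse = "")
  }, character(1))
}

complement_seq <- function(seq) {
  chartr("ACGT", "TGCA", seq)
}
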