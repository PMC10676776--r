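# GC-content statistics with decile binning and cosine-similarity comparison
# of Z-encoded sequence sets.

#' GC content of sequences
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of (G + C) / length fractions.
#' @export
gc_content <- function(seq) {
  if (length(seq) == 0L) stop("empty input", call. = FALSE)
  n <- nchar(seq)
  if (any(n == 0L)) stop("empty sequence", call. = FALSE)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

#' Decile histogram of GC content
#'
#' Bin `Li` covers GC fractions in `(0.1 * (i - 1), 0.1 * i]` (right-closed);
#' a GC content of exactly 0 is assigned to `L1`.
#'
#' @param data Sequence tibble (`id`, `seq`) or character vector.
#' @return Object of class `gc_histogram`: a tibble with columns `bin`
#'   (`L1`..`L10`), `lower`, `upper`, `count`.
#' @export
gc_histogram <- function(data) {
  data <- as_sequence_tbl(data)
  if (nrow(data) == 0L) stop("empty sequence set", call. = FALSE)
  gc <- gc_content(data$seq)
  idx <- pmax(1L, ceiling(gc * 10 - 1e-9))  # right-closed deciles, 0 -> L1
  idx <- pmin(idx, 10L)
  structure(
    tibble::tibble(bin = paste0("L", 1:10),
                   lower = (0:9) / 10, upper = (1:10) / 10,
                   count = tabulate(idx, nbins = 10L)),
    class = c("gc_histogram", "tbl_df", "tbl", "data.frame"),
    n_total = length(gc)
  )
}

#' Plot a GC decile histogram
#' @param object A [gc_histogram()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.gc_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bin <- factor(df$bin, levels = paste0("L", 1:10))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "GC-content decile", y = "sequences") +
    ggplot2::theme_minimal()
}

#' Cosine similarity of two vectors
#'
#' `u . v / (|u| |v|)`, in `[-1, 1]`; 1 means parallel, 0 unrelated, -1
#' opposite. (Often loosely called "cosine distance" in the field; this
#' implementation uses the similarity orientation.)
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("zero vector has no direction", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Mean pairwise cosine similarity between encoded sequence sets
#'
#' Entry (a, b) is the mean cosine similarity over all cross pairs; diagonal
#' entries average over all unordered distinct pairs within the set.
#' `method = "centroid"` compares set centroids instead.
#'
#' @param sets Named list of numeric matrices (rows = Z-vectors, equal
#'   dimension), e.g. `z_matrix()` outputs.
#' @param method `"pairwise"` (default) or `"centroid"`.
#' @return Object of class `set_similarity`: a symmetric labelled matrix.
#' @export
mean_set_similarity <- function(sets, method = c("pairwise", "centroid")) {
  method <- match.arg(method)
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, as.matrix)
  dims <- vapply(sets, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all sets must share one vector dimension", call. = FALSE)
  }
  norm_rows <- function(m) {
    nr <- sqrt(rowSums(m * m))
    if (any(nr == 0)) stop("zero vector has no direction", call. = FALSE)
    m / nr
  }
  k <- length(sets)
  out <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  if (method == "centroid") {
    cents <- do.call(rbind, lapply(sets, colMeans))
    cents <- norm_rows(cents)
    out <- tcrossprod(cents)
  } else {
    normed <- lapply(sets, norm_rows)
    for (a in seq_len(k)) for (b in a:k) {
      g <- tcrossprod(normed[[a]], normed[[b]])
      val <- if (a == b) {
        if (nrow(g) < 2L) {
          stop("set ", names(sets)[a],
               " needs >= 2 vectors for a within-set mean", call. = FALSE)
        }
        mean(g[upper.tri(g)])
      } else {
        mean(g)
      }
      out[a, b] <- out[b, a] <- val
    }
  }
  structure(out, class = c("set_similarity", "matrix", "array"),
            method = method)
}

#' Long-format set-similarity entries
#' @param x A [mean_set_similarity()] result.
#' @param ... Unused.
#' @return Tibble with columns `set_a`, `set_b`, `similarity`.
#' @export
tidy.set_similarity <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(set_a = rep(rownames(m), times = ncol(m)),
                 set_b = rep(colnames(m), each = nrow(m)),
                 similarity = as.vector(m))
}

#' Heatmap of a set-similarity matrix
#' @param object A [mean_set_similarity()] result.
#' @param ... Unused.
#' @return A ggplot tile plot.
#' @export
autoplot.set_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$set_a, .data$set_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data$similarity)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' 2D embedding of encoded sequences (LLE or t-SNE)
#'
#' Thin wrapper for visualization only: delegates to the scikit-learn
#' implementations through the `python` interpreter on the PATH (the
#' manifold algorithms themselves are out of scope here).
#'
#' @param x Numeric matrix (n >= 10 rows) of Z-vectors.
#' @param method `"lle"` or `"tsne"`.
#' @param seed Integer seed passed to the backend.
#' @param n_neighbors LLE neighbourhood size / t-SNE perplexity driver.
#' @return An n x 2 coordinate matrix.
#' @export
embed_2d <- function(x, method = c("lle", "tsne"), seed = 1L,
                     n_neighbors = 10L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("need at least 10 vectors", call. = FALSE)
  python <- Sys.which("python")
  if (python == "") stop("no `python` interpreter on the PATH", call. = FALSE)
  infile <- tempfile(fileext = ".csv"); outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  utils::write.table(x, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- system.file("python", "embed2d.py", package = "oriforge")
  status <- system2(python, c(script, method, infile, outfile,
                              as.integer(seed), as.integer(n_neighbors)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("embedding backend failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  coords <- as.matrix(utils::read.table(outfile, sep = ","))
  dimnames(coords) <- list(rownames(x), c("dim1", "dim2"))
  coords
}
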