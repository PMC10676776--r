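#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

# Integer codes: A=0, C=1, G=2, T=3 (lexicographic, used for k-mer indexing).
BASES <- c("A", "C", "G", "T")

# lookup table from UTF-8 code point to base code (NA for anything else)
.base_code <- local({
  tbl <- rep(NA_integer_, 128L)
  tbl[utf8ToInt("A")] <- 0L
  tbl[utf8ToInt("C")] <- 1L
  tbl[utf8ToInt("G")] <- 2L
  tbl[utf8ToInt("T")] <- 3L
  tbl
})

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and checks that every character is one of A, C, G, T.
#' Ambiguity codes (N and the other IUPAC symbols) have no defined Z-curve
#' coordinates and are rejected.
#'
#' @param seq A single character string over the DNA alphabet.
#' @param id Identifier used in error messages.
#' @return The uppercased sequence string.
#' @export
validate_dna <- function(seq, id = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single non-NA character string (", id, ")",
         call. = FALSE)
  }
  seq <- toupper(seq)
  if (nchar(seq) < 1L) {
    stop("empty sequence: ", id, call. = FALSE)
  }
  codes <- .base_code[utf8ToInt(seq)]
  if (anyNA(codes)) {
    bad <- unique(strsplit(seq, "", fixed = TRUE)[[1]][is.na(codes)])
    stop("sequence ", id, " contains non-ACGT characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}

# integer base codes for a validated sequence
seq_codes <- function(seq) {
  .base_code[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L], multiple = FALSE)
}

#' Split a sequence into its three phase subsequences
#'
#' Phase i (i = 1, 2, 3) collects the bases at 1-based positions i, i+3,
#' i+6, ... so that composition can be measured per codon-like reading phase.
#'
#' @param seq DNA sequence string (ACGT).
#' @return A list with elements `s0` (the input), `s1`, `s2`, `s3`.
#' @examples
#' phase_decompose("ACGTACGTA")
#' @export
phase_decompose <- function(seq) {
  seq <- validate_dna(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sub <- function(i) {
    if (i > n) return("")
    paste(chars[seq.int(i, n, by = 3L)], collapse = "")
  }
  list(s0 = seq, s1 = sub(1L), s2 = sub(2L), s3 = sub(3L))
}

#' Count overlapping k-mers
#'
#' @param seq DNA sequence string.
#' @param k Word length, one of 1, 2, 3.
#' @return Named integer vector of length `4^k` (lexicographic k-mer order).
#'   Counts sum to `max(0, nchar(seq) - k + 1)`.
#' @export
count_kmers <- function(seq, k) {
  if (!(length(k) == 1L && k %in% 1:3)) {
    stop("`k` must be 1, 2 or 3", call. = FALSE)
  }
  seq <- validate_dna(seq)
  counts <- kmer_counts_codes(seq_codes(seq), as.integer(k))
  names(counts) <- kmer_names(k)
  counts
}

kmer_names <- function(k) {
  out <- BASES
  if (k >= 2L) for (i in seq_len(k - 1L)) {
    out <- as.vector(t(outer(out, BASES, paste0)))
  }
  sort(out)
}

# counts from integer codes; zero vector when the sequence is shorter than k
kmer_counts_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(4L^k))
  idx <- codes[seq_len(n - k + 1L)]
  if (k >= 2L) for (j in 2:k) {
    idx <- idx * 4L + codes[j:(n - k + j)]
  }
  tabulate(idx + 1L, nbins = 4L^k)
}

# Z transform of a 4^k count vector: for each (k-1)-context emit
#   x = (cA + cG) - (cC + cT)
#   y = (cA + cC) - (cG + cT)
#   z = (cA + cT) - (cG + cC)
# context-major, axes x, y, z within each context.
z_from_counts <- function(counts, k, n_windows, normalize) {
  m <- matrix(counts, nrow = 4L)  # rows: final base A,C,G,T; cols: contexts
  x <- (m[1L, ] + m[3L, ]) - (m[2L, ] + m[4L, ])
  y <- (m[1L, ] + m[2L, ]) - (m[3L, ] + m[4L, ])
  z <- (m[1L, ] + m[4L, ]) - (m[3L, ] + m[2L, ])
  v <- as.numeric(rbind(x, y, z))
  if (normalize) {
    if (n_windows > 0L) v <- v / n_windows else v[] <- 0
  }
  v
}

#' Phase-free mononucleotide Z-curve coordinates
#'
#' Computes x = (A+G)-(C+T), y = (A+C)-(G+T), z = (A+T)-(G+C) over the whole
#' sequence; with `normalize = TRUE` the counts are divided by the sequence
#' length, so each coordinate lies in \[-1, 1\].
#'
#' @param seq DNA sequence string.
#' @param normalize Divide by the number of counted windows (default TRUE).
#' @return Named numeric vector `c(x, y, z)`.
#' @export
mono_z <- function(seq, normalize = TRUE) {
  seq <- validate_dna(seq)
  codes <- seq_codes(seq)
  v <- z_from_counts(kmer_counts_codes(codes, 1L), 1L, length(codes), normalize)
  names(v) <- c("x", "y", "z")
  v
}

#' Phase-free k-mer Z-curve parameters
#'
#' Generalizes the mononucleotide Z transform to di- and trinucleotides: for
#' every context `c` of length k-1 the three axes contrast the frequency of
#' `c` followed by each base class. Returns 12 components for k = 2 and 48
#' for k = 3.
#'
#' @param seq DNA sequence string.
#' @param k 2 or 3.
#' @param normalize Divide by the number of k-mer windows (default TRUE).
#' @return Named numeric vector, context-major with axes x, y, z.
#' @export
kmer_z <- function(seq, k, normalize = TRUE) {
  if (!(length(k) == 1L && k %in% 2:3)) {
    stop("`k` must be 2 or 3", call. = FALSE)
  }
  seq <- validate_dna(seq)
  codes <- seq_codes(seq)
  n_windows <- length(codes) - k + 1L
  if (n_windows < 1L) {
    warning("sequence shorter than k = ", k, "; returning all-zero vector")
    n_windows <- 0L
  }
  v <- z_from_counts(kmer_counts_codes(codes, as.integer(k)), k,
                     n_windows, normalize)
  names(v) <- z_block_names(k)
  v
}

# component names for one phase-free block of the k family: <context>.<axis>
z_block_names <- function(k) {
  if (k == 1L) return(c("x", "y", "z"))
  contexts <- kmer_names(k - 1L)
  paste(rep(contexts, each = 3L), c("x", "y", "z"), sep = ".")
}

#' Z-space configuration
#'
#' Selects which k-mer parameter families are active. Mononucleotides
#' contribute 12 dimensions (3 phase-free + 3 x 3 phase-specific),
#' dinucleotides 48, trinucleotides 192; active contributions are summed,
#' yielding the seven admissible dimensions 12, 48, 60, 192, 204, 240, 252.
#'
#' @param mono,di,tri Logical flags; at least one must be TRUE.
#' @param normalize Divide counts by the number of counted windows per
#'   (subsequence, k), giving length-invariant components in \[-1, 1\].
#' @return An object of class `zspace_config`.
#' @examples
#' zspace_dim(zspace())            # 252
#' zspace_dim(zspace(di = FALSE, tri = FALSE))  # 12
#' @export
zspace <- function(mono = TRUE, di = TRUE, tri = TRUE, normalize = TRUE) {
  stopifnot(is.logical(mono), is.logical(di), is.logical(tri),
            is.logical(normalize))
  if (!(mono || di || tri)) {
    stop("at least one of `mono`, `di`, `tri` must be TRUE", call. = FALSE)
  }
  structure(list(mono = mono, di = di, tri = tri, normalize = normalize),
            class = "zspace_config")
}

#' @export
print.zspace_config <- function(x, ...) {
  fams <- c("mono", "di", "tri")[c(x$mono, x$di, x$tri)]
  cat("<zspace_config> families:", paste(fams, collapse = "+"),
      "| dimension:", zspace_dim(x),
      "| normalize:", x$normalize, "\n")
  invisible(x)
}

#' Dimension of a Z-space configuration
#' @param config A [zspace()] object.
#' @return Integer vector length 1.
#' @export
zspace_dim <- function(config) {
  stopifnot(inherits(config, "zspace_config"))
  sum(c(12L, 48L, 192L)[c(config$mono, config$di, config$tri)])
}

active_ks <- function(config) {
  which(c(config$mono, config$di, config$tri))
}

#' Component names of a Z-space configuration
#'
#' Ordering is frozen for reproducibility: families mono, di, tri; within a
#' family the phase-free block (`s0`) then phases `s1`, `s2`, `s3`; within a
#' block contexts in lexicographic order with axes x, y, z.
#'
#' @inheritParams zspace_dim
#' @return Character vector of length `zspace_dim(config)` such as
#'   `"mono.s0.x"` or `"tri.s2.GC.y"`.
#' @export
zspace_component_names <- function(config) {
  stopifnot(inherits(config, "zspace_config"))
  fam <- c("mono", "di", "tri")
  unlist(lapply(active_ks(config), function(k) {
    block <- z_block_names(k)
    as.vector(vapply(paste0("s", 0:3), function(s)
      paste(fam[k], s, block, sep = "."), character(length(block))))
  }), use.names = FALSE)
}

# minimum sequence length so that every phase subsequence admits >= 1 window
# for the largest active k: |seq| >= 3 * k_max
zspace_min_length <- function(config) {
  3L * max(active_ks(config))
}

#' Encode one DNA sequence into the Z-space
#'
#' Concatenates, per active k-mer family, the phase-free Z parameters of the
#' full sequence and the phase-specific parameters of the three phase
#' subsequences. The result has the same dimension for sequences of any
#' length (>= `3 * k_max`, so every phase subsequence admits at least one
#' window of the largest active k).
#'
#' @param seq DNA sequence string.
#' @param config A [zspace()] configuration.
#' @param id Identifier used in error messages.
#' @return Named numeric vector of length `zspace_dim(config)`.
#' @export
encode_zcurve <- function(seq, config = zspace(), id = "sequence") {
  stopifnot(inherits(config, "zspace_config"))
  seq <- validate_dna(seq, id = id)
  codes <- seq_codes(seq)
  n <- length(codes)
  kmax <- max(active_ks(config))
  if (n < 3L * kmax) {
    fam <- c("mononucleotide", "dinucleotide", "trinucleotide")[kmax]
    stop("sequence ", id, " (length ", n, ") is too short for the active ",
         fam, " family: need at least ", 3L * kmax, " bp", call. = FALSE)
  }
  phases <- list(codes,
                 codes[seq.int(1L, n, by = 3L)],
                 codes[seq.int(2L, n, by = 3L)],
                 codes[seq.int(3L, n, by = 3L)])
  out <- unlist(lapply(active_ks(config), function(k) {
    unlist(lapply(phases, function(p) {
      w <- length(p) - k + 1L
      z_from_counts(kmer_counts_codes(p, k), k, max(w, 0L), config$normalize)
    }), use.names = FALSE)
  }), use.names = FALSE)
  names(out) <- zspace_component_names(config)
  out
}

#' Encode a batch of sequences into a Z-space feature table
#'
#' @param data A data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()] or the fixture generators); extra columns are preserved.
#' @param config A [zspace()] configuration.
#' @return A tibble with the input's `id` column (and any `label` column)
#'   followed by one numeric column per Z-space component, one row per
#'   sequence in input order.
#' @export
encode_sequences <- function(data, config = zspace()) {
  data <- as_sequence_tbl(data)
  nm <- zspace_component_names(config)
  if (nrow(data) == 0L) {
    mat <- matrix(numeric(0), nrow = 0L, ncol = length(nm),
                  dimnames = list(NULL, nm))
  } else {
    rows <- lapply(seq_len(nrow(data)), function(i) {
      tryCatch(
        encode_zcurve(data$seq[i], config, id = data$id[i]),
        error = function(e) stop("failed to encode sequence '", data$id[i],
                                 "': ", conditionMessage(e), call. = FALSE)
      )
    })
    mat <- do.call(rbind, rows)
  }
  keep <- intersect(c("id", "label", "line"), names(data))
  dplyr::bind_cols(data[keep], tibble::as_tibble(as.data.frame(mat)))
}

#' Extract the numeric feature matrix from an encoded table
#'
#' @param encoded Output of [encode_sequences()].
#' @return Numeric matrix (rows = sequences) with the id column as rownames.
#' @export
z_matrix <- function(encoded) {
  meta <- intersect(c("id", "label", "line"), names(encoded))
  m <- as.matrix(encoded[setdiff(names(encoded), meta)])
  if ("id" %in% names(encoded)) rownames(m) <- encoded$id
  m
}

# coerce to the canonical sequence tibble (columns id, seq)
as_sequence_tbl <- function(data) {
  if (is.character(data)) {
    data <- tibble::tibble(
      id = if (is.null(names(data))) paste0("seq", seq_along(data))
           else names(data),
      seq = unname(data)
    )
  }
  data <- tibble::as_tibble(data)
  if (!all(c("id", "seq") %in% names(data))) {
    stop("`data` must have columns `id` and `seq`", call. = FALSE)
  }
  data
}

#' Write an encoded feature table to a TSV file
#'
#' One row per sequence: the id column, then the ordered Z-space components
#' with a header naming each component (e.g. `mono.s0.x`, `tri.s2.GC.y`).
#'
#' @param encoded Output of [encode_sequences()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_encoding_tsv <- function(encoded, path) {
  utils::write.table(encoded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
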