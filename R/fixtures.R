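# Synthetic labelled sequence sets emulating the statistical structure of the
# ORI benchmark: positives concentrated at 50-60% GC with planted GC-rich
# motifs, negatives either uniform-random (GC ~ 50%) or genome-like with AT
# bias (GC centred near 40%, per-sequence spread ~ +/-0.10).

# derive a reproducible 31-bit sub-seed from a master seed and a label
derive_seed <- function(seed, salt) {
  codes <- utf8ToInt(as.character(salt))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

random_length <- function(n, length_range) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) +
    length_range[1] - 1L
}

#' Generate uniform-random DNA sequences
#'
#' Bases are i.i.d. uniform over A, C, G, T, so GC content concentrates near
#' 50% (the computer-random comparison set of the GC analyses).
#'
#' @param n Number of sequences.
#' @param length_range Integer interval of sequence lengths (inclusive).
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return A tibble with columns `id`, `seq`.
#' @export
gen_uniform_random <- function(n, length_range = c(300L, 3000L), seed = 1L,
                               prefix = "rand") {
  stopifnot(n >= 0)
  withr::with_seed(seed, {
    lens <- random_length(n, length_range)
    seqs <- vapply(lens, function(L)
      codes_to_seq(sample.int(4L, L, replace = TRUE) - 1L), character(1))
  })
  tibble::tibble(id = sprintf("%s_%04d", prefix, seq_len(n))[seq_len(n)],
                 seq = seqs)
}

# i.i.d. bases with P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2
random_seq_gc <- function(L, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes_to_seq(sample.int(4L, L, replace = TRUE, prob = p) - 1L)
}

#' Generate genome-like AT-biased sequences
#'
#' Emulates fragments intercepted from a mammalian genome: each sequence
#' draws its own GC level from a beta distribution with the requested mean
#' (spread roughly +/- 0.10), then bases are i.i.d. given that GC.
#'
#' @inheritParams gen_uniform_random
#' @param gc_mean Mean per-sequence GC fraction (default 0.40).
#' @param concentration Beta concentration; 80 gives an SD of about 0.055.
#' @return A tibble with columns `id`, `seq`.
#' @export
gen_genome_like <- function(n, length_range = c(300L, 3000L), gc_mean = 0.40,
                            seed = 1L, concentration = 80,
                            prefix = "genome") {
  stopifnot(n >= 0, gc_mean > 0, gc_mean < 1)
  withr::with_seed(seed, {
    lens <- random_length(n, length_range)
    gcs <- stats::rbeta(n, gc_mean * concentration,
                        (1 - gc_mean) * concentration)
    seqs <- vapply(seq_len(n), function(i)
      random_seq_gc(lens[i], gcs[i]), character(1))
  })
  tibble::tibble(id = sprintf("%s_%04d", prefix, seq_len(n))[seq_len(n)],
                 seq = seqs)
}

#' Generate ORI-like sequences (GC band + planted GC-rich motifs)
#'
#' Each sequence receives a GC target drawn uniformly from `gc_range`; the
#' background base composition is chosen so the whole sequence (motif copies
#' included) hits that target exactly up to rounding. `motif_copies`
#' non-overlapping copies of `motif` are planted at random positions.
#'
#' @inheritParams gen_uniform_random
#' @param gc_range GC fraction interval of the positives (default 0.50-0.60).
#' @param motif GC-rich motif string planted in every sequence.
#' @param motif_copies Number of non-overlapping copies per sequence.
#' @return A tibble with columns `id`, `seq`.
#' @export
gen_ori_like <- function(n, length_range = c(300L, 3000L),
                         gc_range = c(0.50, 0.60), motif = "GGGCGGGGC",
                         motif_copies = 3L, seed = 1L, prefix = "ori") {
  stopifnot(n >= 0, gc_range[1] <= gc_range[2],
            gc_range[1] > 0, gc_range[2] < 1)
  motif <- validate_dna(motif, id = "motif")
  mlen <- nchar(motif)
  if (mlen * motif_copies > length_range[1]) {
    stop("motif copies do not fit in the minimum sequence length",
         call. = FALSE)
  }
  motif_codes <- seq_codes(motif)
  motif_gc <- sum(motif_codes == 1L | motif_codes == 2L)
  withr::with_seed(seed, {
    lens <- random_length(n, length_range)
    targets <- stats::runif(n, gc_range[1], gc_range[2])
    seqs <- vapply(seq_len(n), function(i) {
      L <- lens[i]
      bg <- L - mlen * motif_copies
      # background S/W counts chosen so total GC hits the target exactly
      n_gc <- round(targets[i] * L - motif_gc * motif_copies)
      n_gc <- min(max(n_gc, 0L), bg)
      codes <- integer(bg)
      strong <- sample.int(bg, n_gc)
      weak <- setdiff(seq_len(bg), strong)
      codes[strong] <- sample(c(1L, 2L), n_gc, replace = TRUE)
      codes[weak] <- sample(c(0L, 3L), length(weak), replace = TRUE)
      plant_motifs(codes, motif_codes, motif_copies)
    }, character(1))
  })
  tibble::tibble(id = sprintf("%s_%04d", prefix, seq_len(n))[seq_len(n)],
                 seq = seqs)
}

# insert `copies` non-overlapping motif occurrences into a background code
# vector; insertion positions are sampled among the (copies+background gaps)
plant_motifs <- function(bg_codes, motif_codes, copies) {
  if (copies == 0L) return(codes_to_seq(bg_codes))
  # choose `copies` distinct slots among bg-length+1 gaps; inserting whole
  # motifs at distinct gaps can never overlap
  gaps <- sort(sample.int(length(bg_codes) + 1L, copies)) - 1L
  pieces <- vector("list", 2L * copies + 1L)
  prev <- 0L
  for (j in seq_len(copies)) {
    pieces[[2L * j - 1L]] <- bg_codes[seq_len(gaps[j] - prev) + prev]
    pieces[[2L * j]] <- motif_codes
    prev <- gaps[j]
  }
  pieces[[2L * copies + 1L]] <-
    if (prev < length(bg_codes)) bg_codes[(prev + 1L):length(bg_codes)]
    else integer(0)
  codes_to_seq(unlist(pieces))
}

#' Specification for a synthetic labelled benchmark
#'
#' Defaults mirror the GC structure reported for the real benchmark:
#' positives in the 50-60% GC band carrying GC-rich motifs, negatives
#' genome-like with mean GC 0.40 (or uniform-random), lengths 300-3000 bp.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Sequence length interval.
#' @param pos_gc_range GC band of the positives.
#' @param neg_mode `"genome"` (AT-biased, default) or `"uniform"`.
#' @param neg_gc_mean Mean GC of genome-like negatives.
#' @param motif,motif_copies Planted motif and copies per positive.
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pos = 1250L, n_neg = 1250L,
                         length_range = c(300L, 3000L),
                         pos_gc_range = c(0.50, 0.60),
                         neg_mode = c("genome", "uniform"),
                         neg_gc_mean = 0.40, motif = "GGGCGGGGC",
                         motif_copies = 3L, seed = 1L) {
  neg_mode <- match.arg(neg_mode)
  stopifnot(n_pos >= 0, n_neg >= 0)
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 pos_gc_range = pos_gc_range, neg_mode = neg_mode,
                 neg_gc_mean = neg_gc_mean, motif = motif,
                 motif_copies = motif_copies, seed = seed),
            class = "fixture_spec")
}

#' Generate a labelled synthetic dataset
#'
#' Positives (label 1) come from [gen_ori_like()], negatives (label 0) from
#' [gen_genome_like()] or [gen_uniform_random()] depending on the spec; the
#' combined table is shuffled with the spec seed. The spec is attached as the
#' `"provenance"` attribute for reproducibility.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble with columns `id`, `seq`, `label`.
#' @export
make_labeled_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  pos <- gen_ori_like(spec$n_pos, spec$length_range, spec$pos_gc_range,
                      spec$motif, spec$motif_copies,
                      seed = derive_seed(spec$seed, "pos"), prefix = "pos")
  neg <- if (spec$neg_mode == "genome") {
    gen_genome_like(spec$n_neg, spec$length_range, spec$neg_gc_mean,
                    seed = derive_seed(spec$seed, "neg"), prefix = "neg")
  } else {
    gen_uniform_random(spec$n_neg, spec$length_range,
                       seed = derive_seed(spec$seed, "neg"), prefix = "neg")
  }
  out <- dplyr::bind_rows(dplyr::mutate(pos, label = 1L),
                          dplyr::mutate(neg, label = 0L))
  out <- withr::with_seed(derive_seed(spec$seed, "shuffle"),
                          out[sample.int(nrow(out)), ])
  attr(out, "provenance") <- spec
  out
}

#' Generate pseudo-cell-line datasets from one shared distribution
#'
#' Draws `n_lines` independent labelled datasets from the same fixture
#' distribution (independent sub-seeds). Because the lines share one
#' generating process, any attempt to classify sequences by line should
#' score near chance, mirroring the negative multi-cell-line result.
#'
#' @param spec A [fixture_spec()] (its seed is the master seed).
#' @param n_lines Number of pseudo-cell-lines.
#' @return Named list of labelled tibbles (`line1`, `line2`, ...).
#' @export
pseudo_cell_lines <- function(spec = fixture_spec(), n_lines = 3L) {
  stopifnot(n_lines >= 2L)
  out <- lapply(seq_len(n_lines), function(i) {
    s <- spec
    s$seed <- derive_seed(spec$seed, paste0("line", i))
    make_labeled_dataset(s)
  })
  stats::setNames(out, paste0("line", seq_len(n_lines)))
}
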