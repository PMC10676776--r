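#' Read a FASTA file into a sequence table
#'
#' Multi-record FASTA with wrapped lines and mixed case is supported;
#' sequences are uppercased. Header text after the first whitespace is parsed
#' for `key=value` annotations (e.g. the `fitness=` values written by the
#' sequence designer), which become extra numeric/character columns.
#'
#' @param path Path to a FASTA file.
#' @param drop_invalid Drop (with a warning) records containing non-ACGT
#'   characters instead of erroring. Ambiguous bases have no defined Z-curve
#'   coordinates, so they are never silently kept.
#' @return A tibble with columns `id`, `seq` plus any annotation columns.
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  ok <- !grepl("[^ACGT]", seqs)
  if (any(!ok)) {
    if (drop_invalid) {
      warning(sum(!ok), " record(s) with non-ACGT characters dropped: ",
              paste(utils::head(ids[!ok], 5L), collapse = ", "))
    } else {
      stop("record(s) with non-ACGT characters (use drop_invalid = TRUE ",
           "to skip them): ", paste(utils::head(ids[!ok], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- tibble::tibble(id = ids[ok], seq = unname(seqs[ok]))
  annot <- parse_header_annotations(headers[ok])
  if (!is.null(annot)) out <- dplyr::bind_cols(out, annot)
  out
}

# "id key=value key2=value2" -> tibble of annotation columns (or NULL)
parse_header_annotations <- function(headers) {
  rest <- sub("^\\S+\\s*", "", headers)
  if (all(rest == "")) return(NULL)
  recs <- lapply(rest, function(r) {
    if (r == "") return(character(0))
    toks <- strsplit(r, "\\s+")[[1]]
    toks <- toks[grepl("=", toks, fixed = TRUE)]
    vals <- sub("^[^=]*=", "", toks)
    stats::setNames(vals, sub("=.*$", "", toks))
  })
  keys <- unique(unlist(lapply(recs, names)))
  if (length(keys) == 0L) return(NULL)
  cols <- lapply(keys, function(k) {
    v <- vapply(recs, function(r) if (k %in% names(r)) r[[k]] else NA_character_,
                character(1))
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) num else v
  })
  tibble::as_tibble(stats::setNames(cols, keys))
}

#' Write a sequence table to a FASTA file
#'
#' @param data Data frame with columns `id` and `seq`; any other atomic
#'   columns listed in `annotations` are appended to the header as
#'   `key=value` pairs.
#' @param path Output path.
#' @param line_width Sequence line wrap width (default 70).
#' @param annotations Character vector of column names to annotate headers
#'   with; defaults to every extra atomic column present.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, line_width = 70L, annotations = NULL) {
  data <- as_sequence_tbl(data)
  if (is.null(annotations)) {
    annotations <- setdiff(names(data), c("id", "seq"))
    annotations <- annotations[vapply(data[annotations], is.atomic, logical(1))]
  }
  headers <- data$id
  for (a in annotations) {
    headers <- paste0(headers, " ", a, "=", format(data[[a]], trim = TRUE))
  }
  if (nrow(data) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(data$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}
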