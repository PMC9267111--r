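#' Coding-sequence sets
#'
#' A `cds_set` is a plain `data.frame` (one row per sequence) with columns
#' `id`, `sequence`, `origin` (`"virus"` or `"host"`), and the optional
#' grouping labels `host_species`, `genome_type` (`"(+)ssRNA"`, `"(-)ssRNA"`,
#' `"dsRNA"`) and `family`. Sequences are uppercase DNA over `{A,C,G,T}`
#' (RNA input is mapped `U -> T` on read).
#'
#' @param id character vector of sequence identifiers (must be unique).
#' @param sequence character vector of CDS strings.
#' @param origin `"virus"` or `"host"`, recycled to length.
#' @param host_species,genome_type,family optional label vectors (recycled).
#' @return A `cds_set` data.frame.
#' @export
coding_sequences <- function(id, sequence, origin = "host",
                             host_species = NA_character_,
                             genome_type = NA_character_,
                             family = NA_character_) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  origin <- match.arg(origin, c("virus", "host"), several.ok = TRUE)
  out <- data.frame(
    id = as.character(id),
    sequence = toupper(chartr("Uu", "Tt", as.character(sequence))),
    origin = rep_len(origin, length(id)),
    host_species = rep_len(as.character(host_species), length(id)),
    genome_type = rep_len(as.character(genome_type), length(id)),
    family = rep_len(as.character(family), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Read coding sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or single-line) FASTA file, uppercases the
#' sequences, maps `U` to `T`, and attaches an origin plus optional labels.
#' The record identifier is the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file.
#' @param origin `"virus"` or `"host"` applied to every record.
#' @param labels optional data.frame with an `id` column and any of
#'   `origin`, `host_species`, `genome_type`, `family`; matched by id.
#' @return A [coding_sequences()] `cds_set`.
#' @export
read_cds_fasta <- function(path, origin = c("host", "virus"), labels = NULL) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("no FASTA records in ", path)
    return(coding_sequences(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out <- coding_sequences(ids, as.character(seqs), origin = origin)
  if (!is.null(labels)) out <- apply_labels(out, labels)
  out
}

#' Read a tab-separated label table
#'
#' @param path TSV with header; must contain an `id` column.
#' @return data.frame of labels.
#' @export
read_label_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

apply_labels <- function(x, labels) {
  stopifnot(is.data.frame(labels), "id" %in% names(labels))
  idx <- match(x$id, labels$id)
  for (col in intersect(c("origin", "host_species", "genome_type", "family"),
                        names(labels))) {
    hit <- !is.na(idx)
    x[[col]][hit] <- as.character(labels[[col]][idx[hit]])
  }
  x
}

#' Validate coding sequences against the study inclusion criteria
#'
#' A CDS passes when it is longer than `min_length_nt` nucleotides (strict),
#' has length divisible by 3, starts with `ATG`, ends with a stop codon
#' (`TAA`/`TAG`/`TGA`), contains no internal stop codon, and has no
#' characters outside `{A,C,G,T}` (degenerate IUPAC codes are rejected, not
#' masked). Failures are reported, never raised.
#'
#' @param x a `cds_set` or character vector of sequences (names used as ids).
#' @param min_length_nt minimum CDS length in nt, strict inequality
#'   (default 300, i.e. "more than 300 nt").
#' @return data.frame with columns `id`, `passed`, `reasons`
#'   (semicolon-separated subset of `too_short`, `not_multiple_of_3`,
#'   `no_start`, `no_stop`, `internal_stop`, `degenerate_base`;
#'   empty string when passed). `passed` is TRUE iff `reasons` is empty.
#' @export
validate_cds <- function(x, min_length_nt = 300) {
  if (is.data.frame(x)) {
    ids <- x$id
    seqs <- x$sequence
  } else {
    seqs <- toupper(chartr("Uu", "Tt", as.character(x)))
    ids <- if (!is.null(names(x))) names(x) else paste0("seq", seq_along(x))
  }
  res <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (nchar(s) == 0L) stop("empty sequence for id ", ids[[i]])
    reasons <- character(0)
    if (nchar(s) <= min_length_nt) reasons <- c(reasons, "too_short")
    if (grepl("[^ACGT]", s)) reasons <- c(reasons, "degenerate_base")
    if (substr(s, 1L, 3L) != "ATG") reasons <- c(reasons, "no_start")
    if (nchar(s) %% 3L != 0L) {
      reasons <- c(reasons, "not_multiple_of_3")
    } else {
      codons <- split_codons(s)
      last <- codons[[length(codons)]]
      if (!last %in% STOP_CODONS) reasons <- c(reasons, "no_stop")
      if (length(codons) > 2L &&
          any(codons[seq.int(2L, length(codons) - 1L)] %in% STOP_CODONS))
        reasons <- c(reasons, "internal_stop")
    }
    reasons
  })
  data.frame(
    id = as.character(ids),
    passed = lengths(res) == 0L,
    reasons = vapply(res, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Keep only sequences that pass validation
#'
#' @inheritParams validate_cds
#' @return the `cds_set` restricted to passing rows; the validation report is
#'   attached as attribute `"validation"`.
#' @export
filter_valid_cds <- function(x, min_length_nt = 300) {
  rep <- validate_cds(x, min_length_nt = min_length_nt)
  out <- x[rep$passed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- rep
  out
}

#' Write a cds_set to FASTA
#'
#' @param x a `cds_set`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
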