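#' Read sequences into a reads tibble
#'
#' Thin wrapper around Biostrings that returns sequences as a tibble of
#' `id` and `seq`, the common currency of all pooling functions. FASTQ is
#' accepted (qualities are discarded); the format is sniffed from the first
#' non-empty character.
#'
#' @param path FASTA or FASTQ file.
#' @param type `"dna"` or `"aa"`.
#' @param max_bases Optional cap on total bases kept: reads are taken in file
#'   order until the cap is reached (emulating analysis of partial files).
#' @return Tibble with columns `id`, `seq`.
#' @export
read_sequences <- function(path, type = c("dna", "aa"), max_bases = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("sequence file not found: ", path, call. = FALSE)
  }
  first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path, format = fmt)
  } else {
    Biostrings::readAAStringSet(path, format = fmt)
  }
  out <- tibble(id = sub("\\s.*$", "", names(set)),
                seq = unname(toupper(as.character(set))))
  if (!is.null(max_bases)) {
    keep <- cumsum(nchar(out$seq)) <= max_bases
    if (!any(keep)) keep[1] <- TRUE
    out <- out[keep, ]
  }
  out
}

#' Write a reads tibble as FASTA
#'
#' @param reads Tibble with `id` and `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  writeLines(paste0(">", reads$id, "\n", reads$seq), path)
  invisible(path)
}

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (nrow(reads) == 0) stop("empty read set", call. = FALSE)
  invisible(reads)
}

n_ambiguous <- function(seqs) {
  nchar(seqs) - nchar(gsub("[^ACGT]", "", seqs))
}

#' Length and ambiguity filter
#'
#' Removes reads whose length falls outside mean +/- 2 standard deviations
#' of the set's lengths (population SD; the boundary is inclusive), or
#' that contain more than `max_ambiguous` non-ACGT characters. This mirrors
#' the standard shotgun-metagenome preprocessing convention for unassembled
#' reads; contigs should skip it.
#'
#' By default the length rule is iterated to a fixed point: truncating a
#' length distribution shrinks its standard deviation, so a single pass is
#' not a well-defined selection (reapplying it can remove further boundary
#' reads). Iterating makes the filter idempotent; `iterate = FALSE` gives
#' the strict single-pass behaviour of the upstream preprocessing scripts.
#'
#' @param reads Reads tibble (`id`, `seq`).
#' @param n_sd Width of the length window in standard deviations.
#' @param max_ambiguous Maximum tolerated count of ambiguous bases per read.
#' @param iterate Repeat the length rule until no further read is removed.
#' @return Filtered reads tibble.
#' @export
length_filter <- function(reads, n_sd = 2, max_ambiguous = 5,
                          iterate = TRUE) {
  check_reads(reads)
  reads <- reads[n_ambiguous(reads$seq) <= max_ambiguous, ]
  repeat {
    len <- nchar(reads$seq)
    mu <- mean(len)
    sdev <- sqrt(mean((len - mu)^2))
    keep <- len >= mu - n_sd * sdev & len <= mu + n_sd * sdev
    if (all(keep)) break
    reads <- reads[keep, ]
    if (!iterate) break
  }
  reads
}

#' Remove artificial duplicate reads
#'
#' Drops reads whose leading `prefix_len` bases are identical to those of an
#' earlier read (artificial duplicate reads from over-amplification); reads
#' shorter than `prefix_len` are compared by their full sequence. The first
#' occurrence is kept, and order is otherwise preserved, so the operation is
#' deterministic and idempotent.
#'
#' @param reads Reads tibble.
#' @param prefix_len Prefix length used for identity (>= 1).
#' @return Dereplicated reads tibble.
#' @export
dereplicate <- function(reads, prefix_len = 50) {
  check_reads(reads)
  if (prefix_len < 1) stop("prefix_len must be >= 1", call. = FALSE)
  key <- substr(reads$seq, 1, prefix_len)
  reads[!duplicated(key), ]
}

#' Orient coding sequences to positive sense
#'
#' Reverse-complements the negative-sense members of a coding-sequence set,
#' so that downstream mRNA composition (T read as U) is computed on the
#' transcribed strand, as an external gene caller defines it.
#'
#' @param reads CDS reads tibble.
#' @param strand Character vector, `"+"` or `"-"`, one per read; if `NULL`,
#'   strands are parsed from FragGeneScan-style headers
#'   (`readid_start_end_strand`).
#' @return Reads tibble, all positive-sense.
#' @export
orient_cds <- function(reads, strand = NULL) {
  check_reads(reads)
  if (is.null(strand)) strand <- parse_fgs_strand(reads$id)
  strand <- rep_len(as.character(strand), nrow(reads))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand label(s): ",
         paste(unique(strand[bad]), collapse = ", "), call. = FALSE)
  }
  neg <- strand == "-"
  if (any(neg)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$seq[neg])))
    reads$seq[neg] <- unname(rc)
  }
  reads
}

#' @rdname orient_cds
#' @param ids Header strings in the gene caller's `id_start_end_strand`
#'   convention.
#' @export
parse_fgs_strand <- function(ids) {
  strand <- sub("^.*_", "", ids)
  if (!all(strand %in% c("+", "-"))) {
    stop("cannot parse strand from headers; supply a strand sidecar table",
         call. = FALSE)
  }
  strand
}

#' Read a strand sidecar table
#'
#' Two-column TSV (`read_id`, `strand`) matching a CDS FASTA, as an
#' alternative to strand-bearing headers.
#'
#' @param path TSV path.
#' @param reads Optional reads tibble; if given, strands are returned in
#'   read order.
#' @return Named character vector of strands.
#' @export
read_strand_table <- function(path, reads = NULL) {
  tab <- readr::read_tsv(path, col_names = c("read_id", "strand"),
                         show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  if (identical(tolower(tab$read_id[1]), "read_id")) tab <- tab[-1, ]
  strands <- setNames(tab$strand, tab$read_id)
  if (!is.null(reads)) {
    miss <- setdiff(reads$id, names(strands))
    if (length(miss)) {
      stop("strand table is missing read(s): ",
           paste(head(miss, 3), collapse = ", "), call. = FALSE)
    }
    strands <- strands[reads$id]
  }
  strands
}
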