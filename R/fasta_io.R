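# FASTA input/output. Chain pairs come in as two records (receptor first);
# fused and masked sequences go out with the segment map encoded in the
# record description, e.g. "receptor=0-5;linker=5-8;peptide=8-11"
# (0-based half-open intervals).

#' Read a receptor/peptide chain pair from FASTA
#'
#' Either one file holding two records (receptor first, peptide second) or a
#' pair of single-record files.
#'
#' @param fasta path to a FASTA file.
#' @param peptide_fasta optional second file; if given, `fasta` holds the
#'   receptor record and `peptide_fasta` the peptide record.
#' @return a [chain_pair()].
#' @export
read_chain_pair <- function(fasta, peptide_fasta = NULL) {
  if (is.null(peptide_fasta)) {
    recs <- Biostrings::readAAStringSet(fasta)
    if (length(recs) != 2L) {
      stop("expected exactly 2 FASTA records (receptor, peptide), found ",
           length(recs), call. = FALSE)
    }
  } else {
    r <- Biostrings::readAAStringSet(fasta)
    p <- Biostrings::readAAStringSet(peptide_fasta)
    if (length(r) != 1L || length(p) != 1L) {
      stop("paired FASTA files must hold one record each", call. = FALSE)
    }
    recs <- c(r, p)
  }
  ids <- sub("\\s.*$", "", names(recs))
  chain_pair(ids[1], as.character(recs[[1]]), ids[2], as.character(recs[[2]]))
}

format_span_map <- function(spans) {
  paste0("receptor=", spans$receptor[1], "-", spans$receptor[2],
         ";linker=", spans$linker[1], "-", spans$linker[2],
         ";peptide=", spans$peptide[1], "-", spans$peptide[2])
}

parse_span_map <- function(desc) {
  get1 <- function(key) {
    m <- regmatches(desc, regexec(paste0(key, "=(\\d+)-(\\d+)"), desc))[[1]]
    if (length(m) != 3L) {
      stop("FASTA description lacks a '", key, "=start-end' segment",
           call. = FALSE)
    }
    as.integer(m[2:3])
  }
  list(receptor = get1("receptor"), linker = get1("linker"),
       peptide = get1("peptide"))
}

#' Write fused (or masked) sequences to FASTA
#'
#' Each record carries the segment map in its description so the fusion can
#' be reconstructed without side information.
#'
#' @param fused a `fused_sequence`, or a character vector of sequences (e.g.
#'   masked variants) sharing one span map.
#' @param file output path.
#' @param ids record identifiers; defaults to `fused`/`fused_1`, ...
#' @param spans span map, required when `fused` is a character vector.
#' @return `file`, invisibly.
#' @export
write_fused_fasta <- function(fused, file, ids = NULL, spans = NULL) {
  if (inherits(fused, "fused_sequence")) {
    seqs <- fused$sequence
    spans <- fused$spans
  } else {
    seqs <- as.character(fused)
    if (is.null(spans)) stop("spans are required for plain sequences",
                             call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- if (length(seqs) == 1L) "fused" else paste0("fused_", seq_along(seqs))
  }
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- paste(ids, format_span_map(spans))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read fused sequences back from FASTA
#'
#' @param file FASTA path written by [write_fused_fasta()].
#' @return a `fused_sequence` (single record) or a list of them.
#' @export
read_fused_fasta <- function(file) {
  recs <- Biostrings::readAAStringSet(file)
  out <- lapply(seq_along(recs), function(i) {
    spans <- parse_span_map(names(recs)[i])
    structure(list(sequence = as.character(recs[[i]]), spans = spans),
              class = "fused_sequence")
  })
  if (length(out) == 1L) out[[1]] else out
}
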