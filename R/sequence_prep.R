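# Sequence preparation: receptor-linker-peptide fusion and random masking.

#' Receptor/peptide chain pair
#'
#' Bundles the two input sequences of a docking problem. Both must be
#' nonempty strings over the 20 standard one-letter amino-acid codes.
#'
#' @param receptor_id,peptide_id text labels for the two chains.
#' @param receptor_seq,peptide_seq one-letter amino-acid sequences.
#' @return an object of class `chain_pair`.
#' @examples
#' chain_pair("rec", "ACDEF", "pep", "KLM")
#' @export
chain_pair <- function(receptor_id, receptor_seq, peptide_id, peptide_seq) {
  check_aa_sequence(receptor_seq, "receptor_seq")
  check_aa_sequence(peptide_seq, "peptide_seq")
  structure(
    list(receptor_id = as.character(receptor_id),
         receptor_seq = receptor_seq,
         peptide_id = as.character(peptide_id),
         peptide_seq = peptide_seq),
    class = "chain_pair")
}

#' Polyglycine linker specification
#'
#' The linker lets a single-chain predictor model a two-chain complex: a run
#' of `length` copies of `symbol` is inserted between receptor and peptide,
#' and excised from the model after prediction. A 30-residue glycine linker
#' with the peptide at the C-terminus is the default protocol; lengths of
#' 100 and 200 and the N-terminal placement are supported for protocol
#' comparisons.
#'
#' @param length linker length in residues (>= 0).
#' @param placement `"peptide_at_C_terminus"` (receptor first, default) or
#'   `"peptide_at_N_terminus"` (peptide first).
#' @param symbol one-letter code used for every linker residue.
#' @return an object of class `linker_spec`.
#' @export
linker_spec <- function(length = 30L,
                        placement = c("peptide_at_C_terminus",
                                      "peptide_at_N_terminus"),
                        symbol = "G") {
  length <- check_count(length, "length", lower = 0L)
  placement <- match.arg(placement)
  if (!is.character(symbol) || nchar(symbol) != 1L ||
      !symbol %in% AA_STANDARD) {
    stop("linker symbol must be a standard one-letter amino-acid code",
         call. = FALSE)
  }
  structure(list(length = length, placement = placement, symbol = symbol),
            class = "linker_spec")
}

#' Fuse receptor and peptide with a flexible linker
#'
#' Concatenates receptor, linker and peptide into a single sequence and
#' records where each segment lies as 0-based half-open intervals. With
#' `peptide_at_N_terminus` the order is peptide, linker, receptor.
#'
#' @param pair a [chain_pair()].
#' @param linker a [linker_spec()].
#' @return an object of class `fused_sequence` with elements `sequence` and
#'   `spans` (a list of `receptor`, `linker`, `peptide` intervals).
#' @examples
#' f <- fuse(chain_pair("r", "ACDEF", "p", "KLM"), linker_spec(length = 3))
#' f$sequence  # "ACDEFGGGKLM"
#' @export
fuse <- function(pair, linker = linker_spec()) {
  stopifnot(inherits(pair, "chain_pair"), inherits(linker, "linker_spec"))
  check_aa_sequence(pair$receptor_seq, "receptor_seq")
  check_aa_sequence(pair$peptide_seq, "peptide_seq")
  link <- strrep(linker$symbol, linker$length)
  r <- nchar(pair$receptor_seq)
  p <- nchar(pair$peptide_seq)
  l <- linker$length
  if (linker$placement == "peptide_at_C_terminus") {
    sequence <- paste0(pair$receptor_seq, link, pair$peptide_seq)
    spans <- list(receptor = c(0L, r),
                  linker   = c(r, r + l),
                  peptide  = c(r + l, r + l + p))
  } else {
    sequence <- paste0(pair$peptide_seq, link, pair$receptor_seq)
    spans <- list(receptor = c(p + l, p + l + r),
                  linker   = c(p, p + l),
                  peptide  = c(0L, p))
  }
  new_fused_sequence(sequence, spans)
}

new_fused_sequence <- function(sequence, spans) {
  spans <- lapply(spans, as.integer)
  validate_span_map(spans, nchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  link_chars <- unique(chars[span_idx(spans$linker)])
  if (length(link_chars) > 1L) {
    stop("linker span is not homogeneous: found {",
         paste(link_chars, collapse = ", "), "}", call. = FALSE)
  }
  structure(list(sequence = sequence, spans = spans),
            class = "fused_sequence")
}

#' Recover the receptor and peptide sequences from a fusion
#'
#' Inverse of [fuse()]: strips the linker span and returns the two original
#' segments.
#'
#' @param fused a `fused_sequence`.
#' @return list with `receptor_seq` and `peptide_seq`.
#' @export
unfuse <- function(fused) {
  stopifnot(inherits(fused, "fused_sequence"))
  chars <- strsplit(fused$sequence, "", fixed = TRUE)[[1]]
  list(receptor_seq = paste(chars[span_idx(fused$spans$receptor)], collapse = ""),
       peptide_seq  = paste(chars[span_idx(fused$spans$peptide)], collapse = ""))
}

#' Random-masking specification
#'
#' Masking a fraction of input residues perturbs a sequence-only predictor
#' into producing diverse conformations. Each variant masks exactly
#' `round(rate * n_eligible)` positions (half-up rounding), sampled without
#' replacement; the linker is scaffold and is never masked under the default
#' eligibility policy.
#'
#' @param rate fraction of eligible positions to mask, in \[0, 1\].
#' @param n_variants number of masked variants to generate (>= 1).
#' @param mask_symbol placeholder character substituted at masked positions;
#'   must not be one of the 20 standard codes.
#' @param eligible_policy `"receptor_and_peptide"` (default; linker excluded)
#'   or `"whole_fusion"`.
#' @return an object of class `mask_spec`.
#' @export
mask_spec <- function(rate = 0.25, n_variants = 8L, mask_symbol = "X",
                      eligible_policy = c("receptor_and_peptide",
                                          "whole_fusion")) {
  check_number(rate, "rate", lower = 0, upper = 1)
  n_variants <- check_count(n_variants, "n_variants", lower = 1L)
  eligible_policy <- match.arg(eligible_policy)
  if (!is.character(mask_symbol) || nchar(mask_symbol) != 1L ||
      mask_symbol %in% AA_STANDARD) {
    stop("mask_symbol must be a single non-standard placeholder character",
         call. = FALSE)
  }
  structure(list(rate = rate, n_variants = n_variants,
                 mask_symbol = mask_symbol,
                 eligible_policy = eligible_policy),
            class = "mask_spec")
}

#' Generate masked sequence variants
#'
#' Produces `spec$n_variants` copies of the fused sequence, each with
#' `round(rate * n_eligible)` positions replaced by the mask placeholder.
#' Variant `i` samples its positions with RNG seed `seed + i`, so the full
#' variant list is reproducible from `(fused, spec, seed)` alone.
#'
#' @param fused a `fused_sequence` from [fuse()].
#' @param spec a [mask_spec()].
#' @param seed integer base seed.
#' @return character vector of length `n_variants`.
#' @export
mask_variants <- function(fused, spec = mask_spec(), seed = 1L) {
  stopifnot(inherits(fused, "fused_sequence"), inherits(spec, "mask_spec"))
  seed <- check_count(seed, "seed", lower = -2147483647L)
  eligible <- switch(spec$eligible_policy,
    receptor_and_peptide = c(span_idx(fused$spans$receptor),
                             span_idx(fused$spans$peptide)),
    whole_fusion = seq_len(nchar(fused$sequence)))
  n_mask <- round_half_up(spec$rate * length(eligible))
  if (spec$rate > 0 && length(eligible) == 0L) {
    stop("no positions are eligible for masking", call. = FALSE)
  }
  chars <- strsplit(fused$sequence, "", fixed = TRUE)[[1]]
  vapply(seq_len(spec$n_variants), function(i) {
    v <- chars
    if (n_mask > 0) {
      pos <- withr::with_seed(seed + i,
                              sample(eligible, n_mask, replace = FALSE))
      v[pos] <- spec$mask_symbol
    }
    paste(v, collapse = "")
  }, character(1))
}

#' Replace mask placeholders with the original residues
#'
#' Predictor output corresponds to the real molecule; the mask token is an
#' input perturbation only. This restores the unmasked letters so chain
#' identities match the native complex downstream.
#'
#' @param masked_seq masked sequence.
#' @param original_seq unmasked sequence of equal length.
#' @param mask_symbol the placeholder character.
#' @return restored sequence.
#' @export
restore_masked <- function(masked_seq, original_seq, mask_symbol = "X") {
  if (nchar(masked_seq) != nchar(original_seq)) {
    stop("masked and original sequences differ in length", call. = FALSE)
  }
  m <- strsplit(masked_seq, "", fixed = TRUE)[[1]]
  o <- strsplit(original_seq, "", fixed = TRUE)[[1]]
  m[m == mask_symbol] <- o[m == mask_symbol]
  paste(m, collapse = "")
}
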