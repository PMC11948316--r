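# Shared helpers: rounding, spans, validation, small numerics.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Round half away from zero
#'
#' Conventional "schoolbook" rounding: halves round up in magnitude, unlike
#' [base::round()], which rounds halves to even. Used wherever a residue
#' count or a printed percentage is derived from a fraction.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## A span is an integer pair c(start, end), 0-based half-open, as used in the
## FASTA segment-map descriptions. Internally converted to 1-based R indices.
span_length <- function(span) span[2] - span[1]

span_idx <- function(span) {
  if (span_length(span) == 0L) return(integer(0))
  seq.int(span[1] + 1L, span[2])
}

validate_span_map <- function(spans, total_length) {
  need <- c("receptor", "linker", "peptide")
  if (!all(need %in% names(spans))) {
    stop("span map must name receptor, linker and peptide segments",
         call. = FALSE)
  }
  covered <- sort(unname(unlist(lapply(spans[need], span_idx))))
  if (!identical(covered, seq_len(total_length))) {
    stop("spans do not partition the sequence: expected to cover 1..",
         total_length, call. = FALSE)
  }
  invisible(spans)
}

## Small deterministic hash of a string, kept below 2^31 so it can seed R's RNG.
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (x in list(...)) {
    xi <- if (is.character(x)) hash_string(x) else as.numeric(x)
    h <- (h * 7919 + xi) %% 2147483647
  }
  as.integer(h)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be TRUE or FALSE", call. = FALSE)
  }
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single number", call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(name, " must be in [", lower, ", ", upper, "], got ", x,
         call. = FALSE)
  }
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop(name, " must be a whole number", call. = FALSE)
  as.integer(x)
}

## Validate a one-letter amino-acid string; `extra` admits non-standard
## placeholder characters (e.g. the mask symbol). Errors name the first
## offending position.
check_aa_sequence <- function(seq, name, extra = character(0)) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(name, " must be a nonempty character string", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- chars %in% c(AA_STANDARD, extra)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(name, " contains non-standard residue '", chars[bad],
         "' at position ", bad, call. = FALSE)
  }
  seq
}
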