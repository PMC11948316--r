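# pLDDT-based scoring, ranking, misdock filtering, confidence flagging.
#
# Three schemes, all over peptide residues: the plain mean, the mean over
# interface residues only (within 5 A of the receptor), and the
# contact-weighted mean, which zeroes non-contacting residues so that the
# score is the interface mean scaled by the fraction of the peptide in
# contact. The weighted scheme is the protocol default for picking the best
# of the 8 masked-variant models.

#' Mean peptide pLDDT
#'
#' @param model a `complex_model`.
#' @return mean of per-residue peptide pLDDT, in \[0, 100\].
#' @export
mean_peptide_plddt <- function(model) {
  p <- residue_plddt(model, "B")
  if (length(p) == 0L) stop("model has no peptide residues", call. = FALSE)
  mean(p)
}

#' Interface-only peptide pLDDT
#'
#' Mean pLDDT over the peptide residues within `cutoff` of the receptor;
#' defined as 0 when nothing is in contact, so misdocked models sort last.
#'
#' @param model a `complex_model`.
#' @param cutoff interface distance in Angstrom (default 5).
#' @return value in \[0, 100\].
#' @export
interface_plddt <- function(model, cutoff = 5) {
  p <- residue_plddt(model, "B")
  if (length(p) == 0L) stop("model has no peptide residues", call. = FALSE)
  contacts <- contacting_peptide_residues(model, cutoff)
  if (length(contacts) == 0L) return(0)
  mean(p[contacts])
}

#' Contact-weighted peptide pLDDT
#'
#' Sum of pLDDT over contacting peptide residues divided by the total
#' peptide length: equivalently the interface mean weighted by the fraction
#' of peptide residues in contact, with non-contacting residues scored 0.
#'
#' @inheritParams interface_plddt
#' @return value in \[0, 100\].
#' @export
contact_weighted_plddt <- function(model, cutoff = 5) {
  p <- residue_plddt(model, "B")
  if (length(p) == 0L) stop("model has no peptide residues", call. = FALSE)
  contacts <- contacting_peptide_residues(model, cutoff)
  sum(p[contacts]) / length(p)
}

#' Ranking scheme
#'
#' @param name `"contact_weighted"` (default), `"mean_peptide"` or
#'   `"interface_only"`.
#' @param contact_cutoff interface cutoff in Angstrom for the two
#'   contact-aware schemes (default 5).
#' @param direction `"maximize"` (default) or `"minimize"`. Minimization is
#'   exposed for protocol experiments with inverted mean-pLDDT selection.
#' @return an object of class `ranking_scheme`.
#' @export
ranking_scheme <- function(name = c("contact_weighted", "mean_peptide",
                                    "interface_only"),
                           contact_cutoff = 5,
                           direction = c("maximize", "minimize")) {
  name <- match.arg(name)
  direction <- match.arg(direction)
  check_number(contact_cutoff, "contact_cutoff")
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive",
                                call. = FALSE)
  structure(list(name = name, contact_cutoff = contact_cutoff,
                 direction = direction),
            class = "ranking_scheme")
}

scheme_score <- function(model, scheme) {
  switch(scheme$name,
    mean_peptide   = mean_peptide_plddt(model),
    interface_only = interface_plddt(model, scheme$contact_cutoff),
    contact_weighted = contact_weighted_plddt(model, scheme$contact_cutoff))
}

#' Rank candidate models and select the top one
#'
#' Orders models by the scheme score in the scheme's direction; ties are
#' broken by higher mean peptide pLDDT, then by lower variant index (taken
#' from provenance, falling back to input position). Exactly one model is
#' selected.
#'
#' @param models nonempty list of `complex_model` objects.
#' @param scheme a [ranking_scheme()].
#' @return an object of class `ranked_models`: the reordered model list plus
#'   a `table` data.frame (variant, all three scheme scores, min interchain
#'   distance, docked and selected flags).
#' @export
rank_and_select <- function(models, scheme = ranking_scheme()) {
  if (!is.list(models) || length(models) == 0L ||
      !all(vapply(models, inherits, logical(1), "complex_model"))) {
    stop("models must be a nonempty list of complex_model objects",
         call. = FALSE)
  }
  variant <- vapply(seq_along(models), function(i) {
    v <- models[[i]]$provenance$variant
    if (is.null(v)) i else as.integer(v)
  }, integer(1))
  tab <- data.frame(
    variant = variant,
    mean_peptide = vapply(models, mean_peptide_plddt, numeric(1)),
    interface_only = vapply(models, interface_plddt, numeric(1),
                            cutoff = scheme$contact_cutoff),
    contact_weighted = vapply(models, contact_weighted_plddt, numeric(1),
                              cutoff = scheme$contact_cutoff),
    min_distance = vapply(models, min_interchain_distance, numeric(1)),
    stringsAsFactors = FALSE)
  tab$docked <- tab$min_distance <= 8
  score <- tab[[scheme$name]]
  key <- if (scheme$direction == "maximize") -score else score
  ord <- order(key, -tab$mean_peptide, tab$variant)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$rank <- seq_len(nrow(tab))
  tab$selected <- tab$rank == 1L
  structure(list(models = models[ord], table = tab, scheme = scheme),
            class = "ranked_models")
}

#' Filter out clearly misdocked models
#'
#' Retains the models whose peptide lies within `cutoff` (minimum heavy-atom
#' distance) of the receptor.
#'
#' @param x a `ranked_models` object or a list of `complex_model`s.
#' @param cutoff misdock criterion in Angstrom (default 8).
#' @return same type as the input, restricted to docked models.
#' @export
filter_misdocked <- function(x, cutoff = 8) {
  if (inherits(x, "ranked_models")) {
    keep <- vapply(x$models, is_docked, logical(1), cutoff = cutoff)
    x$models <- x$models[keep]
    x$table <- x$table[keep, , drop = FALSE]
    rownames(x$table) <- NULL
    x
  } else {
    x[vapply(x, is_docked, logical(1), cutoff = cutoff)]
  }
}

#' Is a prediction high-confidence?
#'
#' TRUE when the mean pLDDT over all residues of both chains strictly
#' exceeds 70, the conventional high-confidence threshold for predicted
#' structures.
#'
#' @param model a `complex_model`.
#' @return logical.
#' @export
is_high_confidence <- function(model) {
  mean(c(residue_plddt(model, "A"), residue_plddt(model, "B"))) > 70
}

#' Write a ranking report
#'
#' Tab-separated table: one row per model with scheme scores, docked and
#' selected flags; consumed by the benchmark summary stage.
#'
#' @param ranked a `ranked_models` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ranking_report <- function(ranked, file) {
  stopifnot(inherits(ranked, "ranked_models"))
  utils::write.table(ranked$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
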