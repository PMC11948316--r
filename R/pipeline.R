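# End-to-end protocol: fuse, mask, predict, excise, rank, filter, evaluate.

#' Restore the original residues in a predicted structure
#'
#' Masked positions are an input perturbation; the emitted model corresponds
#' to the real molecule. Replaces the placeholder letters in the structure's
#' sequence and atom table by the original residues.
#'
#' @param predicted a `predicted_structure`.
#' @param original_sequence the unmasked fused sequence.
#' @param mask_symbol placeholder character.
#' @return the corrected `predicted_structure`.
#' @export
restore_prediction <- function(predicted, original_sequence,
                               mask_symbol = "X") {
  predicted$sequence <- restore_masked(predicted$sequence, original_sequence,
                                       mask_symbol)
  chars <- strsplit(predicted$sequence, "", fixed = TRUE)[[1]]
  predicted$atoms$aa <- chars[predicted$atoms$resno]
  predicted
}

#' Run the full docking protocol for one receptor/peptide pair
#'
#' Fuses the chains with a polyglycine linker, generates masked sequence
#' variants, predicts each through the backend (optionally with adaptive
#' recycling), excises the linker and splits chains, ranks the candidate
#' models by the chosen pLDDT scheme, filters misdocked models, and - when
#' a native complex is supplied - evaluates every model with DockQ.
#'
#' @param pair a [chain_pair()].
#' @param backend_factory function taking a span map and returning a backend
#'   callable, e.g. `function(spans) mock_backend(spans)`.
#' @param native optional native `complex_model` (or `native_fixture`) for
#'   evaluation.
#' @param linker a [linker_spec()].
#' @param mask a [mask_spec()].
#' @param scheme a [ranking_scheme()].
#' @param num_recycles recycles per prediction when `adaptive = FALSE`.
#' @param adaptive use [adaptive_predict()] (3 to 12 recycles in steps of 3).
#' @param misdock_cutoff misdock filter distance in Angstrom.
#' @param seed integer base seed; variant i uses seed + i throughout.
#' @return an object of class `pepdock_run`: `fused`, `variants`, `models`,
#'   `ranked` (a `ranked_models`), `viable`, `selected` (top-ranked model),
#'   `selected_result` (its `dockq_result`, if a native was given), and
#'   `table`, the per-variant report.
#' @export
pepdock_run <- function(pair, backend_factory, native = NULL,
                        linker = linker_spec(), mask = mask_spec(),
                        scheme = ranking_scheme(), num_recycles = 3L,
                        adaptive = FALSE, misdock_cutoff = 8, seed = 1L) {
  stopifnot(inherits(pair, "chain_pair"), is.function(backend_factory))
  check_flag(adaptive, "adaptive")
  if (inherits(native, "native_fixture")) native <- native$model

  fused <- fuse(pair, linker)
  variants <- mask_variants(fused, mask, seed)
  backend <- backend_factory(fused$spans)

  models <- lapply(seq_along(variants), function(i) {
    req <- prediction_request(variants[i], num_recycles = num_recycles,
                              seed = seed + i, mask_symbol = mask$mask_symbol)
    if (adaptive) {
      ap <- adaptive_predict(req, backend, fused$spans,
                             dock_cutoff = misdock_cutoff)
      s <- ap$structure
      recycles <- ap$recycles_used
    } else {
      s <- predict_structure(req, backend)
      recycles <- num_recycles
    }
    s <- restore_prediction(s, fused$sequence, mask$mask_symbol)
    model <- split_and_excise(s, fused$spans)
    model$provenance$variant <- i
    model$provenance$recycles_used <- recycles
    model
  })

  ranked <- rank_and_select(models, scheme)
  viable <- filter_misdocked(ranked, cutoff = misdock_cutoff)

  tab <- ranked$table
  if (!is.null(native)) {
    evals <- lapply(ranked$models, dockq_eval, native = native)
    tab$fnat <- vapply(evals, `[[`, numeric(1), "fnat")
    tab$irmsd <- vapply(evals, `[[`, numeric(1), "irmsd")
    tab$lrmsd <- vapply(evals, `[[`, numeric(1), "lrmsd")
    tab$dockq <- vapply(evals, `[[`, numeric(1), "dockq")
    tab$category <- vapply(evals, `[[`, character(1), "category")
    selected_result <- evals[[1]]
  } else {
    selected_result <- NULL
  }

  structure(list(fused = fused, variants = variants,
                 models = ranked$models, ranked = ranked, viable = viable,
                 selected = ranked$models[[1]],
                 selected_result = selected_result,
                 table = tab, seed = seed),
            class = "pepdock_run")
}

#' @export
print.pepdock_run <- function(x, ...) {
  cat("pepdock run:", length(x$models), "variants,",
      nrow(x$viable$table), "viable after misdock filter\n")
  sel <- x$table[x$table$selected, , drop = FALSE]
  cat(sprintf("selected variant %d: %s score %.1f, min distance %.1f A%s\n",
              sel$variant, x$ranked$scheme$name, sel[[x$ranked$scheme$name]],
              sel$min_distance,
              if (!is.null(x$selected_result))
                sprintf(", DockQ %.3f (%s)", x$selected_result$dockq,
                        x$selected_result$category) else ""))
  invisible(x)
}
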