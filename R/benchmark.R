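# Benchmark bookkeeping: quality-bin counts, viable-model counts, effective
# and overall success rates, and head-to-head method comparison.

DOCKQ_CATEGORIES <- c("incorrect", "acceptable", "medium", "high")
ACCEPTABLE_OR_BETTER <- c("acceptable", "medium", "high")

#' Per-target evaluation record
#'
#' @param target_id target label.
#' @param docked logical misdock-filter outcome for the selected model.
#' @param dockq optional DockQ score of the selected model.
#' @param category quality category; derived from `dockq` when omitted.
#' @return an object of class `target_result`.
#' @export
target_result <- function(target_id, docked, dockq = NULL, category = NULL) {
  check_flag(docked, "docked")
  if (is.null(category) && !is.null(dockq)) category <- classify_dockq(dockq)
  if (!is.null(category) && !category %in% DOCKQ_CATEGORIES) {
    stop("unknown category '", category, "'", call. = FALSE)
  }
  structure(list(target_id = as.character(target_id), docked = docked,
                 dockq = dockq, category = category),
            class = "target_result")
}

as_result_frame <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("target_id", "docked", "category") %in% names(results)))
    df <- results
  } else {
    if (!is.list(results) || length(results) == 0L) {
      stop("no target results supplied", call. = FALSE)
    }
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(target_id = r$target_id, docked = r$docked,
                 category = if (is.null(r$category)) NA_character_
                            else r$category,
                 dockq = if (is.null(r$dockq)) NA_real_ else r$dockq,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0L) stop("no target results supplied", call. = FALSE)
  df
}

#' Summarize a benchmark
#'
#' Counts quality bins among the viable (docked) targets and reports two
#' rates: the effective success rate, acceptable-or-better among viable
#' models (integer percent, half-up), and the overall rate,
#' acceptable-or-better over all targets (one decimal, half-up). Undocked
#' targets count toward the overall denominator only. With no viable
#' targets the effective rate is undefined (`NA`), not 0.
#'
#' @param results a list of [target_result()]s or a data.frame with columns
#'   `target_id`, `docked`, `category` (and optionally `dockq`).
#' @return an object of class `benchmark_summary`.
#' @export
summarize_benchmark <- function(results) {
  df <- as_result_frame(results)
  n_total <- nrow(df)
  viable <- df[df$docked %in% TRUE, , drop = FALSE]
  n_viable <- nrow(viable)
  counts <- vapply(DOCKQ_CATEGORIES,
                   function(k) sum(viable$category %in% k), integer(1))
  acc_viable <- sum(viable$category %in% ACCEPTABLE_OR_BETTER)
  acc_total <- sum(df$category %in% ACCEPTABLE_OR_BETTER)
  eff <- if (n_viable == 0L) NA_real_
         else round_half_up(100 * acc_viable / n_viable)
  overall <- round_half_up(100 * acc_total / n_total, 1)
  structure(list(n_total = n_total, n_viable = n_viable,
                 counts = counts,
                 acceptable_or_better_viable = acc_viable,
                 acceptable_or_better_total = acc_total,
                 effective_success_rate = eff,
                 overall_rate = overall),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Benchmark summary:", x$n_total, "targets,", x$n_viable, "viable\n")
  cat("  viable bins: high", x$counts[["high"]],
      "| medium", x$counts[["medium"]],
      "| acceptable", x$counts[["acceptable"]],
      "| incorrect", x$counts[["incorrect"]], "\n")
  eff <- if (is.na(x$effective_success_rate)) "undefined"
         else paste0(x$effective_success_rate, "%")
  cat("  effective success rate (viable):", eff, "\n")
  cat("  overall acceptable-or-better:", paste0(x$overall_rate, "%"), "\n")
  invisible(x)
}

#' Head-to-head method comparison
#'
#' Joins two result sets on target id and counts rescues in both
#' directions: a target is rescued by method `a` when `a` scores
#' acceptable-or-better and `b` scores incorrect.
#'
#' @param a,b result sets as in [summarize_benchmark()], over the same
#'   target ids.
#' @return list with `table` (per-target categories of both methods),
#'   `rescued_by_a`, `rescued_by_b`.
#' @export
compare_methods <- function(a, b) {
  da <- as_result_frame(a)
  db <- as_result_frame(b)
  if (!setequal(da$target_id, db$target_id) ||
      anyDuplicated(da$target_id) || anyDuplicated(db$target_id)) {
    only_a <- setdiff(da$target_id, db$target_id)
    only_b <- setdiff(db$target_id, da$target_id)
    stop("target sets differ (only in a: ",
         paste(only_a, collapse = ", "), "; only in b: ",
         paste(only_b, collapse = ", "), ")", call. = FALSE)
  }
  db <- db[match(da$target_id, db$target_id), , drop = FALSE]
  tab <- data.frame(target_id = da$target_id,
                    category_a = da$category, category_b = db$category,
                    stringsAsFactors = FALSE)
  acc <- function(k) k %in% ACCEPTABLE_OR_BETTER
  inc <- function(k) k %in% "incorrect"
  list(table = tab,
       rescued_by_a = sum(acc(tab$category_a) & inc(tab$category_b)),
       rescued_by_b = sum(acc(tab$category_b) & inc(tab$category_a)))
}
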