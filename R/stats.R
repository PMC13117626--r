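# Dataset summary statistics for hybridization experiments.

#' Number of unordered strain pairs
#'
#' @param n Number of strains (>= 0).
#' @return `n * (n - 1) / 2`.
#' @examples
#' count_pairs(30) # 435
#' @export
count_pairs <- function(n) {
  if (any(n < 0)) stop("n must be non-negative")
  as.integer(n * (n - 1) / 2)
}

#' Summarize a hybridization dataset
#'
#' Counts strains, dikaryons and pair categories. Sibling pairs (two
#' monokaryons of one dikaryon) are recorded compatible without
#' experimental testing, so they count towards `n_compatible_total` but
#' not towards `n_tested_pairs`/`n_compatible_tested`. The compatibility
#' rate uses observed (non-missing) pairs as its denominator.
#'
#' @param ds An [mti_dataset()].
#' @return An `mti_summary` list with fields `n_strains`, `n_dikaryons`,
#'   `n_pairs_total`, `n_sibling_pairs`, `n_tested_pairs`,
#'   `n_compatible_total`, `n_compatible_tested`, `n_incompatible`,
#'   `n_missing`, `compatibility_rate`, `n_loci_records`.
#' @export
summarize_dataset <- function(ds) {
  n <- length(ds$strains)
  sibs <- sibling_pairs(ds$parents)
  sib_keys <- if (nrow(sibs)) paste(sibs$strain_a, sibs$strain_b,
                                    sep = "\t") else character()
  m <- ds$matrix
  keys <- paste(m$strain_a, m$strain_b, sep = "\t")
  is_sib <- keys %in% sib_keys
  compat <- m$result == "compatible"
  out <- list(
    n_strains = n,
    n_dikaryons = length(unique(ds$parents$dikaryon_id)),
    n_pairs_total = count_pairs(n),
    n_sibling_pairs = nrow(sibs),
    n_tested_pairs = sum(!is_sib),
    n_compatible_total = sum(compat),
    n_compatible_tested = sum(compat & !is_sib),
    n_incompatible = sum(!compat),
    n_missing = count_pairs(n) - nrow(m),
    compatibility_rate = if (nrow(m)) sum(compat) / nrow(m) else NA_real_,
    n_loci_records = nrow(ds$loci))
  class(out) <- "mti_summary"
  out
}

#' @export
print.mti_summary <- function(x, ...) {
  cat("Hybridization dataset summary\n")
  cat(sprintf("  strains: %d (from %d dikaryons)\n",
              x$n_strains, x$n_dikaryons))
  cat(sprintf("  pairs: %d total = %d sibling + %d tested + %d missing\n",
              x$n_pairs_total, x$n_sibling_pairs, x$n_tested_pairs,
              x$n_missing))
  cat(sprintf("  observed: %d compatible (%d tested), %d incompatible\n",
              x$n_compatible_total, x$n_compatible_tested,
              x$n_incompatible))
  cat(sprintf("  compatibility rate: %.3f; OWE-SOJ records: %d\n",
              x$compatibility_rate, x$n_loci_records))
  invisible(x)
}

#' @export
as.data.frame.mti_summary <- function(x, ...) {
  data.frame(field = names(unclass(x)),
             value = unname(vapply(unclass(x), as.numeric, 0)),
             stringsAsFactors = FALSE)
}

#' Write inference results to files
#'
#' Writes `<out_prefix>_assignments.csv` (one row per strain per
#' co-optimal combination: `strain_id`, `combination_index`, `a_allele`,
#' `b_allele`, `mating_type` as `A{i}B{j}`) and `<out_prefix>_result.json`
#' (scores, co-optimal count, flagged suspect pairs, dataset statistics).
#'
#' @param result An `inference_result`.
#' @param out_prefix Output path prefix.
#' @param ds Optional [mti_dataset()]; when given, its summary statistics
#'   are embedded in the JSON document.
#' @return Invisibly, the two file paths written.
#' @export
write_result <- function(result, out_prefix, ds = NULL) {
  if (!length(result$assignments))
    stop("no assignments in result; nothing to write")
  rows <- lapply(seq_along(result$assignments), function(ix) {
    g <- result$assignments[[ix]]
    data.frame(strain_id = names(g$a), combination_index = ix,
               a_allele = unname(g$a), b_allele = unname(g$b),
               mating_type = paste0("A", unname(g$a), "B", unname(g$b)),
               stringsAsFactors = FALSE)
  })
  csv_path <- paste0(out_prefix, "_assignments.csv")
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE,
                   quote = FALSE)
  doc <- list(
    best_score = result$best_score,
    max_score = result$max_score,
    n_optimal = length(result$assignments),
    truncated = result$truncated,
    policy = result$policy,
    n_enumerated = result$n_enumerated,
    assignments = lapply(result$assignments, function(g)
      list(strain_id = names(g$a), a_allele = unname(g$a),
           b_allele = unname(g$b))),
    flagged_pairs = result$flagged_pairs,
    statistics = if (is.null(ds)) NULL else unclass(summarize_dataset(ds)))
  json_path <- paste0(out_prefix, "_result.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}
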