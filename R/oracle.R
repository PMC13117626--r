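# Brute-force exhaustive reference: enumerate every pair of set partitions
# (A-locus partition x B-locus partition) of a small strain set, score each
# against the observations, and return the exact optimum set. Exists to
# verify the branch-and-bound engine on small instances; guarded at n = 8
# (Bell(8) = 4140).

#' Enumerate all set partitions as restricted-growth strings
#'
#' @param n Number of elements, 1..8.
#' @return Integer matrix, one row per partition (Bell(n) rows, n columns),
#'   canonical restricted-growth labels in lexicographic order.
#' @export
enumerate_partitions <- function(n) {
  if (n < 1L || n > 8L)
    stop("enumerate_partitions is guarded to 1 <= n <= 8")
  rows <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      rows[[length(rows) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  do.call(rbind, rows)
}

# Bell numbers by the triangle recurrence (test reference)
bell_numbers <- function(n_max) {
  row <- 1
  bell <- numeric(n_max)
  for (n in seq_len(n_max)) {
    bell[n] <- row[length(row)]
    nxt <- numeric(length(row) + 1L)
    nxt[1L] <- row[length(row)]
    for (k in seq_along(row)) nxt[k + 1L] <- nxt[k] + row[k]
    row <- nxt
  }
  bell
}

# TRUE for each partition row whose every class is connected in the
# same-locus evidence graph E (over sorted-strain indices)
.partition_connected <- function(P, E) {
  apply(P, 1L, function(lab) {
    for (c in unique(lab)) {
      mem <- which(lab == c)
      if (length(mem) <= 1L) next
      seen <- mem[1L]
      repeat {
        nxt <- mem[!mem %in% seen &
                     colSums(E[seen, mem, drop = FALSE]) > 0L]
        if (!length(nxt)) break
        seen <- c(seen, nxt)
      }
      if (length(seen) != length(mem)) return(FALSE)
    }
    TRUE
  })
}

#' Exhaustive mating-type inference (verification oracle)
#'
#' Scores every admissible (A-partition, B-partition) pair of the strain
#' set. Under the `"evidence"` policy only partitions whose allele classes
#' are connected through same-locus OWE-SOJ records are admissible; under
#' `"free"` all partitions are. Independent of the branch-and-bound
#' engine: enumeration is exhaustive and scoring is computed over the full
#' partition grid.
#'
#' @param ds A validated [mti_dataset()] with at most 8 strains.
#' @param policy `"evidence"` or `"free"`.
#' @return An `inference_result` (see [infer_mating_types()]);
#'   `n_enumerated` is the number of admissible partition pairs scored.
#' @export
brute_force_infer <- function(ds, policy = c("evidence", "free")) {
  policy <- match.arg(policy)
  ex <- .expectations(ds)
  n <- ex$n
  if (n > 8L) stop("brute_force_infer is guarded to n <= 8 strains")
  P <- enumerate_partitions(n)
  np <- length(ex$pi)
  # partition x pair same-ness
  same <- matrix(FALSE, nrow(P), np)
  for (p in seq_len(np)) same[, p] <- P[, ex$pi[p]] == P[, ex$pj[p]]
  if (policy == "evidence") {
    ctx <- .engine_context(ds)
    keepA <- .partition_connected(P, ctx$EA)
    keepB <- .partition_connected(P, ctx$EB)
  } else keepA <- keepB <- rep(TRUE, nrow(P))
  PA <- P[keepA, , drop = FALSE]; PB <- P[keepB, , drop = FALSE]
  sameA <- same[keepA, , drop = FALSE]; sameB <- same[keepB, , drop = FALSE]

  full <- ex$type == 2L; co <- ex$type == 1L
  # full pairs separate by locus: score_full[i, j] = fa[i] + fb[j]
  fa <- if (any(full))
    rowSums(2L * (sameA[, full, drop = FALSE] ==
                    matrix(ex$expA[full], nrow(sameA), sum(full),
                           byrow = TRUE)) - 1L)
  else rep(0L, nrow(sameA))
  fb <- if (any(full))
    rowSums(2L * (sameB[, full, drop = FALSE] ==
                    matrix(ex$expB[full], nrow(sameB), sum(full),
                           byrow = TRUE)) - 1L)
  else rep(0L, nrow(sameB))
  # compat-only pairs: +1 unless different at both loci
  nco <- sum(co)
  total <- outer(fa, fb, "+")
  if (nco) {
    n00 <- (!sameA[, co, drop = FALSE]) %*% t(!sameB[, co, drop = FALSE])
    total <- total + nco - 2 * n00
  }
  best <- max(total)
  hits <- which(total == best, arr.ind = TRUE)
  strains <- ex$strains
  assignments <- lapply(seq_len(nrow(hits)), function(h)
    mti_assignment(stats::setNames(PA[hits[h, 1L], ], strains),
                   stats::setNames(PB[hits[h, 2L], ], strains)))
  keys <- vapply(assignments, function(g) .asg_key(g$a, g$b), "")
  o <- order(keys)
  assignments <- assignments[o]
  counts <- t(vapply(assignments, function(g)
    c(n_a = length(unique(g$a)), n_b = length(unique(g$b))),
    c(n_a = 0L, n_b = 0L)))
  out <- list(best_score = as.integer(best), max_score = sum(ex$type),
              assignments = assignments,
              n_enumerated = nrow(PA) * nrow(PB),
              allele_counts = counts, truncated = FALSE,
              policy = policy, starting_pair = NULL, clique = character())
  class(out) <- "inference_result"
  out$flagged_pairs <- detect_suspect_records(out, ds)
  out
}
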