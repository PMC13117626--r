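# Combinatorial pruning traversal for mating-type inference.
#
# A starting sibling pair is designated A1B1/A2B2, a greedy maximal
# pairwise-compatible sub-population is fixed with fresh mutually distinct
# alleles, and the remaining strains are resolved by an exact depth-first
# branch-and-bound over allele-class moves. Under the EVIDENCE_REQUIRED
# policy a strain may only share an allele class when OWE-SOJ "same"
# records connect it to that class; the admissible assignments are exactly
# those whose allele classes are connected through same-locus records, and
# the search realises them with join moves (one evidence edge into one
# class) and merge moves (evidence edges into several classes, which the
# new strain unites). Under the FREE policy every set partition of the
# strains is admissible at each locus; the search then enumerates the full
# restricted-growth space (no clique fixing, no evidence restriction) with
# the same score bound, and is intended for verification on small
# populations.

#' Inference configuration
#'
#' @param starting_pair Optional character vector of two sibling strain
#'   ids designated A1B1 and A2B2; default: both monokaryons of the
#'   lexicographically first two-strain dikaryon.
#' @param policy `"evidence"` (allele sharing requires OWE-SOJ support;
#'   the default) or `"free"` (all partitions admissible; exhaustive,
#'   small populations only).
#' @param max_optima Cap on the number of co-optimal assignments retained.
#' @param prune Use the score upper bound to prune the search (disable
#'   only to measure the unpruned traversal).
#' @return An `inference_config` list.
#' @export
inference_config <- function(starting_pair = NULL,
                             policy = c("evidence", "free"),
                             max_optima = 100L, prune = TRUE) {
  policy <- match.arg(policy)
  stopifnot(is.null(starting_pair) || length(starting_pair) == 2L,
            max_optima >= 1L)
  out <- list(starting_pair = starting_pair, policy = policy,
              max_optima = as.integer(max_optima), prune = isTRUE(prune))
  class(out) <- "inference_config"
  out
}

#' Select the starting sibling pair
#'
#' The two monokaryons of one dikaryon have clearly distinct mating types
#' (they coexisted in a fertile dikaryon) and anchor the labels A1B1 and
#' A2B2.
#'
#' @param ds An [mti_dataset()].
#' @param cfg An [inference_config()]; a user-supplied `starting_pair`
#'   must be a sibling pair.
#' @return Character vector of two strain ids.
#' @export
select_starting_pair <- function(ds, cfg = inference_config()) {
  sibs <- sibling_pairs(ds$parents)
  if (!is.null(cfg$starting_pair)) {
    k <- pair_key(cfg$starting_pair[1L], cfg$starting_pair[2L])
    ok <- any(sibs$strain_a == k$strain_a & sibs$strain_b == k$strain_b)
    if (!ok) stop("starting pair must be two monokaryons of one dikaryon")
    return(as.character(cfg$starting_pair))
  }
  if (!nrow(sibs))
    stop("no complete sibling pair in dataset; supply a starting pair")
  spl <- split(ds$parents$strain_id, ds$parents$dikaryon_id)
  spl <- spl[vapply(spl, length, 1L) == 2L]
  spl[[sort(names(spl))[1L]]]
}

# Internal engine context over sorted strains.
.engine_context <- function(ds) {
  ex <- .expectations(ds)
  n <- ex$n
  TY <- matrix(0L, n, n); XA <- matrix(NA, n, n); XB <- matrix(NA, n, n)
  for (p in seq_along(ex$pi)) {
    i <- ex$pi[p]; j <- ex$pj[p]
    TY[i, j] <- TY[j, i] <- ex$type[p]
    XA[i, j] <- XA[j, i] <- ex$expA[p]
    XB[i, j] <- XB[j, i] <- ex$expB[p]
  }
  # observation matrix: 1 compatible, -1 incompatible, 0 missing
  OB <- matrix(0L, n, n, dimnames = list(ex$strains, ex$strains))
  idx <- stats::setNames(seq_len(n), ex$strains)
  mi <- idx[ds$matrix$strain_a]; mj <- idx[ds$matrix$strain_b]
  v <- ifelse(ds$matrix$result == "compatible", 1L, -1L)
  OB[cbind(mi, mj)] <- v; OB[cbind(mj, mi)] <- v
  # OWE-SOJ "same" evidence adjacency per locus
  EA <- matrix(FALSE, n, n); EB <- matrix(FALSE, n, n)
  if (nrow(ds$loci)) {
    li <- idx[ds$loci$strain_a]; lj <- idx[ds$loci$strain_b]
    sa <- ds$loci$a_rel == "same"; sb <- ds$loci$b_rel == "same"
    EA[cbind(li, lj)[sa, , drop = FALSE]] <- TRUE
    EA[cbind(lj, li)[sa, , drop = FALSE]] <- TRUE
    EB[cbind(li, lj)[sb, , drop = FALSE]] <- TRUE
    EB[cbind(lj, li)[sb, , drop = FALSE]] <- TRUE
  }
  list(strains = ex$strains, n = n, idx = idx,
       TY = TY, XA = XA, XB = XB, OB = OB, EA = EA, EB = EB,
       max_score = sum(ex$type))
}

#' Seed the pairwise-compatible sub-population
#'
#' Greedy maximal compatible set containing the starting pair: remaining
#' strains are considered in identifier order and added iff observed
#' compatible with every current member (a missing or incompatible
#' observation excludes the strain). Members receive fresh, mutually
#' distinct alleles at both loci in order of addition.
#'
#' @param ds An [mti_dataset()].
#' @param start Character vector of two starting strains (observed
#'   compatible with each other).
#' @return Character vector of clique members in order of addition.
#' @export
seed_compatible_clique <- function(ds, start) {
  ctx <- .engine_context(ds)
  i1 <- ctx$idx[[start[1L]]]; i2 <- ctx$idx[[start[2L]]]
  if (ctx$OB[i1, i2] != 1L)
    stop("starting strains are not observed compatible")
  members <- c(i1, i2)
  for (s in seq_len(ctx$n)) {
    if (s %in% members) next
    if (all(ctx$OB[s, members] == 1L)) members <- c(members, s)
  }
  ctx$strains[members]
}

#' Candidate allele labels for one strain at one locus
#'
#' Always includes one fresh label (returned last). Under
#' `"evidence"`, the allele of an assigned strain `t` is additionally a
#' candidate iff an OWE-SOJ record for the pair marks this locus "same";
#' under `"free"` every existing label is a candidate. Existing labels are
#' returned in ascending order.
#'
#' @param strain Strain id, unassigned in `partial`.
#' @param locus `"A"` or `"B"`.
#' @param partial An [mti_assignment()]-like list with named vectors `a`,
#'   `b`; `NA` marks unassigned strains.
#' @param ds An [mti_dataset()].
#' @param policy `"evidence"` or `"free"`.
#' @return Integer vector of candidate labels, fresh label last.
#' @export
candidate_alleles <- function(strain, locus = c("A", "B"), partial, ds,
                              policy = c("evidence", "free")) {
  locus <- match.arg(locus); policy <- match.arg(policy)
  ctx <- .engine_context(ds)
  lab <- if (locus == "A") partial$a else partial$b
  lab <- lab[ctx$strains]
  s <- ctx$idx[[strain]]
  if (!is.na(lab[s])) stop("strain is already assigned")
  assigned <- which(!is.na(lab))
  existing <- sort(unique(lab[assigned]))
  if (policy == "evidence") {
    E <- if (locus == "A") ctx$EA else ctx$EB
    keep <- vapply(existing, function(c)
      any(E[s, assigned[lab[assigned] == c]]), TRUE)
    existing <- existing[keep]
  }
  fresh <- if (length(lab[!is.na(lab)])) max(lab, na.rm = TRUE) + 1L else 1L
  c(existing, fresh)
}

# Restricted-growth canonical relabeling over index order (sorted strains).
.rg <- function(x) match(x, unique(x))

# subsets of a set as a list of integer vectors (includes the empty set)
.subsets <- function(v) {
  k <- length(v)
  if (!k) return(list(integer()))
  out <- vector("list", 2^k)
  for (m in 0:(2^k - 1L))
    out[[m + 1L]] <- v[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]
  out
}

#' Canonicalize a mating-type assignment
#'
#' Relabels the allele classes at each locus by first appearance over
#' strains in sorted identifier order (restricted-growth labeling), so
#' that equivalent assignments map to one identical canonical form.
#'
#' @param asg An [mti_assignment()] or list with full named vectors `a`,
#'   `b`.
#' @return A canonical [mti_assignment()].
#' @export
canonicalize <- function(asg) {
  strains <- sort(names(asg$a))
  a <- asg$a[strains]; b <- asg$b[strains]
  if (anyNA(a) || anyNA(b)) stop("cannot canonicalize a partial assignment")
  mti_assignment(stats::setNames(.rg(unname(a)), strains),
                 stats::setNames(.rg(unname(b)), strains))
}

# signature used for deduplication and lexicographic ordering
.asg_key <- function(a, b) paste(sprintf("%03d", c(a, b)), collapse = ",")

#' Infer monokaryon mating types
#'
#' Runs the combinatorial pruning traversal and returns every co-optimal
#' canonical assignment. The search order over unresolved strains is by
#' descending count of incompatible observations (ties broken by
#' identifier), the branch bound is the partial score plus the maximum
#' contribution of every pair touching an unassigned strain, and branches
#' are pruned only when they provably cannot reach the best score found.
#'
#' @param ds A validated [mti_dataset()] (the input error scan must report
#'   no errors).
#' @param cfg An [inference_config()].
#' @return An `inference_result` list: `best_score`, `max_score`,
#'   `assignments` (canonical, deduplicated, lexicographically sorted),
#'   `n_enumerated` (candidate leaves examined), `flagged_pairs`,
#'   `allele_counts` (matrix, one row per assignment), `truncated`,
#'   `policy`, `starting_pair`, `clique`.
#' @export
infer_mating_types <- function(ds, cfg = inference_config()) {
  if (!length(ds$strains)) stop("empty dataset")
  rep_ <- validate_dataset(ds)
  if (nrow(rep_$errors))
    stop("dataset has validation errors; fix them before inference (",
         paste(unique(rep_$errors$code), collapse = ", "), ")")
  ctx <- .engine_context(ds)
  n <- ctx$n
  start <- select_starting_pair(ds, cfg)

  A <- rep(NA_integer_, n); B <- rep(NA_integer_, n)
  if (cfg$policy == "evidence") {
    clique <- seed_compatible_clique(ds, start)
    ci <- ctx$idx[clique]
    A[ci] <- seq_along(ci); B[ci] <- seq_along(ci)
    unresolved <- setdiff(seq_len(n), ci)
  } else {
    if (n > 10L)
      stop("free policy enumerates every set partition and is limited to ",
           "10 strains; use the evidence policy for larger populations")
    clique <- character()
    unresolved <- seq_len(n)
  }
  # conflict-first deterministic order
  incdeg <- rowSums(ctx$OB == -1L)
  unresolved <- unresolved[order(-incdeg[unresolved],
                                 ctx$strains[unresolved])]
  K <- length(unresolved)

  # initial partial score over pre-assigned pairs
  assigned0 <- which(!is.na(A))
  total0 <- 0L
  if (length(assigned0) >= 2L) {
    cmb <- utils::combn(assigned0, 2L)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1L, q]; j <- cmb[2L, q]
      total0 <- total0 + .contrib_ij(ctx, i, j, A, B)
    }
  }
  # bound: max contribution of pairs touching strains at depth >= d
  UBrem <- integer(K + 1L)
  if (K) for (d in K:1) {
    s <- unresolved[d]
    later <- if (d < K) unresolved[(d + 1L):K] else integer()
    UBrem[d] <- UBrem[d + 1L] +
      sum(ctx$TY[s, ]) - sum(ctx$TY[s, later])
  }

  st <- new.env(parent = emptyenv())
  st$best <- -Inf; st$store <- list(); st$n_leaf <- 0L; st$trunc <- FALSE

  leaf <- function(A, B, total) {
    st$n_leaf <- st$n_leaf + 1L
    if (total > st$best) {
      st$best <- total; st$store <- list(); st$trunc <- FALSE
    }
    if (total == st$best) {
      ca <- .rg(A); cb <- .rg(B)
      key <- .asg_key(ca, cb)
      if (is.null(st$store[[key]])) {
        if (length(st$store) < cfg$max_optima)
          st$store[[key]] <- list(a = ca, b = cb)
        else st$trunc <- TRUE
      }
    }
  }

  recurse <- function(d, A, B, total) {
    if (d > K) { leaf(A, B, total); return(invisible()) }
    if (cfg$prune && total + UBrem[d] < st$best) return(invisible())
    s <- unresolved[d]
    assigned <- which(!is.na(A))
    movesA <- .locus_moves(ctx, s, A, assigned, cfg$policy, "A")
    movesB <- .locus_moves(ctx, s, B, assigned, cfg$policy, "B")
    for (SA in movesA) for (SB in movesB) {
      up <- .apply_move(ctx, s, A, B, SA, SB, assigned)
      recurse(d + 1L, up$A, up$B, total + up$delta)
    }
    invisible()
  }
  recurse(1L, A, B, total0)

  keys <- sort(names(st$store))
  assignments <- lapply(keys, function(k)
    mti_assignment(stats::setNames(st$store[[k]]$a, ctx$strains),
                   stats::setNames(st$store[[k]]$b, ctx$strains)))
  counts <- t(vapply(assignments, function(g)
    c(n_a = length(unique(g$a)), n_b = length(unique(g$b))),
    c(n_a = 0L, n_b = 0L)))
  out <- list(best_score = as.integer(st$best), max_score = ctx$max_score,
              assignments = assignments, n_enumerated = st$n_leaf,
              allele_counts = counts, truncated = st$trunc,
              policy = cfg$policy, starting_pair = start, clique = clique)
  class(out) <- "inference_result"
  out$flagged_pairs <- detect_suspect_records(out, ds)
  out
}

# pair contribution for one (i, j) under current labels
.contrib_ij <- function(ctx, i, j, A, B) {
  t <- ctx$TY[i, j]
  if (t == 0L) return(0L)
  sameA <- A[i] == A[j]; sameB <- B[i] == B[j]
  if (t == 1L) return(2L * (sameA || sameB) - 1L)
  (2L * (sameA == ctx$XA[i, j]) - 1L) + (2L * (sameB == ctx$XB[i, j]) - 1L)
}

# admissible class-move sets for strain s at one locus:
# each move is the set of existing classes the strain unites (empty = fresh)
.locus_moves <- function(ctx, s, lab, assigned, policy, locus) {
  existing <- sort(unique(lab[assigned]))
  if (policy == "free") {
    # restricted-growth enumeration: fresh or join any one class
    return(c(list(integer()), lapply(existing, identity)))
  }
  E <- if (locus == "A") ctx$EA else ctx$EB
  ev <- existing[vapply(existing, function(c)
    any(E[s, assigned[lab[assigned] == c]]), TRUE)]
  .subsets(ev)
}

# apply the (SA, SB) move for strain s; returns updated labels and the
# score delta (merge corrections for previously scored pairs + new pairs)
.apply_move <- function(ctx, s, A, B, SA, SB, assigned) {
  delta <- 0L
  labA <- if (length(SA)) min(SA) else
    (if (length(assigned)) max(A[assigned]) + 1L else 1L)
  if (length(SA) >= 2L) {
    grp <- lapply(SA, function(c) assigned[A[assigned] == c])
    for (u1 in seq_len(length(grp) - 1L)) for (u2 in (u1 + 1L):length(grp))
      for (i in grp[[u1]]) for (j in grp[[u2]]) {
        t <- ctx$TY[i, j]
        if (t == 2L) delta <- delta + (if (isTRUE(ctx$XA[i, j])) 2L else -2L)
        else if (t == 1L) delta <- delta + (if (B[i] == B[j]) 0L else 2L)
      }
    A[A %in% SA] <- labA
  }
  labB <- if (length(SB)) min(SB) else
    (if (length(assigned)) max(B[assigned]) + 1L else 1L)
  if (length(SB) >= 2L) {
    grp <- lapply(SB, function(c) assigned[B[assigned] == c])
    for (u1 in seq_len(length(grp) - 1L)) for (u2 in (u1 + 1L):length(grp))
      for (i in grp[[u1]]) for (j in grp[[u2]]) {
        t <- ctx$TY[i, j]
        if (t == 2L) delta <- delta + (if (isTRUE(ctx$XB[i, j])) 2L else -2L)
        else if (t == 1L) delta <- delta + (if (A[i] == A[j]) 0L else 2L)
      }
    B[B %in% SB] <- labB
  }
  A[s] <- labA; B[s] <- labB
  if (length(assigned)) {
    ty <- ctx$TY[s, assigned]
    sameA <- A[assigned] == labA; sameB <- B[assigned] == labB
    full <- ty == 2L; co <- ty == 1L
    if (any(full))
      delta <- delta +
        sum(2L * (sameA[full] == ctx$XA[s, assigned][full]) - 1L) +
        sum(2L * (sameB[full] == ctx$XB[s, assigned][full]) - 1L)
    if (any(co))
      delta <- delta + sum(2L * (sameA[co] | sameB[co]) - 1L)
  }
  list(A = A, B = B, delta = delta)
}

#' Flag suspect observation records
#'
#' Returns every observed pair whose contribution is negative in all
#' co-optimal assignments: no optimal explanation of the data satisfies
#' the record, so the record itself is suspect. Pairs observed
#' incompatible are labeled `possible_false_negative` (the assignments
#' insist the strains are compatible); others are labeled `inconsistent`.
#' Empty whenever the best score equals the maximum achievable score.
#'
#' @param result An `inference_result`.
#' @param ds The [mti_dataset()] it was computed from.
#' @return Data.frame `strain_a`, `strain_b`, `reason`.
#' @export
detect_suspect_records <- function(result, ds) {
  empty <- data.frame(strain_a = character(), strain_b = character(),
                      reason = character(), stringsAsFactors = FALSE)
  if (!length(result$assignments)) return(empty)
  neg <- NULL
  for (asg in result$assignments) {
    br <- score_assignment(asg, ds)
    this <- br$per_pair$contribution < 0L
    neg <- if (is.null(neg)) this else neg & this
    if (!any(neg)) break
  }
  if (!any(neg)) return(empty)
  pp <- score_assignment(result$assignments[[1L]], ds)$per_pair
  flag <- pp[neg, c("strain_a", "strain_b"), drop = FALSE]
  key <- paste(flag$strain_a, flag$strain_b, sep = "\t")
  inc <- .pk(ds$matrix$strain_a, ds$matrix$strain_b)[
    ds$matrix$result == "incompatible"]
  flag$reason <- ifelse(key %in% inc, "possible_false_negative",
                        "inconsistent")
  rownames(flag) <- NULL
  flag
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Mating-type inference (", x$policy, " policy)\n", sep = "")
  cat("  best score:", x$best_score, "of", x$max_score, "achievable\n")
  cat("  co-optimal assignments:", length(x$assignments),
      if (x$truncated) "(truncated)" else "", "\n")
  if (nrow(x$allele_counts))
    cat("  allele classes (first optimum):",
        x$allele_counts[1L, "n_a"], "A,", x$allele_counts[1L, "n_b"], "B\n")
  cat("  candidate leaves examined:", x$n_enumerated, "\n")
  if (nrow(x$flagged_pairs)) {
    cat("  suspect records:\n")
    print(x$flagged_pairs, row.names = FALSE)
  }
  invisible(x)
}
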