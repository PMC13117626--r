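# Consistency scoring of a candidate mating-type assignment against the
# observations.
#
# Each fully informed unordered pair carries two locus-level checks worth
# +1/-1 each: a compatible observation expects DIFFERENT at both loci; an
# incompatible observation with an OWE-SOJ record expects the record's
# relations. An incompatible pair without a record carries a single
# compatibility-level check (+1 if the assignment predicts incompatibility,
# i.e. shares an allele at A or at B; -1 if it predicts compatibility).
# Unobserved pairs score 0. A complete, fully consistent population of n
# strains therefore has maximum score 2*C(n,2) (870 for n = 30).

#' Expected locus relations for one observed pair
#'
#' @param obs `"compatible"`, `"incompatible"` or `"missing"`.
#' @param loci_record Optional list/row with `a_rel` and `b_rel`
#'   (`"same"`/`"different"`), only allowed with an incompatible
#'   observation.
#' @return A list with `a_rel`, `b_rel` (`"same"`, `"different"` or
#'   `"unknown"`) and flag `compat_only` (incompatible pair with no
#'   locus-level information).
#' @export
pair_expectation <- function(obs, loci_record = NULL) {
  obs <- match.arg(obs, c("compatible", "incompatible", "missing"))
  if (!is.null(loci_record) && obs != "incompatible")
    stop("loci record supplied for a pair not observed incompatible")
  if (obs == "compatible")
    return(list(a_rel = "different", b_rel = "different",
                compat_only = FALSE))
  if (obs == "missing")
    return(list(a_rel = "unknown", b_rel = "unknown", compat_only = FALSE))
  if (is.null(loci_record))
    return(list(a_rel = "unknown", b_rel = "unknown", compat_only = TRUE))
  list(a_rel = loci_record$a_rel, b_rel = loci_record$b_rel,
       compat_only = FALSE)
}

# Internal pair-indexed expectation structure over sorted strains.
# type: 2 = full locus-level expectation, 1 = compatibility-only, 0 = missing
# expA/expB: TRUE = same expected, FALSE = different expected, NA otherwise.
# The per-pair maximum contribution equals `type`.
.expectations <- function(ds) {
  strains <- sort(ds$strains)
  n <- length(strains)
  idx <- stats::setNames(seq_len(n), strains)
  np <- (n * (n - 1L)) %/% 2L
  if (n >= 2L) {
    cmb <- utils::combn(n, 2L)
    pi <- cmb[1L, ]; pj <- cmb[2L, ]
  } else pi <- pj <- integer()
  type <- integer(np); expA <- rep(NA, np); expB <- rep(NA, np)
  pos <- function(i, j) { # i < j among 1..n
    (i - 1L) * n - (i * (i + 1L)) %/% 2L + j
  }
  m <- ds$matrix
  mi <- idx[m$strain_a]; mj <- idx[m$strain_b]
  swap <- mi > mj
  tmp <- mi[swap]; mi[swap] <- mj[swap]; mj[swap] <- tmp
  p <- pos(mi, mj)
  type[p[m$result == "compatible"]] <- 2L
  expA[p[m$result == "compatible"]] <- FALSE
  expB[p[m$result == "compatible"]] <- FALSE
  type[p[m$result == "incompatible"]] <- 1L
  if (nrow(ds$loci)) {
    li <- idx[ds$loci$strain_a]; lj <- idx[ds$loci$strain_b]
    swap <- li > lj
    tmp <- li[swap]; li[swap] <- lj[swap]; lj[swap] <- tmp
    lp <- pos(li, lj)
    type[lp] <- 2L
    expA[lp] <- ds$loci$a_rel == "same"
    expB[lp] <- ds$loci$b_rel == "same"
  }
  list(strains = strains, n = n, pi = pi, pj = pj,
       type = type, expA = expA, expB = expB, pos = pos)
}

# Vectorized pair contributions given logical same-ness at each locus.
.pair_contrib <- function(type, expA, expB, sameA, sameB) {
  out <- integer(length(type))
  full <- type == 2L
  out[full] <- (2L * (sameA[full] == expA[full]) - 1L) +
               (2L * (sameB[full] == expB[full]) - 1L)
  co <- type == 1L
  out[co] <- 2L * (sameA[co] | sameB[co]) - 1L
  out
}

.as_assignment_vectors <- function(asg, strains) {
  if (inherits(asg, "mti_assignment")) {
    a <- asg$a; b <- asg$b
  } else if (is.list(asg) && all(c("a", "b") %in% names(asg))) {
    a <- asg$a; b <- asg$b
  } else stop("assignment must be an mti_assignment or list(a=, b=)")
  if (!all(strains %in% names(a)) || !all(strains %in% names(b)))
    stop("assignment does not cover every strain in the dataset")
  list(a = unname(a[strains]), b = unname(b[strains]))
}

#' Mating-type assignment object
#'
#' An (A-allele, B-allele) label pair per strain. Allele labels are
#' arbitrary identifiers of equivalence classes: two assignments are
#' equivalent iff they induce the same partition of strains at each locus.
#'
#' @param a,b Named integer vectors (names = strain ids) of A- and B-locus
#'   allele labels.
#' @return An `mti_assignment`.
#' @export
mti_assignment <- function(a, b) {
  stopifnot(!is.null(names(a)), !is.null(names(b)),
            setequal(names(a), names(b)))
  out <- list(a = a[sort(names(a))], b = b[sort(names(b))])
  class(out) <- "mti_assignment"
  out
}

#' @export
print.mti_assignment <- function(x, ...) {
  cat("mti_assignment over", length(x$a), "strains:",
      length(unique(x$a)), "A alleles,", length(unique(x$b)), "B alleles\n")
  mt <- paste0("A", x$a, "B", x$b)
  print(stats::setNames(mt, names(x$a)), quote = FALSE)
  invisible(x)
}

#' Score an assignment against a dataset
#'
#' @param asg An [mti_assignment()] covering the dataset's strains.
#' @param ds An [mti_dataset()].
#' @return A `score_breakdown` list: `total`, `max_possible` and
#'   `per_pair` (data.frame `strain_a`, `strain_b`, `contribution`,
#'   `max_contribution` over observed pairs).
#' @export
score_assignment <- function(asg, ds) {
  ex <- .expectations(ds)
  v <- .as_assignment_vectors(asg, ex$strains)
  sameA <- v$a[ex$pi] == v$a[ex$pj]
  sameB <- v$b[ex$pi] == v$b[ex$pj]
  contrib <- .pair_contrib(ex$type, ex$expA, ex$expB, sameA, sameB)
  obs <- ex$type > 0L
  out <- list(
    total = sum(contrib),
    max_possible = sum(ex$type),
    per_pair = data.frame(
      strain_a = ex$strains[ex$pi[obs]],
      strain_b = ex$strains[ex$pj[obs]],
      contribution = contrib[obs],
      max_contribution = ex$type[obs],
      stringsAsFactors = FALSE))
  class(out) <- "score_breakdown"
  out
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("score:", x$total, "of", x$max_possible, "achievable\n")
  neg <- x$per_pair[x$per_pair$contribution < 0, , drop = FALSE]
  if (nrow(neg)) {
    cat("pairs with negative contribution:\n")
    print(neg, row.names = FALSE)
  }
  invisible(x)
}

#' Maximum achievable score of a dataset
#'
#' Sum over pairs of 2 (full locus-level expectation: compatible, or
#' incompatible with an OWE-SOJ record), 1 (incompatible without a record)
#' or 0 (missing).
#'
#' @param ds An [mti_dataset()].
#' @return Integer.
#' @export
max_possible_score <- function(ds) {
  ex <- .expectations(ds)
  sum(ex$type)
}
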