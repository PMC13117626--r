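# Core domain model: monokaryon parent tables, strain compatibility matrices
# from clamp-connection observations, and A/B loci consistency tables from
# OWE-SOJ assays on incompatible pairs. All tables are plain CSV (UTF-8,
# header row required).

OWE_SOJ_TOKENS <- c(
  "AeqBne" = "AeqBne", "AneBeq" = "AneBeq", "AeqBeq" = "AeqBeq",
  # UTF-8 dialect as written on the bench
  "A=B≠" = "AeqBne", "A≠B=" = "AneBeq", "A=B=" = "AeqBeq"
)

#' Canonical unordered pair keys
#'
#' Stores an unordered strain pair in canonical (lexicographic) order so that
#' `(x, y)` and `(y, x)` address the same observation.
#'
#' @param a,b Character vectors of strain identifiers (recycled pairwise).
#' @return A data.frame with columns `strain_a`, `strain_b`
#'   (`strain_a < strain_b` elementwise).
#' @examples
#' pair_key("m2", "m1")
#' @export
pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) stop("self pair: a strain cannot be paired with itself")
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  data.frame(strain_a = lo, strain_b = hi, stringsAsFactors = FALSE)
}

# Collision-free string key; strain ids cannot contain whitespace.
.pk <- function(a, b) {
  k <- pair_key(a, b)
  paste(k$strain_a, k$strain_b, sep = "\t")
}

.check_strain_ids <- function(ids, where) {
  ids <- as.character(ids)
  if (any(is.na(ids) | !nzchar(ids)))
    stop(sprintf("%s: empty strain identifier", where))
  if (any(grepl("[[:space:]]", ids)))
    stop(sprintf("%s: strain identifiers must not contain whitespace", where))
  invisible(ids)
}

#' Construct a monokaryon parent table
#'
#' Maps each protoplast-derived monokaryon to the dikaryon it was isolated
#' from. Two monokaryons sharing a dikaryon are a sibling pair and are
#' inherently compatible (they coexisted in a fertile dikaryon, so they
#' differ at both mating-type loci).
#'
#' @param strain_id Character vector of unique monokaryon identifiers.
#' @param dikaryon_id Character vector of dikaryon identifiers (1 or 2
#'   strains each).
#' @return A `parent_table` data.frame with columns `strain_id`,
#'   `dikaryon_id`; input row order is preserved.
#' @export
parent_table <- function(strain_id, dikaryon_id) {
  strain_id <- .check_strain_ids(strain_id, "parent table")
  dikaryon_id <- as.character(dikaryon_id)
  if (any(is.na(dikaryon_id) | !nzchar(dikaryon_id)))
    stop("parent table: empty dikaryon identifier")
  if (anyDuplicated(strain_id))
    stop("parent table: duplicate strain id: ",
         paste(unique(strain_id[duplicated(strain_id)]), collapse = ", "))
  tab <- table(dikaryon_id)
  if (any(tab > 2))
    stop("parent table: a dikaryon yields at most two monokaryons: ",
         paste(names(tab)[tab > 2], collapse = ", "))
  out <- data.frame(strain_id = strain_id, dikaryon_id = dikaryon_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("parent_table", "data.frame")
  out
}

#' Sibling pairs of a parent table
#'
#' @param parents A [parent_table()].
#' @return Canonical pair-key data.frame of all two-strain dikaryons.
#' @export
sibling_pairs <- function(parents) {
  spl <- split(parents$strain_id, parents$dikaryon_id)
  spl <- spl[vapply(spl, length, 1L) == 2L]
  if (!length(spl))
    return(data.frame(strain_a = character(), strain_b = character(),
                      stringsAsFactors = FALSE))
  out <- pair_key(vapply(spl, `[`, "", 1L), vapply(spl, `[`, "", 2L))
  out[order(out$strain_a, out$strain_b), , drop = FALSE]
}

#' Construct a strain compatibility matrix
#'
#' Holds the clamp-connection outcome of every performed pairwise
#' hybridization: `compatible` (clamp connections observed, the strains
#' differ at both loci) or `incompatible`. Unobserved pairs are missing.
#'
#' @param strain_a,strain_b Strain identifiers per observed pair.
#' @param result Character vector, `"compatible"` or `"incompatible"`.
#' @param strains Character vector of all strains in the study (defines the
#'   matrix dimensions; pairs absent from the table are missing).
#' @return A `compat_matrix` data.frame with canonical pair keys and a
#'   `strains` attribute.
#' @export
compat_matrix <- function(strain_a, strain_b, result, strains) {
  strains <- .check_strain_ids(strains, "compatibility matrix")
  if (anyDuplicated(strains))
    stop("compatibility matrix: duplicate strain id in strain list")
  result <- as.character(result)
  bad <- setdiff(result, c("compatible", "incompatible"))
  if (length(bad))
    stop("compatibility matrix: invalid result token: ",
         paste(unique(bad), collapse = ", "))
  unknown <- setdiff(c(strain_a, strain_b), strains)
  if (length(unknown))
    stop("compatibility matrix: unknown strain: ",
         paste(unique(unknown), collapse = ", "))
  if (length(strain_a)) {
    k <- pair_key(strain_a, strain_b)
  } else {
    k <- data.frame(strain_a = character(), strain_b = character(),
                    stringsAsFactors = FALSE)
  }
  k$result <- result
  key <- paste(k$strain_a, k$strain_b, sep = "\t")
  if (anyDuplicated(key)) {
    # collapse duplicates that agree; conflicting duplicates are an error
    conflicts <- tapply(k$result, key, function(r) length(unique(r)) > 1L)
    if (any(conflicts))
      stop("compatibility matrix: conflicting duplicate observation for pair(s): ",
           paste(gsub("\t", "/", names(conflicts)[conflicts]), collapse = ", "))
    k <- k[!duplicated(key), , drop = FALSE]
  }
  k <- k[order(k$strain_a, k$strain_b), , drop = FALSE]
  rownames(k) <- NULL
  attr(k, "strains") <- strains
  class(k) <- c("compat_matrix", "data.frame")
  k
}

#' Construct an A/B loci consistency table
#'
#' One record per incompatible pair assayed with OWE-SOJ, giving whether the
#' two strains carry the same or different alleles at each locus. A pair
#' cannot be `different` at both loci (that would make it compatible).
#'
#' @param strain_a,strain_b Strain identifiers per record.
#' @param a_rel,b_rel Character vectors, `"same"` or `"different"`.
#' @return A `loci_table` data.frame with canonical pair keys.
#' @export
loci_table <- function(strain_a = character(), strain_b = character(),
                       a_rel = character(), b_rel = character()) {
  a_rel <- as.character(a_rel); b_rel <- as.character(b_rel)
  bad <- setdiff(c(a_rel, b_rel), c("same", "different"))
  if (length(bad))
    stop("loci table: relations must be 'same' or 'different'")
  if (any(a_rel == "different" & b_rel == "different"))
    stop("loci table: a pair differing at both loci would be compatible")
  if (length(strain_a)) {
    k <- pair_key(strain_a, strain_b)
  } else {
    k <- data.frame(strain_a = character(), strain_b = character(),
                    stringsAsFactors = FALSE)
  }
  k$a_rel <- a_rel
  k$b_rel <- b_rel
  key <- paste(k$strain_a, k$strain_b, sep = "\t")
  if (anyDuplicated(key)) {
    rel <- paste(k$a_rel, k$b_rel)
    conflicts <- tapply(rel, key, function(r) length(unique(r)) > 1L)
    if (any(conflicts))
      stop("loci table: conflicting duplicate record for pair(s): ",
           paste(gsub("\t", "/", names(conflicts)[conflicts]), collapse = ", "))
    k <- k[!duplicated(key), , drop = FALSE]
  }
  k <- k[order(k$strain_a, k$strain_b), , drop = FALSE]
  rownames(k) <- NULL
  class(k) <- c("loci_table", "data.frame")
  k
}

#' Read a monokaryon parent table from CSV
#'
#' Expects a header `strain_id,dikaryon_id`.
#'
#' @param path Path to a CSV file.
#' @return A [parent_table()].
#' @export
read_parent_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("strain_id", "dikaryon_id") %in% names(df)))
    stop("parent table: header must be 'strain_id,dikaryon_id'")
  parent_table(df$strain_id, df$dikaryon_id)
}

#' Write a monokaryon parent table to CSV
#' @param parents A [parent_table()].
#' @param path Output path.
#' @export
write_parent_table <- function(parents, path) {
  utils::write.csv(as.data.frame(parents)[c("strain_id", "dikaryon_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a strain compatibility matrix from CSV
#'
#' Accepts two dialects, auto-detected from the header: the canonical long
#' format (`strain_a,strain_b,result` with result `compatible` or
#' `incompatible`) and a wide square-matrix format whose header row and
#' first column hold strain identifiers, with cells `1` (compatible), `0`
#' (incompatible), `NA`/empty (missing) and `-` on the diagonal.
#'
#' @param path Path to a CSV file.
#' @param parents A [parent_table()] supplying the strain universe.
#' @return A [compat_matrix()].
#' @export
read_compatibility <- function(path, parents) {
  strains <- parents$strain_id
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (identical(hdr[seq_len(min(3L, length(hdr)))],
                c("strain_a", "strain_b", "result"))) {
    df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    return(compat_matrix(df$strain_a, df$strain_b, tolower(df$result),
                         strains))
  }
  # wide dialect: first column = strain ids, remaining columns likewise
  wide <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  row_ids <- wide[[1L]]
  col_ids <- names(wide)[-1L]
  if (!length(col_ids) || !all(col_ids %in% strains) ||
      !all(row_ids %in% strains))
    stop("compatibility matrix: unrecognised header; expected long format ",
         "'strain_a,strain_b,result' or a wide matrix of known strain ids")
  cells <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(cells) <- row_ids
  sa <- character(); sb <- character(); res <- character()
  for (i in seq_along(row_ids)) for (j in seq_along(col_ids)) {
    if (row_ids[i] == col_ids[j]) next
    v <- cells[i, j]
    if (is.na(v) || v %in% c("", "NA", "-")) next
    if (!v %in% c("0", "1"))
      stop("compatibility matrix: invalid cell value '", v, "'")
    sa <- c(sa, row_ids[i]); sb <- c(sb, col_ids[j])
    res <- c(res, if (v == "1") "compatible" else "incompatible")
  }
  compat_matrix(sa, sb, res, strains)
}

#' Write a strain compatibility matrix to CSV
#'
#' @param matrix A [compat_matrix()].
#' @param path Output path.
#' @param format `"long"` (canonical) or `"wide"` (square matrix dialect).
#' @export
write_compatibility <- function(matrix, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    utils::write.csv(as.data.frame(matrix)[c("strain_a", "strain_b", "result")],
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  strains <- attr(matrix, "strains")
  n <- length(strains)
  cells <- base::matrix("", n, n, dimnames = list(strains, strains))
  diag(cells) <- "-"
  for (r in seq_len(nrow(matrix))) {
    v <- if (matrix$result[r] == "compatible") "1" else "0"
    cells[matrix$strain_a[r], matrix$strain_b[r]] <- v
    cells[matrix$strain_b[r], matrix$strain_a[r]] <- v
  }
  out <- data.frame(strain_id = strains, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an A/B loci consistency table from CSV
#'
#' Expects a header `strain_a,strain_b,owe_soj` with tokens `AeqBne`
#' (common A, different B), `AneBeq` (different A, common B) or `AeqBeq`
#' (common at both). The UTF-8 spellings `A=B≠`, `A≠B=` and `A=B=` are
#' accepted as synonyms. Records are only valid for pairs observed
#' incompatible in the compatibility matrix.
#'
#' @param path Path to a CSV file.
#' @param matrix A [compat_matrix()] the records must be consistent with.
#' @return A [loci_table()].
#' @export
read_loci_table <- function(path, matrix) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                        fileEncoding = "UTF-8")
  if (!all(c("strain_a", "strain_b", "owe_soj") %in% names(df)))
    stop("loci table: header must be 'strain_a,strain_b,owe_soj'")
  tok <- OWE_SOJ_TOKENS[df$owe_soj]
  if (any(is.na(tok)) && nrow(df))
    stop("loci table: unknown OWE-SOJ token: ",
         paste(unique(df$owe_soj[is.na(tok)]), collapse = ", "))
  a_rel <- c(AeqBne = "same", AneBeq = "different", AeqBeq = "same")[tok]
  b_rel <- c(AeqBne = "different", AneBeq = "same", AeqBeq = "same")[tok]
  lt <- loci_table(df$strain_a, df$strain_b, unname(a_rel), unname(b_rel))
  incompat <- .pk(matrix$strain_a, matrix$strain_b)[
    matrix$result == "incompatible"]
  if (nrow(lt)) {
    key <- paste(lt$strain_a, lt$strain_b, sep = "\t")
    bad <- !key %in% incompat
    if (any(bad))
      stop("loci table: record for a pair not observed incompatible: ",
           paste(gsub("\t", "/", key[bad]), collapse = ", "))
  }
  lt
}

#' Write an A/B loci consistency table to CSV
#' @param loci A [loci_table()].
#' @param path Output path.
#' @export
write_loci_table <- function(loci, path) {
  tok <- ifelse(loci$a_rel == "same" & loci$b_rel == "different", "AeqBne",
         ifelse(loci$a_rel == "different" & loci$b_rel == "same", "AneBeq",
                "AeqBeq"))
  out <- data.frame(strain_a = loci$strain_a, strain_b = loci$strain_b,
                    owe_soj = tok, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a dataset from its three tables
#'
#' Bundles the parent table, compatibility matrix and loci consistency
#' table. Sibling pairs absent from the matrix are auto-filled as
#' compatible with a warning: same-dikaryon monokaryons are inherently
#' compatible and are recorded without experimental testing.
#'
#' @param parents A [parent_table()].
#' @param matrix A [compat_matrix()].
#' @param loci A [loci_table()] (may be empty).
#' @param autofill_siblings Record absent sibling pairs as compatible.
#' @return An `mti_dataset` (list with elements `parents`, `matrix`,
#'   `loci`, `strains`).
#' @export
mti_dataset <- function(parents, matrix, loci = loci_table(),
                        autofill_siblings = TRUE) {
  stopifnot(inherits(parents, "parent_table"),
            inherits(matrix, "compat_matrix"))
  if (autofill_siblings) {
    sibs <- sibling_pairs(parents)
    if (nrow(sibs)) {
      have <- paste(matrix$strain_a, matrix$strain_b, sep = "\t")
      need <- paste(sibs$strain_a, sibs$strain_b, sep = "\t")
      add <- !need %in% have
      if (any(add)) {
        warning(sum(add), " sibling pair(s) absent from the matrix ",
                "auto-recorded as compatible")
        matrix <- compat_matrix(
          c(matrix$strain_a, sibs$strain_a[add]),
          c(matrix$strain_b, sibs$strain_b[add]),
          c(matrix$result, rep("compatible", sum(add))),
          attr(matrix, "strains"))
      }
    }
  }
  out <- list(parents = parents, matrix = matrix, loci = loci,
              strains = attr(matrix, "strains"))
  class(out) <- "mti_dataset"
  out
}

#' Read a full dataset from its three CSV files
#'
#' @param parents_path,matrix_path,loci_path CSV paths; `loci_path` may be
#'   `NULL` when no incompatible pair was assayed.
#' @param ... Passed to [mti_dataset()].
#' @return An [mti_dataset()].
#' @export
read_dataset <- function(parents_path, matrix_path, loci_path = NULL, ...) {
  parents <- read_parent_table(parents_path)
  matrix <- read_compatibility(matrix_path, parents)
  loci <- if (is.null(loci_path)) loci_table() else
    read_loci_table(loci_path, matrix)
  mti_dataset(parents, matrix, loci, ...)
}

#' Scan a dataset for input errors
#'
#' The pre-inference error scan. Errors (which bar inference): a sibling
#' pair recorded incompatible, a loci record claiming both loci differ, a
#' matrix strain absent from the parent table, a loci record for a pair not
#' observed incompatible. Warnings: incompatible pairs lacking an OWE-SOJ
#' record (they are scored on compatibility alone). `missing_pairs` lists
#' every unordered pair with no observation.
#'
#' @param ds An [mti_dataset()].
#' @return A `validation_report` list with `errors`, `warnings`
#'   (data.frames with columns `code`, `item`, `message`) and
#'   `missing_pairs` (pair-key data.frame).
#' @export
validate_dataset <- function(ds) {
  err <- list(); wrn <- list()
  note <- function(code, item, message)
    data.frame(code = code, item = item, message = message,
               stringsAsFactors = FALSE)

  unknown <- setdiff(ds$strains, ds$parents$strain_id)
  for (s in unknown)
    err[[length(err) + 1L]] <- note("unknown_strain", s,
      "strain in compatibility matrix absent from parent table")

  sibs <- sibling_pairs(ds$parents)
  sib_keys <- if (nrow(sibs)) paste(sibs$strain_a, sibs$strain_b, sep = "\t")
              else character()
  m <- ds$matrix
  mkeys <- paste(m$strain_a, m$strain_b, sep = "\t")
  bad_sib <- mkeys[m$result == "incompatible" & mkeys %in% sib_keys]
  for (k in bad_sib)
    err[[length(err) + 1L]] <- note("sibling_incompatible",
      gsub("\t", "/", k),
      "monokaryons from one dikaryon are inherently compatible")

  if (nrow(ds$loci)) {
    lk <- paste(ds$loci$strain_a, ds$loci$strain_b, sep = "\t")
    both_diff <- ds$loci$a_rel == "different" & ds$loci$b_rel == "different"
    for (k in lk[both_diff])
      err[[length(err) + 1L]] <- note("loci_both_different",
        gsub("\t", "/", k),
        "different at both loci implies compatibility")
    incompat <- mkeys[m$result == "incompatible"]
    for (k in setdiff(lk, incompat))
      err[[length(err) + 1L]] <- note("loci_for_compatible_pair",
        gsub("\t", "/", k),
        "loci record for a pair not observed incompatible")
    covered <- lk
  } else covered <- character()

  no_record <- setdiff(mkeys[m$result == "incompatible"], covered)
  for (k in no_record)
    wrn[[length(wrn) + 1L]] <- note("incompatible_without_loci_record",
      gsub("\t", "/", k),
      "incompatible pair lacking an OWE-SOJ record; scored on compatibility only")

  strains <- sort(ds$strains)
  miss <- data.frame(strain_a = character(), strain_b = character(),
                     stringsAsFactors = FALSE)
  if (length(strains) >= 2L) {
    cmb <- utils::combn(strains, 2L)
    allk <- paste(cmb[1L, ], cmb[2L, ], sep = "\t")
    absent <- !allk %in% mkeys
    miss <- data.frame(strain_a = cmb[1L, absent], strain_b = cmb[2L, absent],
                       stringsAsFactors = FALSE)
  }

  empty <- data.frame(code = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE)
  out <- list(
    errors = if (length(err)) do.call(rbind, err) else empty,
    warnings = if (length(wrn)) do.call(rbind, wrn) else empty,
    missing_pairs = miss)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation report\n")
  cat("  errors:  ", nrow(x$errors), "\n")
  if (nrow(x$errors))
    cat(paste0("    [", x$errors$code, "] ", x$errors$item, ": ",
               x$errors$message, collapse = "\n"), "\n")
  cat("  warnings:", nrow(x$warnings), "\n")
  cat("  missing pairs:", nrow(x$missing_pairs), "\n")
  invisible(x)
}

#' @export
print.mti_dataset <- function(x, ...) {
  cat("mti_dataset:", length(x$strains), "strains,",
      nrow(x$matrix), "observed pairs (",
      sum(x$matrix$result == "incompatible"), "incompatible ),",
      nrow(x$loci), "OWE-SOJ records\n")
  invisible(x)
}
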