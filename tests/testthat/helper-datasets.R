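# Fixture builders shared across test files. All datasets are constructed
# in code; nothing is read from disk unless a test writes it first.

# compact dataset builder: `pairs` is a data.frame-like list with columns
# strain_a, strain_b, result and optionally owe_soj ("" = no record)
make_dataset <- function(parents_df, pairs, autofill_siblings = TRUE) {
  parents <- parent_table(parents_df$strain_id, parents_df$dikaryon_id)
  m <- compat_matrix(pairs$strain_a, pairs$strain_b, pairs$result,
                     parents$strain_id)
  lt <- loci_table()
  if (!is.null(pairs$owe_soj)) {
    has <- nzchar(pairs$owe_soj)
    if (any(has)) {
      a_rel <- c(AeqBne = "same", AneBeq = "different",
                 AeqBeq = "same")[pairs$owe_soj[has]]
      b_rel <- c(AeqBne = "different", AneBeq = "same",
                 AeqBeq = "same")[pairs$owe_soj[has]]
      lt <- loci_table(pairs$strain_a[has], pairs$strain_b[has],
                       unname(a_rel), unname(b_rel))
    }
  }
  suppressWarnings(mti_dataset(parents, m, lt,
                               autofill_siblings = autofill_siblings))
}

# the worked four-strain instance: five compatible pairs plus one
# incompatible pair with a common-A OWE-SOJ record
four_strain_dataset <- function() {
  parents <- data.frame(
    strain_id = c("s1", "s2", "s3", "s4"),
    dikaryon_id = c("D1", "D1", "D2", "D3"))
  pairs <- data.frame(
    strain_a = c("s1", "s1", "s1", "s2", "s2", "s3"),
    strain_b = c("s2", "s3", "s4", "s3", "s4", "s4"),
    result = c(rep("compatible", 5), "incompatible"),
    owe_soj = c(rep("", 5), "AeqBne"),
    stringsAsFactors = FALSE)
  make_dataset(parents, pairs)
}

# canonical signature of an assignment, for set comparisons
asg_sig <- function(g) paste(c(g$a, g$b), collapse = ",")

sig_set <- function(result)
  sort(vapply(result$assignments, asg_sig, ""))

same_assignment <- function(g1, g2) {
  c1 <- canonicalize(g1); c2 <- canonicalize(g2)
  identical(unname(c1$a), unname(c2$a)) &&
    identical(unname(c1$b), unname(c2$b)) &&
    identical(names(c1$a), names(c2$a))
}

truth_in_optima <- function(result, truth) {
  any(vapply(result$assignments, same_assignment, TRUE,
             g2 = truth$assignment))
}

# random small population + derived observations + optional injected errors
random_small_case <- function(seed, n_dik = 3L, pool = 4L,
                              n_fp = 0L, n_fn = 0L) {
  cfg <- population_config(n_dik, "pools", a_pool = pool, b_pool = pool,
                           seed = seed)
  truth <- generate_population(cfg)
  ds <- derive_observations(truth)
  if (n_fp || n_fn) {
    inj <- tryCatch(
      inject_errors(ds, truth, n_fp = n_fp, n_fn = n_fn, seed = seed + 7L),
      error = function(e) NULL)
    if (is.null(inj)) return(NULL) # draw lacked eligible pairs
    return(list(truth = truth, dataset = inj$dataset,
                record = inj$record))
  }
  list(truth = truth, dataset = ds,
       record = list(injected_fp = NULL, injected_fn = NULL))
}
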