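# Synthetic monokaryon populations, derivation of error-free observations
# from a ground-truth assignment, false-positive / false-negative
# injection into the compatibility matrix, and the perturbation experiment
# grid.

# run code with a private, seeded RNG stream; caller's RNG is untouched
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic population configuration
#'
#' Describes a population of protoplast-derived monokaryons:
#' `n_dikaryons` dikaryons each yielding two sibling monokaryons whose
#' true (A, B) allele pairs differ at both loci.
#'
#' Three draw modes are available. `"all_distinct"` gives every strain
#' unique alleles at both loci (every non-sibling cross compatible; the
#' clean analytic setting). `"pools"` draws alleles uniformly from pools
#' of `a_pool`/`b_pool` distinct alleles, resampling each dikaryon until
#' its two monokaryons differ at both loci; cross-dikaryon sharing arises
#' naturally when the pools are smaller than twice `n_dikaryons`.
#' `"paired"` starts from all-distinct alleles and then makes
#' `n_share_a` disjoint non-sibling strain pairs share an A allele and
#' `n_share_b` further disjoint pairs share a B allele, so every shared
#' allele class has exactly two members; the default (15 dikaryons, 6 A-
#' and 4 B-sharing pairs) emulates the structure of a real 30-monokaryon
#' population with 10 incompatible pairs among 435.
#'
#' @param n_dikaryons Number of dikaryons (strains = 2x this).
#' @param mode `"all_distinct"`, `"pools"` or `"paired"`.
#' @param a_pool,b_pool Pool sizes for `"pools"` mode (>= 2).
#' @param n_share_a,n_share_b Number of sharing pairs for `"paired"` mode.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `population_config` list.
#' @export
population_config <- function(n_dikaryons = 15L,
                              mode = c("all_distinct", "pools", "paired"),
                              a_pool = NULL, b_pool = NULL,
                              n_share_a = 6L, n_share_b = 4L,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_dikaryons >= 1L)
  if (mode == "pools") {
    if (is.null(a_pool) || is.null(b_pool))
      stop("pools mode requires a_pool and b_pool")
    stopifnot(a_pool >= 2L, b_pool >= 2L)
  }
  out <- list(n_dikaryons = as.integer(n_dikaryons), mode = mode,
              a_pool = a_pool, b_pool = b_pool,
              n_share_a = as.integer(n_share_a),
              n_share_b = as.integer(n_share_b),
              seed = as.integer(seed))
  class(out) <- "population_config"
  out
}

#' Generate a synthetic monokaryon population with known mating types
#'
#' @param cfg A [population_config()].
#' @return An `mti_truth` list: `assignment` (the true
#'   [mti_assignment()]), `parents` (the [parent_table()]) and `config`.
#' @export
generate_population <- function(cfg) {
  n <- 2L * cfg$n_dikaryons
  w <- max(2L, nchar(as.character(n)))
  strains <- sprintf(paste0("m%0", w, "d"), seq_len(n))
  dik <- sprintf(paste0("D%0", w, "d"), rep(seq_len(cfg$n_dikaryons),
                                            each = 2L))
  parents <- parent_table(strains, dik)
  a <- integer(n); b <- integer(n)
  .with_seed(cfg$seed, {
    if (cfg$mode == "all_distinct") {
      a <- seq_len(n); b <- seq_len(n)
    } else if (cfg$mode == "pools") {
      for (d in seq_len(cfg$n_dikaryons)) {
        i <- 2L * d - 1L; j <- 2L * d
        repeat {
          draw <- c(sample.int(cfg$a_pool, 2L, replace = TRUE),
                    sample.int(cfg$b_pool, 2L, replace = TRUE))
          if (draw[1L] != draw[2L] && draw[3L] != draw[4L]) break
        }
        a[i] <- draw[1L]; a[j] <- draw[2L]
        b[i] <- draw[3L]; b[j] <- draw[4L]
      }
    } else { # paired
      a <- seq_len(n); b <- seq_len(n)
      need <- 2L * (cfg$n_share_a + cfg$n_share_b)
      if (need > n)
        stop("paired mode: not enough strains for ",
             cfg$n_share_a + cfg$n_share_b, " disjoint sharing pairs")
      pool <- sample.int(n) # random strain order
      # draw disjoint non-sibling pairs from the shuffled pool
      pick_pairs <- function(k, avoid_dik) {
        pairs <- list()
        while (length(pairs) < k) {
          if (length(pool) < 2L)
            stop("paired mode: could not place disjoint non-sibling pairs")
          i <- pool[1L]
          partner <- which(dik[pool] != dik[i])[1L]
          if (is.na(partner))
            stop("paired mode: could not place disjoint non-sibling pairs")
          j <- pool[partner]
          pool <<- setdiff(pool, c(i, j))
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
        pairs
      }
      for (pr in pick_pairs(cfg$n_share_a)) a[pr[2L]] <- a[pr[1L]]
      for (pr in pick_pairs(cfg$n_share_b)) b[pr[2L]] <- b[pr[1L]]
    }
  })
  asg <- mti_assignment(stats::setNames(a, strains),
                        stats::setNames(b, strains))
  out <- list(assignment = asg, parents = parents, config = cfg)
  class(out) <- "mti_truth"
  out
}

#' Derive complete error-free observations from a ground truth
#'
#' Every unordered pair is observed: compatible iff the strains differ at
#' both loci, incompatible otherwise, in which case the OWE-SOJ record
#' implied by the true allele identities is attached (common-A/different-B,
#' different-A/common-B, or common at both).
#'
#' @param truth An `mti_truth` from [generate_population()].
#' @return An [mti_dataset()] with a complete matrix and no missing pairs.
#' @export
derive_observations <- function(truth) {
  asg <- truth$assignment
  strains <- names(asg$a)
  n <- length(strains)
  cmb <- utils::combn(n, 2L)
  i <- cmb[1L, ]; j <- cmb[2L, ]
  sameA <- asg$a[i] == asg$a[j]
  sameB <- asg$b[i] == asg$b[j]
  compat <- !sameA & !sameB
  m <- compat_matrix(strains[i], strains[j],
                     ifelse(compat, "compatible", "incompatible"),
                     strains)
  inc <- which(!compat)
  lt <- loci_table(strains[i[inc]], strains[j[inc]],
                   ifelse(sameA[inc], "same", "different"),
                   ifelse(sameB[inc], "same", "different"))
  mti_dataset(truth$parents, m, lt, autofill_siblings = FALSE)
}

#' Inject false-positive / false-negative records
#'
#' A false positive turns a uniformly chosen truly-incompatible pair into
#' a compatible record and deletes its OWE-SOJ record (a pair scored
#' compatible would never enter the OWE-SOJ assay). A false negative
#' turns a uniformly chosen truly-compatible non-sibling pair into an
#' incompatible record with no OWE-SOJ record attached (assays are only
#' performed downstream of an apparent incompatibility). Selections are
#' without replacement and reproducible from the seed.
#'
#' @param ds The error-free [mti_dataset()] derived from `truth`.
#' @param truth The `mti_truth` the dataset was derived from.
#' @param n_fp,n_fn Number of false positives / negatives to inject.
#' @param seed Integer seed.
#' @return List: `dataset` (perturbed), `record` (list with data.frames
#'   `injected_fp`, `injected_fn` of canonical pair keys).
#' @export
inject_errors <- function(ds, truth, n_fp = 0L, n_fn = 0L, seed = 1L) {
  asg <- truth$assignment
  m <- ds$matrix
  truly_inc <- asg$a[m$strain_a] == asg$a[m$strain_b] |
               asg$b[m$strain_a] == asg$b[m$strain_b]
  sibs <- sibling_pairs(truth$parents)
  sib_keys <- paste(sibs$strain_a, sibs$strain_b, sep = "\t")
  keys <- paste(m$strain_a, m$strain_b, sep = "\t")
  elig_fp <- which(m$result == "incompatible" & truly_inc)
  elig_fn <- which(m$result == "compatible" & !truly_inc &
                     !keys %in% sib_keys)
  if (n_fp > length(elig_fp))
    stop("not enough truly-incompatible pairs for ", n_fp,
         " false positives")
  if (n_fn > length(elig_fn))
    stop("not enough truly-compatible non-sibling pairs for ", n_fn,
         " false negatives")
  .with_seed(seed, {
    fp <- if (n_fp)
      sort(elig_fp[sample.int(length(elig_fp), n_fp)]) else integer()
    fn <- if (n_fn)
      sort(elig_fn[sample.int(length(elig_fn), n_fn)]) else integer()
  })
  res <- m$result
  res[fp] <- "compatible"
  res[fn] <- "incompatible"
  m2 <- compat_matrix(m$strain_a, m$strain_b, res, attr(m, "strains"))
  lt <- ds$loci
  if (length(fp) && nrow(lt)) {
    drop <- paste(lt$strain_a, lt$strain_b, sep = "\t") %in% keys[fp]
    lt <- lt[!drop, , drop = FALSE]
    class(lt) <- c("loci_table", "data.frame")
  }
  pk_df <- function(ix) data.frame(strain_a = m$strain_a[ix],
                                   strain_b = m$strain_b[ix],
                                   stringsAsFactors = FALSE)
  list(dataset = mti_dataset(ds$parents, m2, lt,
                             autofill_siblings = FALSE),
       record = list(injected_fp = pk_df(fp), injected_fn = pk_df(fn)))
}

#' Run the error-perturbation experiment grid
#'
#' For each error type, error count `k` and replicate: generate a
#' population, derive complete error-free observations, inject `k` errors,
#' infer mating types, and record how the optimum relates to the truth
#' and whether the flagged suspect records identify the injected pairs.
#'
#' @param pop_cfg A [population_config()] (its seed is ignored; replicate
#'   seeds are drawn from `seed`).
#' @param k_values Error counts to test (default 1..5).
#' @param reps Replicates per condition (default 50).
#' @param policy Inference policy (default `"evidence"`).
#' @param error_types Subset of `c("fn", "fp")`.
#' @param seed Master seed for the whole grid.
#' @return An `experiment_table` data.frame with one row per replicate:
#'   `error_type`, `k`, `replicate`, `best_score`, `max_score`,
#'   `truth_score`, `n_optima`, `n_flagged`, `truth_recovered`,
#'   `detection_exact`.
#' @export
run_error_experiment <- function(pop_cfg, k_values = 1:5, reps = 50L,
                                 policy = "evidence",
                                 error_types = c("fn", "fp"),
                                 seed = 1L) {
  error_types <- match.arg(error_types, c("fn", "fp"), several.ok = TRUE)
  n_cond <- length(error_types) * length(k_values) * reps
  seeds <- .with_seed(seed,
    matrix(sample.int(2^30, 2L * n_cond), ncol = 2L))
  rows <- vector("list", n_cond)
  r <- 0L
  for (et in error_types) for (k in k_values) for (rep_i in seq_len(reps)) {
    r <- r + 1L
    gen_seed <- seeds[r, 1L]
    # regenerate (bounded) if the draw lacks eligible pairs to perturb
    for (try in 0:99) {
      cfg <- pop_cfg; cfg$seed <- gen_seed + try
      truth <- generate_population(cfg)
      ds0 <- derive_observations(truth)
      inj <- tryCatch(
        inject_errors(ds0, truth,
                      n_fp = if (et == "fp") k else 0L,
                      n_fn = if (et == "fn") k else 0L,
                      seed = seeds[r, 2L]),
        error = function(e) NULL)
      if (!is.null(inj)) break
    }
    if (is.null(inj))
      stop("could not generate a population with ", k,
           " eligible ", et, " pairs")
    res <- infer_mating_types(inj$dataset,
                              inference_config(policy = policy))
    ctruth <- canonicalize(truth$assignment)
    tkey <- .asg_key(ctruth$a, ctruth$b)
    akeys <- vapply(res$assignments, function(g) .asg_key(g$a, g$b), "")
    injected <- rbind(inj$record$injected_fp, inj$record$injected_fn)
    ikeys <- paste(injected$strain_a, injected$strain_b, sep = "\t")
    fkeys <- paste(res$flagged_pairs$strain_a, res$flagged_pairs$strain_b,
                   sep = "\t")
    rows[[r]] <- data.frame(
      error_type = et, k = k, replicate = rep_i,
      best_score = res$best_score, max_score = res$max_score,
      truth_score = score_assignment(truth$assignment, inj$dataset)$total,
      n_optima = length(res$assignments),
      n_flagged = nrow(res$flagged_pairs),
      truth_recovered = tkey %in% akeys,
      detection_exact = setequal(fkeys, ikeys) && length(ikeys) > 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("experiment_table", "data.frame")
  out
}
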