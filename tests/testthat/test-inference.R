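# Branch-and-bound traversal: seeding, candidate generation,
# canonicalization, optimum search and suspect-record flagging.

test_that("starting pair defaults to the first two-strain dikaryon", {
  parents <- data.frame(strain_id = c("m1", "m2", "m3", "m4"),
                        dikaryon_id = c("D2", "D2", "D1", "D1"))
  pairs <- data.frame(strain_a = c("m1", "m3"), strain_b = c("m2", "m4"),
                      result = "compatible")
  ds <- make_dataset(parents, pairs)
  expect_setequal(select_starting_pair(ds), c("m3", "m4")) # D1 < D2
  cfg <- inference_config(starting_pair = c("m1", "m2"))
  expect_setequal(select_starting_pair(ds, cfg), c("m1", "m2"))
  expect_error(select_starting_pair(ds, inference_config(
    starting_pair = c("m1", "m3"))), "one dikaryon")

  solo <- make_dataset(
    data.frame(strain_id = c("m1", "m2"), dikaryon_id = c("D1", "D2")),
    data.frame(strain_a = "m1", strain_b = "m2", result = "compatible"))
  expect_error(select_starting_pair(solo), "no complete sibling pair")
})

test_that("clique seeding is greedy in identifier order", {
  parents <- data.frame(strain_id = paste0("s", 1:5),
                        dikaryon_id = c("D1", "D1", "D2", "D2", "D3"))
  cmb <- t(combn(paste0("s", 1:5), 2))
  pairs <- data.frame(strain_a = cmb[, 1], strain_b = cmb[, 2],
                      result = "compatible")
  ds <- make_dataset(parents, pairs)
  expect_equal(seed_compatible_clique(ds, c("s1", "s2")), paste0("s", 1:5))

  # an incompatible pair excludes the later strain
  pairs$result[pairs$strain_a == "s3" & pairs$strain_b == "s4"] <-
    "incompatible"
  ds <- make_dataset(parents, pairs)
  expect_equal(seed_compatible_clique(ds, c("s1", "s2")),
               c("s1", "s2", "s3", "s5"))

  # a missing observation also excludes
  pairs2 <- pairs[!(pairs$strain_a == "s2" & pairs$strain_b == "s5"), ]
  ds <- make_dataset(parents, pairs2)
  expect_equal(seed_compatible_clique(ds, c("s1", "s2")),
               c("s1", "s2", "s3"))
})

test_that("candidate alleles require evidence unless the policy is free", {
  ds <- four_strain_dataset()
  partial <- list(a = c(s1 = 1L, s2 = 2L, s3 = 3L, s4 = NA),
                  b = c(s1 = 1L, s2 = 2L, s3 = 3L, s4 = NA))
  # record (s3,s4) marks A same: s3's label plus a fresh one
  expect_equal(candidate_alleles("s4", "A", partial, ds, "evidence"),
               c(3L, 4L))
  # no B-locus evidence: fresh only
  expect_equal(candidate_alleles("s4", "B", partial, ds, "evidence"), 4L)
  # free policy offers every existing label, ascending, fresh last
  expect_equal(candidate_alleles("s4", "A", partial, ds, "free"),
               c(1L, 2L, 3L, 4L))
  expect_error(candidate_alleles("s1", "A", partial, ds), "already assigned")
})

test_that("canonicalization is first-appearance relabeling and idempotent", {
  g <- list(a = c(m1 = 7L, m2 = 7L, m3 = 4L), b = c(m1 = 9L, m2 = 4L,
                                                    m3 = 9L))
  cg <- canonicalize(g)
  expect_equal(unname(cg$a), c(1L, 1L, 2L))
  expect_equal(unname(cg$b), c(1L, 2L, 1L))
  expect_equal(canonicalize(cg), cg)
  # label permutations of one partition map to the same canonical form
  g2 <- list(a = c(m1 = 2L, m2 = 2L, m3 = 9L), b = c(m1 = 1L, m2 = 5L,
                                                     m3 = 1L))
  expect_equal(canonicalize(g2), cg)
  expect_error(canonicalize(list(a = c(m1 = 1L, m2 = NA),
                                 b = c(m1 = 1L, m2 = 1L))), "partial")
})

test_that("smallest instance: two compatible siblings", {
  parents <- data.frame(strain_id = c("m1", "m2"),
                        dikaryon_id = c("D1", "D1"))
  pairs <- data.frame(strain_a = "m1", strain_b = "m2",
                      result = "compatible")
  res <- infer_mating_types(make_dataset(parents, pairs))
  expect_equal(res$best_score, 2L)
  expect_equal(res$max_score, 2L)
  expect_equal(length(res$assignments), 1L)
  expect_equal(unname(res$assignments[[1]]$a), c(1L, 2L))
  expect_equal(unname(res$assignments[[1]]$b), c(1L, 2L))
})

test_that("worked four-strain instance has the expected unique optimum", {
  ds <- four_strain_dataset()
  res <- infer_mating_types(ds)
  expect_equal(res$best_score, 12L)
  expect_equal(res$max_score, 12L)
  expect_equal(length(res$assignments), 1L)
  g <- res$assignments[[1]]
  expect_equal(g$a[["s3"]], g$a[["s4"]])       # shared A class
  expect_equal(length(unique(g$b)), 4L)        # all B distinct
  expect_equal(unname(res$allele_counts[1, ]), c(3L, 4L))
  expect_equal(nrow(res$flagged_pairs), 0L)
  # matches the exhaustive oracle
  or <- brute_force_infer(ds, "evidence")
  expect_equal(or$best_score, 12L)
  expect_equal(sig_set(or), sig_set(res))
})

test_that("co-optimal assignments are collected, deduplicated and capped", {
  # two incompatible pairs without records admit symmetric optimal
  # explanations (share at A or at B)
  parents <- data.frame(strain_id = c("m1", "m2", "m3"),
                        dikaryon_id = c("D1", "D1", "D2"))
  pairs <- data.frame(strain_a = c("m1", "m1", "m2"),
                      strain_b = c("m2", "m3", "m3"),
                      result = c("compatible", "incompatible",
                                 "incompatible"))
  ds <- make_dataset(parents, pairs)
  res <- infer_mating_types(ds, inference_config(policy = "free"))
  or <- brute_force_infer(ds, "free")
  expect_equal(res$best_score, or$best_score)
  expect_equal(sig_set(res), sig_set(or))
  expect_gt(length(res$assignments), 1L)
  expect_false(res$truncated)
  # cap respected
  capped <- infer_mating_types(ds, inference_config(policy = "free",
                                                    max_optima = 1L))
  expect_equal(length(capped$assignments), 1L)
  expect_true(capped$truncated)
})

test_that("inference is deterministic and input-order independent", {
  case <- random_small_case(77, n_dik = 3, pool = 4, n_fn = 1)
  ds <- case$dataset
  r1 <- infer_mating_types(ds)
  r2 <- infer_mating_types(ds)
  expect_identical(sig_set(r1), sig_set(r2))
  expect_identical(r1$n_enumerated, r2$n_enumerated)
  # permute observation rows and parent rows
  set.seed(5)
  m <- ds$matrix; o <- sample(nrow(m))
  m2 <- compat_matrix(m$strain_a[o], m$strain_b[o], m$result[o],
                      attr(m, "strains"))
  po <- sample(nrow(ds$parents))
  p2 <- parent_table(ds$parents$strain_id[po], ds$parents$dikaryon_id[po])
  ds2 <- mti_dataset(p2, m2, ds$loci, autofill_siblings = FALSE)
  r3 <- infer_mating_types(ds2)
  expect_identical(sig_set(r1), sig_set(r3))
  expect_equal(r1$best_score, r3$best_score)
})

test_that("suspect records: injected false negative flagged, clean data not", {
  cfg <- population_config(5, "all_distinct", seed = 2)
  truth <- generate_population(cfg)
  ds <- derive_observations(truth)
  res <- infer_mating_types(ds)
  expect_equal(nrow(res$flagged_pairs), 0L)

  inj <- inject_errors(ds, truth, n_fn = 1, seed = 12)
  res <- infer_mating_types(inj$dataset)
  expect_equal(res$flagged_pairs$strain_a, inj$record$injected_fn$strain_a)
  expect_equal(res$flagged_pairs$strain_b, inj$record$injected_fn$strain_b)
  expect_equal(res$flagged_pairs$reason, "possible_false_negative")

  inj <- inject_errors(derive_observations(truth), truth, n_fp = 0,
                       n_fn = 0, seed = 3)
  expect_equal(nrow(inj$record$injected_fp), 0L)
})

test_that("evidence policy only merges classes connected by records", {
  # truth A-class {x, y, z}; deleting the x-y record (false positive)
  # leaves an inconsistent expectation triangle: the engine must still
  # reach the grouped class through the connector z (merge move)
  parents <- data.frame(strain_id = c("x", "y", "z", "w"),
                        dikaryon_id = c("D1", "D2", "D3", "D1"))
  pairs <- data.frame(
    strain_a = c("x", "x", "x", "y", "y", "z"),
    strain_b = c("y", "z", "w", "z", "w", "w"),
    result = c("compatible", "incompatible", "compatible",
               "incompatible", "compatible", "compatible"),
    owe_soj = c("", "AeqBne", "", "AeqBne", "", ""),
    stringsAsFactors = FALSE)
  ds <- make_dataset(parents, pairs)
  res <- infer_mating_types(ds)
  or <- brute_force_infer(ds, "evidence")
  expect_equal(res$best_score, or$best_score)
  expect_equal(sig_set(res), sig_set(or))
  # the inconsistent triangle costs exactly 2 and admits three co-optima
  expect_equal(res$best_score, res$max_score - 2L)
  expect_equal(length(res$assignments), 3L)
  grouped <- vapply(res$assignments, function(g)
    length(unique(g$a[c("x", "y", "z")])) == 1L, TRUE)
  expect_true(any(grouped))
})
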