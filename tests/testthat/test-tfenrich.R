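# small deterministic loop set for geometry tests
toy_loops <- function() {
  data.table::data.table(
    chrom = "chr1",
    start1 = c(100000L, 300000L), end1 = c(101000L, 301000L),
    start2 = c(200000L, 500000L), end2 = c(201000L, 501000L),
    pet_count = 20L, p_value = 1e-6, enrichment_score = 5,
    distance = c(100000, 200000), id = c("l1", "l2"))
}

test_that("background regions step outward and avoid true anchors", {
  bg <- build_background_regions(toy_loops()[1])
  expect_equal(nrow(bg), 3L)
  expect_equal(bg$step, 1:3)
  # left regions step upstream by one anchor width each
  expect_equal(bg$start1, 100000L - 1000L * 1:3)
  expect_equal(bg$start2, 200000L + 1000L * 1:3)
  # a false pair overlapping a true anchor is removed as a whole
  close_loops <- data.table::copy(toy_loops())
  close_loops$start1[2] <- 97500L; close_loops$end1[2] <- 98500L
  close_loops$start2[2] <- 203500L; close_loops$end2[2] <- 204500L
  bg2 <- build_background_regions(close_loops)
  # loop 1's step-3 left window [97000,98000) hits loop 2's left anchor
  expect_false(any(bg2$loop_id == "l1" & bg2$step == 3L))
  # a loop at the chromosome start yields fewer pairs
  edge <- data.table::copy(toy_loops()[1])
  edge$start1 <- 1500L; edge$end1 <- 2500L
  expect_equal(nrow(build_background_regions(edge)), 1L)
})

test_that("binding matrix matches a quadratic overlap oracle", {
  with_seed(90, {
    regions <- data.table::data.table(
      chrom = "chr1", start = sort(sample.int(1e6, 50)) )
    regions$end <- regions$start + sample(200:2000, 50, TRUE)
    peak_sets <- list(
      tf_a = data.table::data.table(chrom = "chr1",
                                    start = sample.int(1e6, 80)),
      tf_b = data.table::data.table(chrom = "chr1",
                                    start = sample.int(1e6, 5)),
      tf_empty = data.table::data.table(chrom = character(),
                                        start = integer(),
                                        end = integer()))
    peak_sets$tf_a$end <- peak_sets$tf_a$start + 300L
    peak_sets$tf_b$end <- peak_sets$tf_b$start + 300L
  })
  m <- build_binding_matrix(regions, peak_sets)
  expect_true(all(m[, "tf_empty"] == 0L))
  for (f in c("tf_a", "tf_b")) {
    pk <- peak_sets[[f]]
    oracle <- vapply(seq_len(nrow(regions)), function(i)
      as.integer(any(pk$start < regions$end[i] &
                       pk$end > regions$start[i])), integer(1))
    expect_equal(unname(m[, f]), oracle)
  }
  # peak spanning a whole region binds it
  span <- build_binding_matrix(
    data.table::data.table(chrom = "chr1", start = 500L, end = 600L),
    list(big = data.table::data.table(chrom = "chr1", start = 0L,
                                      end = 10000L)))
  expect_equal(unname(span[1, 1]), 1L)
})

test_that("anchor consistency equals the phi coefficient on binary data", {
  expect_equal(anchors_consistency(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(anchors_consistency(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_true(is.na(anchors_consistency(c(1, 1, 1), c(1, 0, 1))))
  with_seed(91, {
    for (k in 1:50) {
      a <- rbinom(200, 1, runif(1, 0.2, 0.8))
      b <- rbinom(200, 1, runif(1, 0.2, 0.8))
      if (sd(a) == 0 || sd(b) == 0) next
      expect_lt(abs(anchors_consistency(a, b) - phi_coefficient(a, b)),
                1e-12)
    }
    # independent vectors: correlation concentrates near 0
    rho <- replicate(50, anchors_consistency(rbinom(1000, 1, 0.3),
                                             rbinom(1000, 1, 0.3)))
    expect_gte(mean(abs(rho) < 0.1), 0.98)
  })
})

tf_sim <- function(seed = 101L, n_loops = 150L) {
  cfg <- sim_config(chrom_length = 2e7, n_peaks = 600L, n_loops = n_loops,
                    pets_per_loop = c(5L, 10L), n_background_pets = 1000L,
                    tf_specs = list(
                      list(name = "planted", p_cobind_true = 0.8,
                           p_bind_background = 0.1),
                      list(name = "indep", p_cobind_true = 0,
                           p_bind_background = 0.3),
                      list(name = "absent", p_cobind_true = 0,
                           p_bind_background = 0)),
                    seed = seed)
  simulate_dataset(cfg)
}

test_that("score_factors separates planted, independent and absent factors", {
  sim <- cache_get("tfsim", function() tf_sim())
  loops <- truth_as_loops(sim)
  rec <- score_factors(loops, sim$tf_peaks)
  planted <- rec[factor_name == "planted"]
  indep <- rec[factor_name == "indep"]
  absent <- rec[factor_name == "absent"]
  expect_true(planted$pass)
  expect_gt(planted$cobind_ratio, 0.5)
  expect_false(isTRUE(indep$pass))     # consistency ratio <= 2
  expect_false(isTRUE(absent$pass))    # cobind 0
  expect_equal(absent$cobind_ratio, 0)
})

test_that("permutation FDR is reproducible and separates factors", {
  sim <- cache_get("tfsim", function() tf_sim())
  loops <- truth_as_loops(sim)
  rec <- score_factors(loops, sim$tf_peaks)
  f1 <- permutation_fdr(attr(rec, "left_mat"), attr(rec, "right_mat"),
                        n_shuffles = 200, seed = 5)
  f2 <- permutation_fdr(attr(rec, "left_mat"), attr(rec, "right_mat"),
                        n_shuffles = 200, seed = 5)
  expect_identical(f1, f2)
  expect_equal(f1[factor_name == "planted"]$fdr_consistency, 0)
  expect_gt(f1[factor_name == "indep"]$fdr_consistency, 0.01)
})

test_that("rank_report orders passing factors by consistency", {
  rec <- data.table::data.table(
    factor_name = c("a", "b", "c", "d"),
    consistency = c(0.2, 0.9, 0.9, 0.5),
    cobind_ratio = c(0.5, 0.3, 0.6, 0.2),
    pass = c(TRUE, TRUE, TRUE, FALSE))
  rk <- rank_report(rec)
  expect_equal(rk$factor_name, c("c", "b", "a", "d"))  # tie by cobind
  # empty pass set: table still emitted
  rec$pass <- FALSE
  expect_equal(nrow(rank_report(rec)), 4L)
})

test_that("tf_enrichment ranks the planted factor first", {
  sim <- cache_get("tfsim", function() tf_sim())
  loops <- truth_as_loops(sim)
  rec <- tf_enrichment(loops, sim$tf_peaks, n_shuffles = 200, seed = 5)
  expect_equal(rec$factor_name[1], "planted")
  expect_true(rec$pass[1])
  expect_equal(sum(rec$pass), 1L)
})
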