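test_that("dbscan2d finds dense groups and marks isolated points as noise", {
  with_seed(10, {
    core <- cbind(5000 + runif(20, 0, 50), 9000 + runif(20, 0, 50))
    iso <- cbind(seq(50000, 90000, length.out = 5),
                 seq(150000, 190000, length.out = 5))
  })
  x <- c(core[, 1], iso[, 1]); y <- c(core[, 2], iso[, 2])
  lab <- dbscan2d(x, y, eps = 200, minPts = 10)
  expect_equal(sum(!is.na(lab)), 20L)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_true(all(is.na(lab[21:25])))
  # minPts > n: all noise
  expect_true(all(is.na(dbscan2d(x, y, eps = 200, minPts = 26))))
})

test_that("grid DBSCAN partition is identical to the naive oracle", {
  with_seed(20, {
    for (trial in 1:10) {
      n <- sample(50:200, 1)
      eps <- runif(1, 100, 3000)
      minPts <- sample(3:20, 1)
      x <- runif(n, 0, 50000)
      y <- x + runif(n, 0, 20000)
      expect_identical(dbscan2d(x, y, eps, minPts),
                       dbscan_naive(x, y, eps, minPts))
    }
  })
})

test_that("auto_max_cut keeps a pure power-law decay and trims flat noise", {
  with_seed(30, {
    d_pow <- petloops:::rpowerlaw(50000, 1.5, 1000, 1e7)
    d_flat <- runif(30000, 1e6, 1e7)  # distance-independent noise floor
  })
  # pure decay: never flattens, cutoff = max distance
  expect_equal(auto_max_cut(d_pow), max(d_pow))
  # decay + flat background: cutoff lands before the flat regime dominates
  cut <- auto_max_cut(c(d_pow, d_flat))
  expect_lt(cut, 5e6)
  expect_gt(cut, 1e4)
})

test_that("call_candidates recovers a planted cluster and honours cut", {
  with_seed(40, {
    lx <- rnorm(30, 1.00e6, 150); ly <- rnorm(30, 1.20e6, 150)
  })
  p <- pets(chrom1 = "chr1", start1 = round(lx) - 25, end1 = round(lx) + 25,
            chrom2 = "chr1", start2 = round(ly) - 25, end2 = round(ly) + 25)
  idx <- pet_index(p)
  cand <- call_candidates(idx, eps_list = 500, minPts = 10)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$start1 <= 1.00e6 && cand$end1 >= 1.00e6)
  expect_true(cand$start2 <= 1.20e6 && cand$end2 >= 1.20e6)
  expect_equal(cand$member_count, 30L)
  # all PETs below cut: nothing to cluster
  expect_equal(nrow(call_candidates(idx, eps_list = 500, minPts = 10,
                                    cut = 5e5)), 0L)
})

test_that("test_candidate Poisson tail matches direct PMF summation", {
  sim <- small_fixture()
  idx <- small_index()
  tl <- sim$truth$loops[1]
  cand <- list(chrom = tl$chrom, start1 = tl$start1, end1 = tl$end1,
               start2 = tl$start2, end2 = tl$end2)
  res <- test_candidate(idx, cand)
  expect_gt(res$n_obs, 0)
  expect_equal(res$p_value,
               poisson_tail_naive(res$n_obs, res$lambda), tolerance = 1e-12)
  expect_equal(res$enrichment_score, res$n_obs / res$lambda)
  # n_obs = 0 in an empty corner -> p = 1
  res0 <- test_candidate(idx, list(chrom = tl$chrom, start1 = 10,
                                   end1 = 1010, start2 = 1.95e6,
                                   end2 = 1.951e6))
  expect_equal(res0$n_obs, 0L)
  expect_equal(res0$p_value, 1)
})

test_that("enrichment scores on uniform random PETs centre near 1", {
  p <- random_pets(20000, seed = 55, L = 2e6)
  idx <- pet_index(p)
  with_seed(56, {
    es <- replicate(40, {
      s1 <- runif(1, 2e5, 8e5); s2 <- runif(1, 1.2e6, 1.7e6)
      r <- test_candidate(idx, list(chrom = "chrT", start1 = s1,
                                    end1 = s1 + 20000, start2 = s2,
                                    end2 = s2 + 20000))
      r$enrichment_score
    })
  })
  expect_gt(mean(es, na.rm = TRUE), 0.6)
  expect_lt(mean(es, na.rm = TRUE), 1.4)
})

test_that("call_loops merges multi-eps candidates and filters properly", {
  sim <- small_fixture()
  idx <- small_index()
  loops <- call_loops(idx, eps_list = c(200, 500), minPts = 10, cut = 5000)
  expect_gt(nrow(loops), 0)
  # merging: no two reported loops may overlap on both anchors
  if (nrow(loops) > 1) {
    for (i in seq_len(nrow(loops) - 1)) {
      for (j in (i + 1):nrow(loops)) {
        both <- loops$start1[i] < loops$end1[j] &&
          loops$start1[j] < loops$end1[i] &&
          loops$start2[i] < loops$end2[j] &&
          loops$start2[j] < loops$end2[i]
        expect_false(both)
      }
    }
  }
  # monotonicity: raising min_pets never increases the call count
  n_prev <- Inf
  for (mp in c(10, 20, 40)) {
    n_now <- nrow(call_loops(idx, eps_list = c(200, 500), minPts = 10,
                             cut = 5000, min_pets = mp))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("estimate_resolution matches a hash-count oracle", {
  p <- random_pets(2000, seed = 60, L = 5e5)
  idx <- pet_index(p)
  res <- estimate_resolution(idx, c(200, 1000, 5000))
  # oracle: count PETs in bin pairs with >= 2 members
  m1 <- floor((p$start1 + p$end1) / 2); m2 <- floor((p$start2 + p$end2) / 2)
  for (k in seq_len(nrow(res))) {
    bs <- res$bin_size[k]
    key <- paste(floor(m1 / bs), floor(m2 / bs))
    expect_equal(res$fraction_non_singleton[k],
                 mean(table(key)[key] >= 2))
  }
  # monotone in bin size (nested bins)
  expect_true(all(diff(res$fraction_non_singleton) >= 0))
  # degenerate cases
  same <- pets(chrom1 = "chr1", start1 = rep(100, 5), end1 = rep(150, 5),
               chrom2 = "chr1", start2 = rep(900, 5), end2 = rep(950, 5))
  expect_equal(estimate_resolution(pet_index(same),
                                   c(200, 1000))$fraction_non_singleton,
               c(1, 1))
})

test_that("overlap_loops applies the 5 kb anchor extension", {
  l1 <- data.table::data.table(chrom = "chr1", start1 = 10000L, end1 = 11000L,
                               start2 = 90000L, end2 = 91000L,
                               pet_count = 20L, p_value = 1e-5,
                               enrichment_score = 5, distance = 80000,
                               id = "a1")
  shift <- function(l, by, to_chrom = "chr1") {
    m <- data.table::copy(l)
    m[, `:=`(chrom = to_chrom, start1 = start1 + by, end1 = end1 + by,
             start2 = start2 + by, end2 = end2 + by, id = "b1")]
    m
  }
  expect_equal(overlap_loops(l1, l1)$both, 1L)
  expect_equal(overlap_loops(l1, shift(l1, 4000))$both, 1L)   # inside 5 kb
  expect_equal(overlap_loops(l1, shift(l1, 12000))$both, 0L)  # beyond
  expect_equal(overlap_loops(l1, shift(l1, 0, "chr2"))$both, 0L)
})
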