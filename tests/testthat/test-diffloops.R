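test_that("poisson_diff_p implements the literal summation formula", {
  # empty sum: fg <= 1 -> p = 1
  expect_equal(poisson_diff_p(1, 0, 0, 0), 1)
  expect_equal(poisson_diff_p(0, 0, 0, 0), 1)
  # fg = 2, lambda = 1 -> 1 - e^-1
  expect_equal(poisson_diff_p(2, 1, 0, 0), 1 - exp(-1), tolerance = 1e-12)
  # brute-force summation oracle over a parameter sweep
  for (fg in c(2, 5, 20, 73)) {
    for (lam in c(0.5, 1, 5, 20)) {
      expect_lt(abs(poisson_diff_p(fg, 0, 0, 0, pseudo = lam) -
                      poisson_diff_p_naive(fg, lam)), 1e-10,
                label = sprintf("fg=%d lambda=%g", fg, lam))
    }
  }
  # lambda takes the max of bg, fgNearby, bgNearby, pseudo
  expect_equal(poisson_diff_p(20, 3, 7, 2), poisson_diff_p_naive(20, 7))
  expect_error(poisson_diff_p(5, -1, 0, 0), "non-negative")
  # exact-tail option drops the stray PMF(0) term
  expect_equal(poisson_diff_p(2, 1, 0, 0, tail_exact = TRUE),
               1 - dpois(0, 1) - dpois(1, 1), tolerance = 1e-12)
})

test_that("poisson_diff_p is monotone in fg and (exact tail) in lambda", {
  p_fg <- poisson_diff_p(2:50, 5, 0, 0)
  expect_true(all(diff(p_fg) <= 1e-15))
  # the literal formula's stray PMF(0) term breaks lambda-monotonicity;
  # the property holds for the standard upper tail
  p_lam <- vapply(1:30, function(l)
    poisson_diff_p(20, l, 0, 0, tail_exact = TRUE), numeric(1))
  expect_true(all(diff(p_lam) >= -1e-15))
})

test_that("fit_background recovers the linear model and validates input", {
  a <- c(rep(0:40, 6))
  expect_equal(fit_background(a, a)$slope, 1, tolerance = 1e-9)
  expect_equal(fit_background(a, a)$intercept, 0, tolerance = 1e-9)
  expect_error(fit_background(1:5, 1:5), "at least 10")
  expect_warning(fit_background(rep(3, 20), rep(3, 20)), "degenerate")
  # doubled treatment: transform approximately halves treatment counts
  with_seed(80, {
    na_ <- rpois(300, 20)
    nb_ <- rpois(300, 2 * na_) # treatment at twice the control depth
  })
  fit <- fit_background(na_, nb_)
  back <- transform_to_control(2 * na_, fit)
  expect_equal(median(back / pmax(na_, 1)), 1, tolerance = 0.15)
})

test_that("find_ma_cutoffs honours the target background FDR", {
  with_seed(81, {
    A_bg <- runif(500, 0, 8)
    M_bg <- rnorm(500, 0, 0.5)
  })
  expect_equal(find_ma_cutoffs(A_bg, M_bg, fdr = 1)[c("a_cut", "m_cut")],
               list(a_cut = 0, m_cut = 0))
  co0 <- find_ma_cutoffs(A_bg, M_bg, fdr = 0)
  expect_equal(mean(A_bg >= co0$a_cut & abs(M_bg) >= co0$m_cut), 0)
  # exceedance at the chosen cutoffs is within the target
  for (fdr in c(0.2, 0.05, 0.01)) {
    co <- find_ma_cutoffs(A_bg, M_bg, fdr)
    frac <- mean(A_bg >= co$a_cut & abs(M_bg) >= co$m_cut)
    expect_lte(frac, fdr)
  }
  # m_cut grows as fdr shrinks on a symmetric null
  cuts <- vapply(c(0.5, 0.1, 0.02),
                 function(f) find_ma_cutoffs(A_bg, M_bg, f)$m_cut,
                 numeric(1))
  expect_true(all(diff(cuts) >= 0))
})

test_that("quantify_pair counts both conditions against the same loops", {
  sim <- small_fixture()
  idx <- small_index()
  loops <- truth_as_loops(sim)
  q <- quantify_pair(idx, idx, loops)
  expect_equal(q$count_a, q$count_b)
  expect_equal(q$nearby_a, q$nearby_b)
  # empty condition B
  qb <- quantify_pair(idx, pet_index(sim$pets_a[0]), loops)
  expect_true(all(qb$count_b == 0))
  # counts match the rectangle oracle
  p <- dedup_pets(sim$pets_a)
  for (k in c(1, 5)) {
    expect_equal(q$count_a[k],
                 rect_count_naive(p, loops$chrom[k], loops$start1[k],
                                  loops$end1[k], loops$start2[k],
                                  loops$end2[k]))
  }
})

test_that("identical conditions produce no differential calls", {
  sim <- small_fixture()
  idx <- small_index()
  loops <- truth_as_loops(sim)
  # with so few loops the 5% background FDR is unattainable (warning path)
  res <- suppressWarnings(diff_loops(idx, idx, loops, loops))
  expect_true(all(res$records$call == "unchanged"))
  expect_equal(res$fit$slope, 1, tolerance = 1e-6)
})

test_that("planted fold changes are recovered with correct direction", {
  fold <- rep(1, 12); fold[c(2, 6, 10)] <- 4
  sim <- cache_get("diff_small", function()
    simulate_dataset(sim_config(chrom_length = 2e6, n_peaks = 80L,
                                n_loops = 12L, pets_per_loop = c(30L, 60L),
                                n_background_pets = 20000L,
                                fold_changes = fold, seed = 31L)))
  ia <- pet_index(dedup_pets(sim$pets_a))
  ib <- pet_index(dedup_pets(sim$pets_b))
  loops <- truth_as_loops(sim)
  res <- suppressWarnings(diff_loops(ia, ib, loops, loops))
  rec <- res$records
  changed <- rec[call != "unchanged"]
  # loops called enriched must be enriched in B (the scaled condition)
  expect_true(all(changed$call == "enriched_in_B"))
  # at least 2 of the 3 planted 4x loops are recovered
  truth_changed <- truth_as_loops(sim)[c(2, 6, 10)]
  hit <- overlap_loops(truth_changed, changed)$both
  expect_gte(hit, 2L)
  # -noPCorr -pcut 0.001 mode calls at least as many
  rec_np <- call_diff_loops(res$records, res$cutoffs, p_cut = 0.001,
                            correct = FALSE)
  expect_gte(sum(rec_np$call != "unchanged"), nrow(changed))
})
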