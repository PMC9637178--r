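toy_ann <- function() {
  regions <- data.table::data.table(
    chrom = "chr1",
    start = c(9500L, 50000L, 50950L, 200000L, 400000L),
    end = c(10500L, 50900L, 51800L, 201000L, 401000L))
  tss <- data.table::data.table(chrom = "chr1", start = c(10000L, 300000L),
                                end = c(10001L, 300001L),
                                name = c("geneA", "geneB"))
  build_annotation(regions, tss)
}

test_that("annotation applies the 2 kb promoter rule and <100 bp merging", {
  ann <- toy_ann()
  # region at the TSS -> promoter; regions 50000-51800 are two enhancers
  # 50 bp apart -> merged into one
  expect_equal(nrow(ann$promoters), 1L)
  expect_equal(ann$promoters$start, 9500L)
  expect_true(any(ann$enhancers$start == 50000L &
                    ann$enhancers$end == 51800L))
  # region 10 kb beyond any TSS stays an enhancer
  expect_true(any(ann$enhancers$start == 400000L))
  # merging is idempotent
  m1 <- petloops:::merge_intervals(ann$enhancers, gap = 100)
  expect_equal(m1, ann$enhancers)
  # region 500 bp from a TSS is a promoter
  ann2 <- build_annotation(
    data.table::data.table(chrom = "chr1", start = 10500L, end = 11000L),
    data.table::data.table(chrom = "chr1", start = 10000L, end = 10001L))
  expect_equal(nrow(ann2$promoters), 1L)
})

mk_loop <- function(s1, s2, w = 1000L) {
  data.table::data.table(chrom = "chr1", start1 = s1, end1 = s1 + w,
                         start2 = s2, end2 = s2 + w, pet_count = 10L,
                         p_value = 1e-4, enrichment_score = 3,
                         distance = s2 - s1, id = paste0("L", s1, "_", s2))
}

test_that("classify_loop labels anchors with promoter priority", {
  ann <- toy_ann()
  expect_equal(classify_loop(mk_loop(9500L, 50000L), ann), "E-P")
  expect_equal(classify_loop(mk_loop(50000L, 400000L), ann), "E-E")
  expect_equal(classify_loop(mk_loop(9500L, 700000L), ann), "P-other")
  expect_equal(classify_loop(mk_loop(600000L, 700000L), ann), "other-other")
  # symmetric under anchor swap (left/right exchanged gives same label)
  expect_equal(classify_loop(mk_loop(50000L, 200000L), ann),
               classify_loop(mk_loop(200000L, 50000L + 0L), ann))
  # anchor overlapping both a promoter and an enhancer: promoter wins
  ann3 <- build_annotation(
    data.table::data.table(chrom = "chr1",
                           start = c(9500L, 11000L),
                           end = c(10500L, 12000L)),
    data.table::data.table(chrom = "chr1", start = 10000L, end = 10001L))
  wide <- mk_loop(9500L, 200000L, w = 3000L)
  expect_equal(substr(classify_loop(wide, ann3), 1, 1), "P")
})

test_that("ctcf_orientation uses the strongest motif per anchor", {
  motifs <- data.table::data.table(
    chrom = "chr1",
    start = c(10100L, 10200L, 50100L, 90100L),
    end = c(10119L, 10219L, 50119L, 90119L),
    name = "CTCF", score = c(5, 9, 7, 7),
    strand = c("+", "-", "-", "+"))
  # left anchor picks the score-9 '-' motif; right anchor '-' -> tandem
  expect_equal(ctcf_orientation(mk_loop(10000L, 50000L), motifs), "tandem")
  # convergent: '+' at left (only motif), '-' at right
  m2 <- motifs[c(1, 3)]
  expect_equal(ctcf_orientation(mk_loop(10000L, 50000L), m2), "convergent")
  # divergent
  m3 <- data.table::copy(m2)[, strand := c("-", "+")]
  m3$start <- c(10100L, 50100L); m3$end <- c(10119L, 50119L)
  expect_equal(ctcf_orientation(mk_loop(10000L, 50000L), m3), "divergent")
  # single and none
  expect_equal(ctcf_orientation(mk_loop(10000L, 300000L), m2), "single")
  expect_equal(ctcf_orientation(mk_loop(200000L, 300000L), m2), "none")
})

test_that("build_network reproduces adjacency-count degrees", {
  # star: promoter at 9.5-10.5 kb looping to three enhancers
  ann <- toy_ann()
  loops <- rbind(mk_loop(9500L, 50000L), mk_loop(9500L, 200000L),
                 mk_loop(9500L, 400000L))
  net <- build_network(loops, ann)
  expect_equal(nrow(net$edges), 3L)
  pid <- net$nodes[type == "P"]$node_id
  expect_equal(unname(net$degrees[pid]), 3)
  expect_equal(sum(net$degrees), 2L * nrow(net$edges))
  # two disconnected loop pairs -> 2 non-trivial components
  loops2 <- rbind(mk_loop(9500L, 50000L), mk_loop(200000L, 400000L))
  net2 <- build_network(loops2, ann)
  conn <- net2$components[names(net2$degrees)[net2$degrees > 0]]
  expect_equal(length(unique(conn)), 2L)
  # degrees equal an adjacency-count oracle
  adj <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(net$degrees[names(adj)]), as.vector(adj))
})

test_that("fit_powerlaw recovers a planted exponent", {
  with_seed(120, {
    k <- 1:60
    deg <- sample(k, 2000, replace = TRUE, prob = k^(-2))
  })
  fit <- fit_powerlaw(deg)
  expect_gt(fit$gamma, 1.7); expect_lt(fit$gamma, 2.3)
  expect_false(fit$poor_fit)
  # uniform degree counts: slope ~ 0, flagged poor
  flat <- rep(1:10, each = 50)
  expect_true(fit_powerlaw(flat)$poor_fit)
  expect_error(fit_powerlaw(rep(c(1L, 7L), 10)), "at least 3")
})
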