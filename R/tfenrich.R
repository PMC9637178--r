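# Transcription-factor loop-anchor association: binary binding matrices over
# anchors and flanking false-loop backgrounds, three attributes per factor
# (anchor consistency, co-binding ratio, peak-overlap ratio), a four-rule
# filter against the flanking background, and a column-shuffle permutation
# FDR.

#' Build flanking false-loop background regions
#'
#' For each loop, three anchor-width windows stepping upstream of the left
#' anchor are paired (by step index) with three stepping downstream of the
#' right anchor, giving three false loops per true loop. A false pair is
#' dropped entirely when either member overlaps any true loop anchor or runs
#' off the chromosome start.
#'
#' @param loops Loop table.
#' @param n_steps Steps per side (default 3).
#' @return `data.table` with columns `loop_id`, `step`, and the false pair's
#'   anchor intervals (`chrom`, `start1`, `end1`, `start2`, `end2`).
#' @export
build_background_regions <- function(loops, n_steps = 3L) {
  if (nrow(loops) == 0L)
    return(data.table(loop_id = character(), step = integer(),
                      chrom = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(),
                      end2 = integer()))
  reps <- loops[rep(seq_len(.N), each = n_steps)]
  reps[, step := rep(seq_len(n_steps), nrow(loops))]
  w1 <- reps$end1 - reps$start1
  w2 <- reps$end2 - reps$start2
  bg <- data.table(loop_id = reps$id, step = reps$step, chrom = reps$chrom,
                   start1 = reps$start1 - reps$step * w1,
                   end1 = reps$end1 - reps$step * w1,
                   start2 = reps$start2 + reps$step * w2,
                   end2 = reps$end2 + reps$step * w2)
  bg <- bg[start1 >= 0L]
  # drop pairs overlapping any true anchor
  anchors <- rbindlist(list(
    loops[, .(chrom, start = start1, end = end1)],
    loops[, .(chrom, start = start2, end = end2)]))
  hit1 <- region_overlaps_any(bg[, .(chrom, start = start1, end = end1)],
                              anchors)
  hit2 <- region_overlaps_any(bg[, .(chrom, start = start2, end = end2)],
                              anchors)
  bg[!(hit1 | hit2)]
}

# logical: does each query interval overlap >= 1 subject interval
region_overlaps_any <- function(query, subjects) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subjects) == 0L) return(logical(nrow(query)))
  s <- copy(subjects)[, `:=`(start = as.numeric(start),
                             end = as.numeric(end) - 1)]
  setkey(s, chrom, start, end)
  q <- copy(query)[, `:=`(start = as.numeric(start),
                          end = as.numeric(end) - 1,
                          qid = seq_len(nrow(query)))]
  setkey(q, chrom, start, end)
  ov <- foverlaps(q, s, type = "any", nomatch = NULL)
  out <- logical(nrow(query))
  out[unique(ov$qid)] <- TRUE
  out
}

#' Build a binary region-by-factor binding matrix
#'
#' Cell (region, factor) is 1 when the region overlaps at least one peak
#' (>= 1 bp) of the factor.
#'
#' @param regions `data.table` with `chrom`, `start`, `end` (row order is
#'   preserved).
#' @param peak_sets Named list of peak tables (`chrom`, `start`, `end`), one
#'   per factor.
#' @return Integer 0/1 matrix, rows = regions, columns = factors.
#' @export
build_binding_matrix <- function(regions, peak_sets) {
  stopifnot(length(names(peak_sets)) == length(peak_sets))
  m <- matrix(0L, nrow(regions), length(peak_sets),
              dimnames = list(NULL, names(peak_sets)))
  for (f in names(peak_sets)) {
    pk <- peak_sets[[f]]
    if (is.null(pk) || nrow(pk) == 0L) next
    m[, f] <- as.integer(region_overlaps_any(regions, pk))
  }
  m
}

#' Anchor co-binding consistency of a factor
#'
#' Rank (Spearman) correlation of the paired left/right binary binding
#' vectors; on binary data this equals the phi coefficient. Undefined when a
#' vector is constant.
#'
#' @param left_col,right_col Binary vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
anchors_consistency <- function(left_col, right_col) {
  stopifnot(length(left_col) == length(right_col), length(left_col) >= 3L)
  if (sd(left_col) == 0 || sd(right_col) == 0) return(NA_real_)
  cor(left_col, right_col, method = "spearman")
}

tf_attributes <- function(left_mat, right_mat) {
  fac <- colnames(left_mat)
  data.table(
    factor_name = fac,
    consistency = vapply(fac, function(f) {
      if (sd(left_mat[, f]) == 0 || sd(right_mat[, f]) == 0) NA_real_
      else cor(left_mat[, f], right_mat[, f], method = "spearman")
    }, numeric(1)),
    cobind_ratio = vapply(fac, function(f)
      mean(left_mat[, f] & right_mat[, f]), numeric(1)))
}

peak_overlap_ratio <- function(peak_sets, anchors) {
  vapply(names(peak_sets), function(f) {
    pk <- peak_sets[[f]]
    if (is.null(pk) || nrow(pk) == 0L) return(NA_real_)
    mean(region_overlaps_any(pk, anchors))
  }, numeric(1))
}

#' Score factors against the flanking false-loop background
#'
#' Computes the three attributes on true loops and on the false-loop
#' background, their fg/bg ratios (background floored at `bg_floor`), and the
#' four-rule pass flag: consistency ratio > 2, co-binding ratio > 0.1,
#' co-binding ratio fg/bg > 2, and peak-overlap ratio fg/bg >= 1.
#'
#' @param loops Loop table.
#' @param peak_sets Named list of per-factor peak tables.
#' @param bg_regions Optional precomputed [build_background_regions()]
#'   output.
#' @param bg_floor Floor for background denominators (default 1e-6).
#' @return `data.table` of per-factor records (one row per factor), including
#'   the binding matrices as attributes `left_mat`/`right_mat` for use by
#'   [permutation_fdr()].
#' @export
score_factors <- function(loops, peak_sets, bg_regions = NULL,
                          bg_floor = 1e-6) {
  if (is.null(bg_regions)) bg_regions <- build_background_regions(loops)
  la <- loops[, .(chrom, start = start1, end = end1)]
  ra <- loops[, .(chrom, start = start2, end = end2)]
  lb <- bg_regions[, .(chrom, start = start1, end = end1)]
  rb <- bg_regions[, .(chrom, start = start2, end = end2)]
  left_mat <- build_binding_matrix(la, peak_sets)
  right_mat <- build_binding_matrix(ra, peak_sets)
  left_bg <- build_binding_matrix(lb, peak_sets)
  right_bg <- build_binding_matrix(rb, peak_sets)
  tru <- tf_attributes(left_mat, right_mat)
  bkg <- tf_attributes(left_bg, right_bg)
  anchors <- rbindlist(list(la, ra))
  bg_anch <- rbindlist(list(lb, rb))
  rec <- data.table(
    factor_name = tru$factor_name,
    consistency = tru$consistency,
    cobind_ratio = tru$cobind_ratio,
    peak_overlap_ratio = peak_overlap_ratio(peak_sets, anchors),
    bg_consistency = bkg$consistency,
    bg_cobind_ratio = bkg$cobind_ratio,
    bg_peak_overlap_ratio = peak_overlap_ratio(peak_sets, bg_anch))
  rec[, `:=`(
    consistency_ratio = consistency / pmax(bg_consistency, bg_floor),
    cobind_ratio_ratio = cobind_ratio / pmax(bg_cobind_ratio, bg_floor),
    peak_overlap_ratio_ratio =
      peak_overlap_ratio / pmax(bg_peak_overlap_ratio, bg_floor))]
  rec[, pass := !is.na(consistency) & !is.na(consistency_ratio) &
        consistency_ratio > 2 & cobind_ratio > 0.1 &
        cobind_ratio_ratio > 2 &
        (is.na(peak_overlap_ratio_ratio) | peak_overlap_ratio_ratio >= 1)]
  setattr(rec, "left_mat", left_mat)
  setattr(rec, "right_mat", right_mat)
  rec[]
}

#' Permutation FDR for factor attributes
#'
#' For each of `n_shuffles` rounds, every factor's binding column is permuted
#' across rows, independently for the left and the right anchor matrix
#' (preserving each factor's marginal binding frequency); `fdr_perm` is the
#' fraction of shuffles whose attribute is at least the observed one. The
#' peak-overlap ratio is invariant under this shuffle and gets `NA`. The
#' enforced gate downstream uses the consistency FDR only.
#'
#' @param left_mat,right_mat Binary anchor binding matrices.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Integer seed (reproducible).
#' @return `data.table` with `factor_name`, `fdr_consistency`, `fdr_cobind`,
#'   `fdr_peak_overlap` (all `NA` for the latter).
#' @export
permutation_fdr <- function(left_mat, right_mat, n_shuffles = 1000L,
                            seed = 7L) {
  obs <- tf_attributes(left_mat, right_mat)
  n <- nrow(left_mat)
  fac <- colnames(left_mat)
  exceed_cons <- exceed_cob <- setNames(numeric(length(fac)), fac)
  withr_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      for (f in fac) {
        l <- left_mat[sample.int(n), f]
        r <- right_mat[sample.int(n), f]
        cons <- if (sd(l) == 0 || sd(r) == 0) NA_real_
          else cor(l, r, method = "spearman")
        ob <- obs[factor_name == f]
        if (!is.na(ob$consistency) && !is.na(cons) &&
              cons >= ob$consistency)
          exceed_cons[f] <- exceed_cons[f] + 1
        if (mean(l & r) >= ob$cobind_ratio)
          exceed_cob[f] <- exceed_cob[f] + 1
      }
    }
  })
  data.table(factor_name = fac,
             fdr_consistency = exceed_cons / n_shuffles,
             fdr_cobind = exceed_cob / n_shuffles,
             fdr_peak_overlap = NA_real_)
}

#' Rank the factor report
#'
#' Passing factors first, sorted by consistency descending (ties broken by
#' co-binding ratio descending); the full attribute table is kept.
#'
#' @param records Scored records (from [score_factors()], optionally merged
#'   with [permutation_fdr()]).
#' @return Re-ordered `data.table`.
#' @export
rank_report <- function(records) {
  rec <- copy(records)
  setorder(rec, -pass, -consistency, -cobind_ratio, na.last = TRUE)
  rec[]
}

#' Full TF loop-anchor enrichment analysis
#'
#' [score_factors()] plus [permutation_fdr()] (gating `pass` additionally on
#' `fdr_consistency < fdr_cut`), ranked with [rank_report()].
#'
#' @param loops Loop table.
#' @param peak_sets Named list of per-factor peak tables.
#' @param n_shuffles,seed See [permutation_fdr()].
#' @param fdr_cut Consistency permutation FDR threshold (default 0.001).
#' @return Ranked per-factor `data.table`.
#' @export
tf_enrichment <- function(loops, peak_sets, n_shuffles = 1000L, seed = 7L,
                          fdr_cut = 0.001) {
  rec <- score_factors(loops, peak_sets)
  fdr <- permutation_fdr(attr(rec, "left_mat"), attr(rec, "right_mat"),
                         n_shuffles, seed)
  rec <- merge(rec, fdr, by = "factor_name", sort = FALSE)
  rec[, pass := pass & fdr_consistency < fdr_cut]
  rank_report(rec)
}
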