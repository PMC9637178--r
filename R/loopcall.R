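# Density-based loop calling on PET 2D coordinates.
#
# Each cis PET is a point (x, y) = (left-end midpoint, right-end midpoint),
# x <= y. Candidate loops are DBSCAN clusters of these points (Euclidean
# metric), found at several eps radii; each candidate's significance comes
# from Poisson tails against permuted nearby background windows; candidates
# from different eps values are merged when both anchor pairs overlap.

#' 2D DBSCAN clustering
#'
#' Deterministic DBSCAN with Euclidean distance: a core point has at least
#' `minPts` neighbours within `eps` (itself included); clusters are maximal
#' density-connected sets; border points join the first discovered core's
#' cluster. Points are processed in (x, y) sorted order so labels are
#' reproducible; the grid-bucketed search is exactly equivalent to a naive
#' O(n^2) scan.
#'
#' @param x,y Point coordinates in bp.
#' @param eps Neighbourhood radius in bp (> 0).
#' @param minPts Core threshold (>= 2).
#' @return Integer cluster labels aligned to the input order; `NA` marks
#'   noise.
#' @export
dbscan2d <- function(x, y, eps, minPts) {
  stopifnot(eps > 0, minPts >= 2, length(x) == length(y))
  n <- length(x)
  if (n == 0L) return(integer(0))
  ord <- order(x, y)
  lab <- .dbscan_grid(as.numeric(x)[ord], as.numeric(y)[ord],
                      as.numeric(eps), as.integer(minPts))
  out <- integer(n); out[] <- NA_integer_
  out[ord] <- lab
  out
}

#' Automatic upper distance cutoff from the distance-decay curve
#'
#' Estimates where the PET distance decay flattens into background: the
#' log10-distance histogram is converted to a per-bp density and the cutoff is
#' the left edge of the first bin where the local log-log slope of that
#' density rises above `slope_cut`. A pure power-law decay d^-alpha has slope
#' -alpha throughout and never triggers, in which case the maximum observed
#' distance is returned.
#'
#' @param distances Numeric PET distances (bp), positive.
#' @param n_bins Number of log10 bins (default 50).
#' @param slope_cut Slope threshold (default -0.5).
#' @return Distance cutoff in bp.
#' @export
auto_max_cut <- function(distances, n_bins = 50L, slope_cut = -0.5,
                         window = 7L, min_count = 5L) {
  d <- distances[distances > 0]
  if (length(d) < 100L) return(max(d, 1))
  lg <- log10(d)
  br <- seq(min(lg), max(lg), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(lg, br, rightmost.closed = TRUE), n_bins)
  width_bp <- 10^br[-1L] - 10^br[-(n_bins + 1L)]
  dens <- cnt / width_bp
  mid <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  # sparse tail bins carry too much Poisson noise for slope estimation
  ok <- which(cnt >= min_count)
  if (length(ok) < window + 1L) return(max(d))
  ld <- log10(dens[ok]); lm <- mid[ok]
  peak <- which.max(dens[ok])
  # sliding-window OLS slope; trigger past the decay mode only
  for (s in seq_len(length(ok) - window + 1L)) {
    if (s <= peak) next
    w <- s:(s + window - 1L)
    sl <- coef(lm(ld[w] ~ lm[w]))[2]
    if (sl > slope_cut) return(10^br[ok[s]])
  }
  max(d)
}

#' Find candidate loops by multi-eps clustering
#'
#' PETs with distance below `cut` or above `max_cut` are excluded, DBSCAN is
#' run per chromosome and per eps, each cluster's bounding box becomes a
#' candidate, and clusters whose anchors (extended by eps) straddle the
#' diagonal are discarded as self-ligation-like signal.
#'
#' @param index A `pet_index`.
#' @param eps_list Ascending eps radii in bp, e.g. `c(200, 500, 1000, 2000)`.
#' @param minPts DBSCAN core threshold (default 10).
#' @param cut Minimum PET distance in bp (default 0; the reference human
#'   setting is 5000).
#' @param max_cut Maximum PET distance; `"auto"` uses [auto_max_cut()],
#'   `Inf` disables.
#' @return A `data.table` of candidates with anchor intervals, `member_count`
#'   and source `eps`.
#' @export
call_candidates <- function(index, eps_list = c(200, 500, 1000, 2000),
                            minPts = 10L, cut = 0, max_cut = Inf) {
  stopifnot(length(eps_list) >= 1L, !is.unsorted(eps_list))
  out <- list()
  all_d <- unlist(lapply(index$chrs, function(s) s$y - s$x), use.names = FALSE)
  if (identical(max_cut, "auto"))
    max_cut <- if (length(all_d)) auto_max_cut(all_d) else Inf
  for (ch in names(index$chrs)) {
    store <- index$chrs[[ch]]
    keep <- which((store$y - store$x) >= cut & (store$y - store$x) <= max_cut)
    if (length(keep) < minPts) next
    x <- store$x[keep]; y <- store$y[keep]
    for (ep in eps_list) {
      lab <- dbscan2d(x, y, ep, minPts)
      cl <- which(!is.na(lab))
      if (!length(cl)) next
      dt <- data.table(x = x[cl], y = y[cl], label = lab[cl])
      bb <- dt[, .(start1 = min(x), end1 = max(x) + 1,
                   start2 = min(y), end2 = max(y) + 1,
                   member_count = .N), by = label]
      # diagonal guard: anchors extended by eps must not overlap
      bb <- bb[start2 - ep > end1 + ep]
      if (nrow(bb)) {
        bb[, `:=`(chrom = ch, eps = ep, label = NULL)]
        out[[length(out) + 1L]] <- bb
      }
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(), end2 = numeric(),
                      member_count = integer(), eps = numeric()))
  rbindlist(out, use.names = TRUE)[
    , .(chrom, start1, end1, start2, end2, member_count, eps)]
}

# Background window shifts for one candidate: all (i, j) in
# {-n_shifts..n_shifts}^2 minus (0, 0), step = own anchor width per axis.
# Windows that overlap the candidate rectangle, cross the diagonal, or leave
# the chromosome are dropped.
candidate_bg_counts <- function(index, ch, s1, e1, s2, e2, n_shifts = 5L) {
  w1 <- e1 - s1; w2 <- e2 - s2
  grid <- data.table(expand.grid(i = -n_shifts:n_shifts,
                                 j = -n_shifts:n_shifts))
  grid <- grid[!(i == 0L & j == 0L)]
  x1 <- s1 + grid$i * w1; x2 <- e1 + grid$i * w1
  y1 <- s2 + grid$j * w2; y2 <- e2 + grid$j * w2
  clen <- index_chrom_len(index, ch)
  ok <- x1 >= 0 & y1 >= 0 & x2 <= clen & y2 <= clen &
    (y1 >= x2) &                      # background must stay above diagonal
    !(x1 < e1 & x2 > s1 & y1 < e2 & y2 > s2)  # no 2D overlap with candidate
  if (!any(ok)) return(integer(0))
  rect_counts(index, ch, x1[ok], x2[ok], y1[ok], y2[ok])
}

#' Test one candidate loop against permuted nearby background
#'
#' Two null rates are combined. (1) Local permutation: background windows
#' are the (i, j) grid shifts of the candidate's anchor pair (step = anchor
#' width), excluding the candidate itself, windows crossing the diagonal and
#' windows off the chromosome. (2) Distance-decay conditional expectation:
#' because PET signal concentrates at accessible regions, anchor-width
#' shifts can step off the occupied stripe and understate the null near the
#' diagonal; the expected count given each anchor's 1D occupancy is
#' `n_anchor * P(distance in the candidate's distance span)` under the
#' chromosome-wide distance distribution, evaluated for both anchors. The
#' Poisson rate is `lambda = max(mean(bg_counts), decay expectation,
#' pseudo)`; `p = P(X >= n_obs)` under Poisson(lambda) and
#' `enrichment_score = n_obs / lambda`.
#'
#' @param index A `pet_index`.
#' @param cand One-row candidate (as from [call_candidates()]), or a list
#'   with `chrom`, `start1`, `end1`, `start2`, `end2`.
#' @param n_shifts Shift grid half-width (default 5).
#' @param pseudo Rate floor (default 1).
#' @param decay Sorted PET distance vector for the chromosome (computed from
#'   the index when `NULL`); set `FALSE` to disable the decay term and test
#'   against the local permutation alone.
#' @return A list with `n_obs`, `bg_counts`, `lambda`, `p_value`,
#'   `enrichment_score`; `p_value` is `NA` when no background window is
#'   valid (such candidates are rejected).
#' @export
test_candidate <- function(index, cand, n_shifts = 5L, pseudo = 1,
                           decay = NULL) {
  ch <- as.character(cand$chrom)
  n_obs <- rect_counts(index, ch, cand$start1, cand$end1, cand$start2,
                       cand$end2)
  bg <- candidate_bg_counts(index, ch, cand$start1, cand$end1, cand$start2,
                            cand$end2, n_shifts)
  if (!length(bg))
    return(list(n_obs = n_obs, bg_counts = integer(0), lambda = NA_real_,
                p_value = NA_real_, enrichment_score = NA_real_))
  lam_decay <- 0
  if (!isFALSE(decay)) {
    store <- index$chrs[[ch]]
    if (is.null(decay)) decay <- sort(store$y - store$x)
    if (length(decay)) {
      dlo <- cand$start2 - cand$end1
      dhi <- cand$end2 - cand$start1
      frac <- (findInterval(dhi, decay) - findInterval(dlo - 1, decay)) /
        length(decay)
      n_x <- sum(store$x >= cand$start1 & store$x < cand$end1)
      n_y <- sum(store$y >= cand$start2 & store$y < cand$end2)
      lam_decay <- max(n_x, n_y) * frac
    }
  }
  lambda <- max(mean(bg), lam_decay, pseudo)
  p <- ppois(n_obs - 1, lambda, lower.tail = FALSE)
  list(n_obs = n_obs, bg_counts = bg, lambda = lambda, p_value = p,
       enrichment_score = n_obs / lambda)
}

# Merge candidates whose anchor pairs both overlap (per chromosome) into
# connected components; union extent, min p-value (its ES travels along).
merge_candidates <- function(cands) {
  cands <- copy(cands)
  cands[, grp := NA_integer_]
  gid <- 0L
  for (ch in unique(cands$chrom)) {
    idx <- which(cands$chrom == ch)
    sub <- cands[idx]
    n <- nrow(sub)
    # adjacency: pairs overlapping on both axes
    o1 <- overlap_pairs(sub$start1, sub$end1)
    o2 <- overlap_pairs(sub$start2, sub$end2)
    key1 <- paste(o1$a, o1$b); key2 <- paste(o2$a, o2$b)
    both <- unique(o1[key1 %in% key2])
    g <- igraph::graph_from_data_frame(
      data.frame(from = both$a, to = both$b), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership
    cands[idx, grp := gid + as.integer(comp)]
    gid <- gid + max(comp)
  }
  merged <- cands[, .(
    chrom = chrom[1L],
    start1 = min(start1), end1 = max(end1),
    start2 = min(start2), end2 = max(end2),
    p_value = min(p_value),
    enrichment_score = enrichment_score[which.min(p_value)],
    n_members = .N), by = grp]
  merged[, grp := NULL]
  merged[]
}

# all unordered pairs (a <= b) of overlapping half-open integer intervals
overlap_pairs <- function(start, end) {
  n <- length(start)
  y <- data.table(s = as.numeric(start), e = as.numeric(end) - 1,
                  idx2 = seq_len(n))
  setkey(y, s, e)
  x <- data.table(s = as.numeric(start), e = as.numeric(end) - 1,
                  idx = seq_len(n))
  setkey(x, s, e)
  ov <- foverlaps(x, y, type = "any")
  data.table(a = pmin(ov$idx, ov$idx2), b = pmax(ov$idx, ov$idx2))
}

#' Call significant loops
#'
#' Runs [call_candidates()] at every eps, tests each candidate with
#' [test_candidate()], merges candidates across eps when both anchor pairs
#' overlap (union extent, minimum p-value), re-quantifies the merged extent,
#' and keeps loops with `pet_count >= min_pets`, Bonferroni-adjusted
#' `p <= p_cut` and `enrichment_score >= es_cut`.
#'
#' @inheritParams call_candidates
#' @param min_pets Minimum supporting PETs (default `minPts`).
#' @param p_cut Significance cutoff on the Bonferroni-adjusted p (default
#'   0.01).
#' @param es_cut Minimum enrichment score (default 2).
#' @param n_shifts,pseudo Passed to [test_candidate()].
#' @return A loop table (see [write_loops()] for the schema).
#' @export
call_loops <- function(index, eps_list = c(200, 500, 1000, 2000),
                       minPts = 10L, cut = 0, max_cut = Inf,
                       min_pets = minPts, p_cut = 0.01, es_cut = 2,
                       n_shifts = 5L, pseudo = 1) {
  cands <- call_candidates(index, eps_list, minPts, cut, max_cut)
  if (nrow(cands) == 0L) return(empty_loops())
  decay <- lapply(index$chrs, function(s) sort(s$y - s$x))
  tested <- lapply(seq_len(nrow(cands)), function(k)
    test_candidate(index, cands[k], n_shifts, pseudo,
                   decay = decay[[cands$chrom[k]]]))
  cands[, p_value := vapply(tested, `[[`, numeric(1), "p_value")]
  cands[, enrichment_score := vapply(tested, `[[`, numeric(1),
                                     "enrichment_score")]
  n_tested <- nrow(cands)
  cands <- cands[!is.na(p_value)]
  if (nrow(cands) == 0L) return(empty_loops())
  merged <- merge_candidates(cands)
  merged[, pet_count := rect_counts(index, chrom[1L], start1, end1, start2,
                                    end2), by = chrom]
  merged[, p_adj := pmin(1, p_value * n_tested)]
  keep <- merged[pet_count >= min_pets & p_adj <= p_cut &
                   enrichment_score >= es_cut]
  if (nrow(keep) == 0L) return(empty_loops())
  setorder(keep, chrom, start1, start2)
  keep[, `:=`(
    distance = (start2 + end2) / 2 - (start1 + end1) / 2,
    id = sprintf("loop_%d", .I))]
  keep[, .(chrom, start1 = as.integer(start1), end1 = as.integer(end1),
           start2 = as.integer(start2), end2 = as.integer(end2),
           pet_count = as.integer(pet_count), p_value = p_adj,
           enrichment_score, distance, id)]
}

#' Resolution estimation from singleton-bin fractions
#'
#' For each bin size, PET 2D points are binned into (x_bin, y_bin) pairs; the
#' statistic is the fraction of PETs whose bin pair contains at least two
#' PETs. The achievable resolution is the smallest bin size whose fraction
#' exceeds 0.5.
#'
#' @param index A `pet_index`.
#' @param bin_sizes Bin sizes in bp (e.g. `c(200, 1000, 5000, 10000)`).
#' @return A `data.table` with `bin_size`, `fraction_non_singleton`, and an
#'   attribute-free helper column `achieved` (fraction > 0.5).
#' @export
estimate_resolution <- function(index, bin_sizes = c(200, 1000, 5000, 10000)) {
  stopifnot(all(bin_sizes > 0))
  res <- lapply(bin_sizes, function(bs) {
    tot <- 0; nons <- 0
    for (ch in names(index$chrs)) {
      s <- index$chrs[[ch]]
      dt <- data.table(xbin = floor(s$x / bs), ybin = floor(s$y / bs))
      cnt <- dt[, .N, by = .(xbin, ybin)]
      tot <- tot + nrow(dt)
      nons <- nons + sum(cnt$N[cnt$N >= 2L])
    }
    data.table(bin_size = bs,
               fraction_non_singleton = if (tot > 0) nons / tot else NA_real_)
  })
  out <- rbindlist(res)
  out[, achieved := fraction_non_singleton > 0.5]
  out[]
}

#' Overlap two loop sets with anchor extension
#'
#' Loop `a` matches loop `b` when, after extending every anchor by
#' `extension` bp on both sides, the left anchors overlap and the right
#' anchors overlap (same chromosome).
#'
#' @param set_a,set_b Loop tables.
#' @param extension Anchor extension in bp (default 5000).
#' @return A list with `both` (match count in `set_a`), `a_only`, `b_only`,
#'   and logical match vectors `a_matched`, `b_matched`.
#' @export
overlap_loops <- function(set_a, set_b, extension = 5000) {
  am <- logical(nrow(set_a)); bm <- logical(nrow(set_b))
  if (nrow(set_a) && nrow(set_b)) {
    for (i in seq_len(nrow(set_a))) {
      a <- set_a[i]
      cand <- set_b[chrom == a$chrom &
                      start1 - extension < a$end1 + extension &
                      end1 + extension > a$start1 - extension &
                      start2 - extension < a$end2 + extension &
                      end2 + extension > a$start2 - extension]
      if (nrow(cand)) {
        am[i] <- TRUE
        bm[set_b$chrom == a$chrom & set_b$id %in% cand$id] <- TRUE
      }
    }
  }
  list(both = sum(am), a_only = sum(!am), b_only = sum(!bm),
       a_matched = am, b_matched = bm)
}
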