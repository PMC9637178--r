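# Aggregate (APA-style) loop analysis: per-loop 11 x 11 contact matrices,
# individual and global enrichment scores, and the normalised mean heatmap.

#' Per-loop 11 x 11 contact matrix
#'
#' Row windows tile the left anchor plus its five upstream and five
#' downstream windows of the same width; column windows do the same for the
#' right anchor. Cell (i, j) is the PET count in window pair (i, j); the loop
#' itself sits in the centre cell (6, 6). Matrices whose windows leave the
#' chromosome are flagged `partial` and are excluded from global statistics.
#'
#' @param index A `pet_index`.
#' @param loop One-row loop table (or list with `chrom`, `start1`, `end1`,
#'   `start2`, `end2`).
#' @param n_flank Windows on each side of an anchor (default 5, giving
#'   11 x 11).
#' @return A list with `raw` ((2*n_flank+1)^2 matrix) and `partial`.
#' @export
loop_matrix <- function(index, loop, n_flank = 5L) {
  ch <- as.character(loop$chrom)
  w1 <- loop$end1 - loop$start1
  w2 <- loop$end2 - loop$start2
  k <- -n_flank:n_flank
  xs <- loop$start1 + k * w1
  ys <- loop$start2 + k * w2
  clen <- index_chrom_len(index, ch)
  partial <- min(xs) < 0 || min(ys) < 0 || max(xs) + w1 > clen ||
    max(ys) + w2 > clen
  grid <- expand.grid(i = seq_along(k), j = seq_along(k))
  cnt <- rect_counts(index, ch, xs[grid$i], xs[grid$i] + w1,
                     ys[grid$j], ys[grid$j] + w2)
  m <- matrix(0L, length(k), length(k))
  m[cbind(grid$i, grid$j)] <- cnt
  list(raw = m, partial = partial)
}

#' Enrichment score of a loop contact matrix
#'
#' Centre cell divided by the mean of all other cells. Undefined (`NA`) when
#' that mean is zero; such loops are excluded from the global score.
#'
#' @param m Matrix from [loop_matrix()] (the `raw` element) or a square
#'   matrix.
#' @return Numeric ratio, or `NA` when undefined.
#' @export
enrichment_score <- function(m) {
  if (is.list(m)) m <- m$raw
  n <- nrow(m)
  c0 <- (n + 1L) %/% 2L
  centre <- m[c0, c0]
  others <- m[-((c0 - 1L) * n + c0)]
  mo <- mean(others)
  if (mo == 0) return(NA_real_)
  centre / mo
}

#' Aggregate loops into a global enrichment score and mean heatmap
#'
#' Per loop: build the 11 x 11 matrix and its enrichment score. For the mean
#' heatmap each matrix is normalised by its total PET count (zero-total
#' matrices skipped) and z-scored over its cells, then averaged element-wise.
#' The global enrichment score is the mean of the defined per-loop scores.
#'
#' @param index A `pet_index`.
#' @param loops Loop table.
#' @param loop_norm Apply the per-matrix total + z-score normalisation before
#'   averaging (default `TRUE`); otherwise raw matrices are averaged.
#' @param min_window_pets Minimum total PETs in a loop's matrix for the loop
#'   to enter the analysis (default 0; use e.g. 20 for sparse contact data).
#' @param n_flank See [loop_matrix()].
#' @return A list with `global_es`, `mean_matrix`, `per_loop_es` (aligned to
#'   `loops`, `NA` for excluded loops), `n_excluded`.
#' @export
aggregate_loops <- function(index, loops, loop_norm = TRUE,
                            min_window_pets = 0L, n_flank = 5L) {
  if (nrow(loops) == 0L) stop("no loops to aggregate")
  es <- rep(NA_real_, nrow(loops))
  acc <- NULL
  n_mat <- 0L
  for (i in seq_len(nrow(loops))) {
    lm <- loop_matrix(index, loops[i], n_flank)
    if (lm$partial || sum(lm$raw) < min_window_pets) next
    es[i] <- enrichment_score(lm$raw)
    m <- lm$raw
    if (loop_norm) {
      tot <- sum(m)
      if (tot == 0) next
      m <- m / tot
      s <- sd(as.numeric(m))
      m <- if (s > 0) (m - mean(m)) / s else m * 0
    }
    acc <- if (is.null(acc)) m else acc + m
    n_mat <- n_mat + 1L
  }
  if (all(is.na(es)))
    stop("no loop has a defined enrichment score")
  list(global_es = mean(es, na.rm = TRUE),
       mean_matrix = if (n_mat > 0L) acc / n_mat else NULL,
       per_loop_es = es,
       n_excluded = sum(is.na(es)))
}
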