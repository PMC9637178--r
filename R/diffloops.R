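# Differential loop calling between two conditions (A = control,
# B = treatment): joint quantification, linear background fit in log2 space,
# MA cutoffs at a target FDR on the background cloud, and a Poisson test on
# the larger vs smaller transformed loop count with the rate floored by the
# nearby backgrounds and a pseudo-count.

#' Combine two loop sets into a non-redundant union
#'
#' Loops from the two conditions are concatenated and merged when both anchor
#' pairs overlap (union extent), so each genomic loop is quantified once.
#'
#' @param loops_a,loops_b Loop tables.
#' @return Loop table of the union (p-value/ES columns carry the minimum /
#'   matching values of the merged members).
#' @export
union_loops <- function(loops_a, loops_b) {
  all_loops <- rbindlist(list(loops_a, loops_b), use.names = TRUE)
  if (nrow(all_loops) == 0L) return(empty_loops())
  cands <- all_loops[, .(chrom, start1, end1, start2, end2, p_value,
                         enrichment_score)]
  merged <- merge_candidates(cands)
  setorder(merged, chrom, start1, start2)
  merged[, `:=`(
    pet_count = NA_integer_,
    distance = (start2 + end2) / 2 - (start1 + end1) / 2,
    id = sprintf("uloop_%d", .I))]
  merged[, .(chrom, start1 = as.integer(start1), end1 = as.integer(end1),
             start2 = as.integer(start2), end2 = as.integer(end2),
             pet_count, p_value, enrichment_score, distance, id)]
}

#' Quantify a loop union in two conditions
#'
#' Per loop: the rectangle PET count in each condition plus the mean count
#' over the same permuted nearby background windows used by loop calling.
#'
#' @param index_a,index_b `pet_index` objects for conditions A (control) and
#'   B (treatment).
#' @param loops Loop table (typically from [union_loops()]).
#' @param n_shifts Background shift grid half-width (default 5).
#' @return `data.table` with the loop columns plus `count_a`, `count_b`,
#'   `nearby_a`, `nearby_b`.
#' @export
quantify_pair <- function(index_a, index_b, loops, n_shifts = 5L) {
  out <- copy(loops)
  ca <- cb <- na_ <- nb_ <- numeric(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    l <- loops[i]
    ca[i] <- rect_counts(index_a, l$chrom, l$start1, l$end1, l$start2, l$end2)
    cb[i] <- rect_counts(index_b, l$chrom, l$start1, l$end1, l$start2, l$end2)
    bga <- candidate_bg_counts(index_a, l$chrom, l$start1, l$end1, l$start2,
                               l$end2, n_shifts)
    bgb <- candidate_bg_counts(index_b, l$chrom, l$start1, l$end1, l$start2,
                               l$end2, n_shifts)
    na_[i] <- if (length(bga)) mean(bga) else 0
    nb_[i] <- if (length(bgb)) mean(bgb) else 0
  }
  out[, `:=`(count_a = ca, count_b = cb, nearby_a = na_, nearby_b = nb_)]
  out[]
}

#' Fit the linear background model between two conditions
#'
#' Ordinary least squares of `log2(nearby_b + 1)` on `log2(nearby_a + 1)`,
#' the MA plot's natural scale. The fitted line describes how background
#' (nearby-window) signal in the treatment scales against the control;
#' [transform_to_control()] inverts it to place treatment counts on the
#' control scale, under the assumption that background regions are not
#' differential.
#'
#' @param nearby_a,nearby_b Background counts per loop for control (A) and
#'   treatment (B); at least 10 points.
#' @param min_informative Minimum number of background pairs with signal
#'   (`max(nearby_a, nearby_b) >= 1`) required to attempt the fit (default
#'   10). Empty windows carry no depth information; when nearly all
#'   background windows are empty the OLS slope is driven by a handful of
#'   single-PET log ratios and distorts the transform, so the fit falls back
#'   to the identity (equal-depth assumption) with a warning.
#' @return A list with `slope` and `intercept` (class `bg_fit`). A degenerate
#'   (constant) background yields the identity fit with a warning.
#' @export
fit_background <- function(nearby_a, nearby_b, min_informative = 10L) {
  stopifnot(length(nearby_a) == length(nearby_b))
  if (length(nearby_a) < 10L)
    stop("need at least 10 background points to fit")
  la <- log2(nearby_a + 1); lb <- log2(nearby_b + 1)
  if (sum(pmax(nearby_a, nearby_b) >= 1) < min_informative) {
    warning("background windows too sparse to fit a depth model; ",
            "using identity transform")
    return(structure(list(slope = 1, intercept = 0), class = "bg_fit"))
  }
  if (sd(la) == 0 || sd(lb) == 0) {
    warning("degenerate background; using identity transform")
    return(structure(list(slope = 1, intercept = 0), class = "bg_fit"))
  }
  co <- coef(lm(lb ~ la))
  structure(list(slope = unname(co[2]), intercept = unname(co[1])),
            class = "bg_fit")
}

#' Map treatment-scale counts onto the control scale
#'
#' Inverts the background fit: `2^((log2(x + 1) - intercept) / slope) - 1`.
#' With `nearby_b ~ 2 * nearby_a` the transform roughly halves treatment
#' counts.
#'
#' @param x Counts on the treatment (B) scale.
#' @param fit A `bg_fit` from [fit_background()].
#' @return Transformed counts (control scale), floored at 0.
#' @export
transform_to_control <- function(x, fit) {
  pmax(0, 2^((log2(x + 1) - fit$intercept) / fit$slope) - 1)
}

#' Find MA cutoffs on the background cloud at a target FDR
#'
#' Grid search over candidate (`a_cut`, `m_cut`) pairs drawn from the
#' observed background `A` and `|M|` values: the selected pair is the
#' lexicographically smallest (minimal `m_cut`, then minimal `a_cut`) whose
#' background exceedance fraction (`A >= a_cut & |M| >= m_cut`) is at most
#' `fdr`.
#'
#' @param A_bg,M_bg Background mean-signal and log2-fold-change vectors.
#' @param fdr Target fraction of background points allowed past the cutoffs
#'   (default 0.05).
#' @return A list with `a_cut`, `m_cut`, `fdr_target` (class `ma_cutoffs`).
#' @export
find_ma_cutoffs <- function(A_bg, M_bg, fdr = 0.05) {
  stopifnot(length(A_bg) == length(M_bg), fdr >= 0, fdr <= 1)
  absM <- abs(M_bg)
  n <- length(A_bg)
  m_grid <- c(0, sort(unique(absM)))
  a_grid <- c(0, sort(unique(A_bg)))
  for (m in m_grid) {
    sel <- absM >= m
    if (!any(sel)) {
      return(structure(list(a_cut = 0, m_cut = m, fdr_target = fdr),
                       class = "ma_cutoffs"))
    }
    # smallest a with exceedance <= fdr, scanning ascending
    for (a in a_grid) {
      if (sum(sel & A_bg >= a) / n <= fdr)
        return(structure(list(a_cut = a, m_cut = m, fdr_target = fdr),
                         class = "ma_cutoffs"))
    }
  }
  warning("target FDR unattainable on this background; ",
          "using cutoffs beyond the observed extremes")
  structure(list(a_cut = max(A_bg) + 1e-9, m_cut = max(absM) + 1e-9,
                 fdr_target = fdr), class = "ma_cutoffs")
}

#' Poisson p-value for a differential loop
#'
#' Implements the printed one-sided test literally:
#' `p = 1 - sum_{i=1}^{fg-1} Poisson(i, lambda)` with
#' `lambda = max(bg, fgNearby, bgNearby, pseudo)`; the sum is empty when
#' `fg <= 1` (then `p = 1`). Inputs are transformed counts floored to
#' integers. Note this equals the standard upper tail `P(X >= fg)` plus the
#' `PMF(0)` term; `tail_exact = TRUE` computes the standard upper tail
#' instead.
#'
#' @param fg Larger transformed loop count (treatment vs control).
#' @param bg Smaller transformed loop count.
#' @param fgNearby,bgNearby Transformed nearby background counts matched to
#'   the fg/bg conditions.
#' @param pseudo Noise floor (default 1).
#' @param tail_exact Use `P(X >= fg)` instead of the literal formula.
#' @return p-value(s) in \[0, 1\]; vectorised over its arguments.
#' @export
poisson_diff_p <- function(fg, bg, fgNearby, bgNearby, pseudo = 1,
                           tail_exact = FALSE) {
  if (any(c(fg, bg, fgNearby, bgNearby) < 0))
    stop("poisson_diff_p inputs must be non-negative")
  fg <- floor(fg); bg <- floor(bg)
  fgNearby <- floor(fgNearby); bgNearby <- floor(bgNearby)
  lambda <- pmax(bg, fgNearby, bgNearby, pseudo)
  upper <- ppois(fg - 1, lambda, lower.tail = FALSE)  # P(X >= fg)
  if (tail_exact) return(pmin(1, upper))
  p <- upper + dpois(0, lambda)
  p[fg <= 1] <- 1
  pmin(1, p)
}

#' Assemble differential-loop records
#'
#' Applies the background fit to treatment counts, computes `A`/`M`, the
#' fg/bg assignment (fg is the larger transformed loop count regardless of
#' condition) and the Poisson p-value per loop.
#'
#' @param quant Output of [quantify_pair()].
#' @param fit A `bg_fit`; when `NULL` it is fitted from `quant`'s nearby
#'   counts.
#' @param pseudo Noise floor (default 1).
#' @param tail_exact See [poisson_diff_p()].
#' @return `quant` with added `tcount_b`, `tnearby_b`, `A`, `M`, `fg`, `bg`,
#'   `p_raw`.
#' @export
diff_records <- function(quant, fit = NULL, pseudo = 1, tail_exact = FALSE) {
  rec <- copy(quant)
  if (is.null(fit)) fit <- fit_background(rec$nearby_a, rec$nearby_b)
  tb <- transform_to_control(rec$count_b, fit)
  tnb <- transform_to_control(rec$nearby_b, fit)
  rec[, `:=`(tcount_b = tb, tnearby_b = tnb)]
  rec[, `:=`(A = (log2(count_a + 1) + log2(tcount_b + 1)) / 2,
             M = log2(tcount_b + 1) - log2(count_a + 1))]
  fg <- pmax(rec$count_a, tb); bg <- pmin(rec$count_a, tb)
  fgN <- ifelse(tb >= rec$count_a, tnb, rec$nearby_a)
  bgN <- ifelse(tb >= rec$count_a, rec$nearby_a, tnb)
  rec[, `:=`(fg = floor(fg), bg = floor(bg))]
  rec[, p_raw := poisson_diff_p(fg, bg, fgN, bgN, pseudo, tail_exact)]
  rec[]
}

#' Call differential loops
#'
#' A loop is significant when `A >= a_cut`, `|M| >= m_cut` and its p-value
#' passes `p_cut` (Bonferroni-adjusted across tested loops by default, raw
#' when `correct = FALSE`). Direction follows the sign of `M`
#' (`enriched_in_B` for positive M, i.e. stronger in treatment).
#'
#' @param records Output of [diff_records()].
#' @param cutoffs An `ma_cutoffs` (from [find_ma_cutoffs()]); `NULL` applies
#'   no MA gating.
#' @param p_cut Significance cutoff (default 0.01).
#' @param correct Apply Bonferroni correction (default `TRUE`); the
#'   uncorrected mode with `p_cut = 0.001` mirrors knockdown-style analyses.
#' @return `records` with `p_adj` and `call` columns.
#' @export
call_diff_loops <- function(records, cutoffs = NULL, p_cut = 0.01,
                            correct = TRUE) {
  rec <- copy(records)
  n <- nrow(rec)
  rec[, p_adj := pmin(1, p_raw * n)]
  p_use <- if (correct) rec$p_adj else rec$p_raw
  ok <- p_use <= p_cut
  if (!is.null(cutoffs))
    ok <- ok & rec$A >= cutoffs$a_cut & abs(rec$M) >= cutoffs$m_cut
  rec[, call := "unchanged"]
  rec[ok & M > 0, call := "enriched_in_B"]
  rec[ok & M < 0, call := "enriched_in_A"]
  rec[]
}

#' Full differential-loop analysis between two conditions
#'
#' Union of the two loop sets, joint quantification, background fit, MA
#' cutoffs at the target FDR, Poisson test and calling.
#'
#' @param index_a,index_b `pet_index` for control (A) and treatment (B).
#' @param loops_a,loops_b Loop tables per condition.
#' @param fdr Target background FDR for the MA cutoffs (default 0.05).
#' @param p_cut,correct,pseudo,tail_exact See [call_diff_loops()] and
#'   [poisson_diff_p()].
#' @return A list with `records` (called records), `fit`, `cutoffs`.
#' @export
diff_loops <- function(index_a, index_b, loops_a, loops_b, fdr = 0.05,
                       p_cut = 0.01, correct = TRUE, pseudo = 1,
                       tail_exact = FALSE) {
  loops <- union_loops(loops_a, loops_b)
  quant <- quantify_pair(index_a, index_b, loops)
  fit <- fit_background(quant$nearby_a, quant$nearby_b)
  rec <- diff_records(quant, fit, pseudo, tail_exact)
  tnb <- rec$tnearby_b
  A_bg <- (log2(rec$nearby_a + 1) + log2(tnb + 1)) / 2
  M_bg <- log2(tnb + 1) - log2(rec$nearby_a + 1)
  cutoffs <- find_ma_cutoffs(A_bg, M_bg, fdr)
  list(records = call_diff_loops(rec, cutoffs, p_cut, correct),
       fit = fit, cutoffs = cutoffs)
}
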