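# Regulatory annotation of anchors (promoter / enhancer / other), loop
# categorisation, CTCF motif-orientation classes, and the enhancer-promoter
# network with degree statistics and a power-law fit.

#' Build a promoter/enhancer annotation set
#'
#' Overlapping raw regions are merged; a merged region within `promoter_dist`
#' bp (default 2 kb) upstream or downstream of any TSS is labelled promoter,
#' otherwise enhancer; finally same-label neighbours with gaps smaller than
#' `merge_gap` bp (default 100) are merged again.
#'
#' @param regions `data.table` with `chrom`, `start`, `end` (raw candidate
#'   elements, e.g. accessible peaks or chromatin-state segments).
#' @param tss `data.table` with `chrom`, `start` (TSS position; `end`
#'   optional) and optionally `name` (gene).
#' @param promoter_dist Promoter distance rule in bp (default 2000).
#' @param merge_gap Re-merge gap in bp (default 100).
#' @return A list of class `annotation_set` with `promoters` and `enhancers`
#'   tables.
#' @export
build_annotation <- function(regions, tss, promoter_dist = 2000,
                             merge_gap = 100) {
  merged <- merge_intervals(regions, gap = 0)
  tss_pos <- tss$start
  tss_win <- data.table(chrom = tss$chrom,
                        start = pmax(0, tss_pos - promoter_dist),
                        end = tss_pos + promoter_dist + 1)
  is_prom <- region_overlaps_any(merged, tss_win)
  prom <- merge_intervals(merged[is_prom], gap = merge_gap)
  enh <- merge_intervals(merged[!is_prom], gap = merge_gap)
  structure(list(promoters = prom, enhancers = enh),
            class = "annotation_set")
}

# merge intervals closer than `gap` (gap = 0 merges overlapping/adjacent-less)
merge_intervals <- function(dt, gap = 0) {
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  d <- dt[, .(chrom, start, end)]
  setorder(d, chrom, start, end)
  d[, grp := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                        (start[-1] - cummax_by(end, chrom)[-.N] >= gap)))]
  out <- d[, .(chrom = chrom[1], start = min(start), end = max(end)),
           by = grp]
  out[, grp := NULL]
  out[]
}

# running max of end within chromosome runs (input sorted by chrom, start)
cummax_by <- function(x, g) {
  out <- x
  for (i in seq_along(x)[-1])
    out[i] <- if (g[i] == g[i - 1]) max(out[i - 1], x[i]) else x[i]
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$promoters), "promoters,",
      nrow(x$enhancers), "enhancers\n")
  invisible(x)
}

# label one set of anchor intervals: promoter > enhancer > other
label_anchors <- function(anchors, ann) {
  lab <- rep("other", nrow(anchors))
  lab[region_overlaps_any(anchors, ann$enhancers)] <- "E"
  lab[region_overlaps_any(anchors, ann$promoters)] <- "P"
  lab
}

#' Classify loops by the regulatory identity of their anchors
#'
#' Each anchor is labelled by overlap with the annotation (priority
#' promoter > enhancer > other); the unordered pair label is one of
#' `P-P`, `E-P`, `E-E`, `P-other`, `E-other`, `other-other`.
#'
#' @param loops Loop table.
#' @param ann An `annotation_set`.
#' @return Character vector of pair labels aligned to `loops`.
#' @export
classify_loop <- function(loops, ann) {
  if (nrow(loops) == 0L) return(character(0))
  l1 <- label_anchors(loops[, .(chrom, start = start1, end = end1)], ann)
  l2 <- label_anchors(loops[, .(chrom, start = start2, end = end2)], ann)
  rank <- c(E = 1L, P = 2L, other = 3L)
  a <- ifelse(rank[l1] <= rank[l2], l1, l2)
  b <- ifelse(rank[l1] <= rank[l2], l2, l1)
  paste(a, b, sep = "-")
}

#' Classify loops by CTCF motif orientation at the anchors
#'
#' Each anchor takes the strand of its strongest-scoring overlapping motif.
#' Classes: `convergent` (left `+`, right `-`), `divergent` (left `-`,
#' right `+`), `tandem` (same strand), `single` (exactly one anchor has a
#' motif), `none`.
#'
#' @param loops Loop table.
#' @param motifs `data.table` with `chrom`, `start`, `end`, `score`,
#'   `strand` (BED6-style).
#' @return Character vector of classes aligned to `loops`.
#' @export
ctcf_orientation <- function(loops, motifs) {
  if (nrow(loops) == 0L) return(character(0))
  s1 <- anchor_motif_strand(loops[, .(chrom, start = start1, end = end1)],
                            motifs)
  s2 <- anchor_motif_strand(loops[, .(chrom, start = start2, end = end2)],
                            motifs)
  out <- rep("none", nrow(loops))
  one <- xor(is.na(s1), is.na(s2))
  out[one] <- "single"
  both <- !is.na(s1) & !is.na(s2)
  out[both & s1 == "+" & s2 == "-"] <- "convergent"
  out[both & s1 == "-" & s2 == "+"] <- "divergent"
  out[both & s1 == s2] <- "tandem"
  out
}

anchor_motif_strand <- function(anchors, motifs) {
  if (nrow(motifs) == 0L) return(rep(NA_character_, nrow(anchors)))
  m <- copy(motifs)
  if (!"score" %in% names(m)) m[, score := 0]
  s <- m[, .(chrom, start = as.numeric(start), end = as.numeric(end) - 1,
             score, strand)]
  setkey(s, chrom, start, end)
  q <- anchors[, .(chrom, start = as.numeric(start),
                   end = as.numeric(end) - 1, qid = .I)]
  setkey(q, chrom, start, end)
  ov <- foverlaps(q, s, type = "any", nomatch = NULL)
  out <- rep(NA_character_, nrow(anchors))
  if (nrow(ov)) {
    best <- ov[order(qid, -score)][, .SD[1L], by = qid]
    out[best$qid] <- best$strand
  }
  out
}

#' Build the regulatory (enhancer-promoter) network
#'
#' Nodes are the merged annotated elements; undirected edges are loops whose
#' anchors both map to an element (largest-overlap assignment after the
#' promoter > enhancer priority). Loops touching unannotated anchors are
#' dropped.
#'
#' @param loops Loop table.
#' @param ann An `annotation_set`.
#' @return A list of class `regulatory_network` with `graph` (igraph),
#'   `nodes`, `edges`, `degrees` and `components` (membership vector).
#' @export
build_network <- function(loops, ann) {
  nodes <- rbindlist(list(
    copy(ann$promoters)[, type := "P"],
    copy(ann$enhancers)[, type := "E"]))
  nodes[, node_id := sprintf("%s_%s:%d-%d", type, chrom, start, end)]
  a1 <- assign_element(loops[, .(chrom, start = start1, end = end1)], nodes)
  a2 <- assign_element(loops[, .(chrom, start = start2, end = end2)], nodes)
  keep <- !is.na(a1) & !is.na(a2)
  edges <- data.table(from = nodes$node_id[a1[keep]],
                      to = nodes$node_id[a2[keep]],
                      loop_id = loops$id[keep])
  g <- igraph::graph_from_data_frame(edges[, .(from, to)], directed = FALSE,
                                     vertices = nodes$node_id)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)$membership
  structure(list(graph = g, nodes = nodes, edges = edges,
                 degrees = deg, components = comp),
            class = "regulatory_network")
}

# index of best element per anchor (promoter priority, then largest overlap)
assign_element <- function(anchors, nodes) {
  s <- nodes[, .(chrom, start = as.numeric(start),
                 end = as.numeric(end) - 1, nid = .I, type)]
  setkey(s, chrom, start, end)
  q <- anchors[, .(chrom, start = as.numeric(start),
                   end = as.numeric(end) - 1, qid = .I)]
  setkey(q, chrom, start, end)
  ov <- foverlaps(q, s, type = "any", nomatch = NULL)
  out <- rep(NA_integer_, nrow(anchors))
  if (nrow(ov)) {
    ov[, olap := pmin(end, i.end) - pmax(start, i.start) + 1]
    ov[, prio := ifelse(type == "P", 0L, 1L)]
    best <- ov[order(qid, prio, -olap)][, .SD[1L], by = qid]
    out[best$qid] <- best$nid
  }
  out
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", max(x$components), "component(s)\n")
  invisible(x)
}

#' Fit a power law to a degree sequence
#'
#' Least-squares slope of `log(count)` versus `log(degree)` over degrees with
#' non-zero count; the exponent is `gamma = -slope`. The fit is flagged poor
#' when R^2 < 0.5.
#'
#' @param degrees Integer degree sequence (connected nodes, degree >= 1).
#' @return A list with `gamma`, `r_squared`, `poor_fit`, `n_distinct`.
#' @export
fit_powerlaw <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3L)
    stop("need at least 3 distinct degrees to fit a power law")
  fit <- lm(log(cnt) ~ log(k))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  gamma <- -unname(coef(fit)[2])
  # poor: ill-conditioned fit, weak fit, or no decay at all
  list(gamma = gamma, r_squared = r2,
       poor_fit = !is.finite(r2) || r2 < 0.5 || gamma <= 0.1,
       n_distinct = length(k))
}
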