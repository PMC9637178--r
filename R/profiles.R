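# Virtual 4C extraction, profile correlation and montage (circle-plot style)
# interaction-density tables.

#' Define a virtual 4C viewpoint
#'
#' @param chrom Chromosome.
#' @param center Viewpoint centre (e.g. a TSS position).
#' @param flank Half-width of the viewpoint selection window in bp (default
#'   1000, i.e. +/- 1 kb around a TSS).
#' @param window Half-width of the analysis span in bp (default 250000).
#' @return A list of class `viewpoint`.
#' @export
viewpoint <- function(chrom, center, flank = 1000, window = 250000) {
  stopifnot(flank > 0, window >= flank)
  structure(list(chrom = as.character(chrom), center = as.numeric(center),
                 flank = as.numeric(flank), window = as.numeric(window)),
            class = "viewpoint")
}

#' Virtual 4C profile from a viewpoint
#'
#' Selects PETs with at least one end midpoint within
#' `[center - flank, center + flank]` and piles the selected PETs' other-end
#' intervals (full interval coverage, not midpoints) into bins over
#' `[center - window, center + window)`. Bin values are covered bases divided
#' by `bin_size`, so the profile mass equals total (clipped) distal covered
#' bases / bin_size. PETs with both ends inside the viewpoint contribute
#' their right end once and are counted in `n_self`.
#'
#' @param index A `pet_index` built with end intervals (the default).
#' @param vp A [viewpoint()].
#' @param bin_size Bin width in bp (default 200).
#' @return A `profile1d` with attributes `n_selected` and `n_self`.
#' @export
virtual_4c <- function(index, vp, bin_size = 200) {
  stopifnot(inherits(vp, "viewpoint"))
  r_start <- vp$center - vp$window
  r_end <- vp$center + vp$window
  prof <- profile1d(vp$chrom, r_start, r_end, bin_size)
  store <- index$chrs[[vp$chrom]]
  if (is.null(store)) {
    attr(prof, "n_selected") <- 0L; attr(prof, "n_self") <- 0L
    return(prof)
  }
  in_vp_l <- abs(store$x - vp$center) <= vp$flank
  in_vp_r <- abs(store$y - vp$center) <= vp$flank
  sel <- in_vp_l | in_vp_r
  if (!any(sel)) {
    attr(prof, "n_selected") <- 0L; attr(prof, "n_self") <- 0L
    return(prof)
  }
  ends <- store$ends[sel]
  use_right <- in_vp_l[sel]  # left end in viewpoint -> pile the right end
  os <- ifelse(use_right, ends$start2, ends$start1)
  oe <- ifelse(use_right, ends$end2, ends$end1)
  prof$values <- bin_coverage(os, oe, r_start, r_end, bin_size)
  attr(prof, "n_selected") <- sum(sel)
  attr(prof, "n_self") <- sum(in_vp_l & in_vp_r)
  prof
}

# per-bin covered bases / bin_size for a set of intervals, clipped to region
bin_coverage <- function(starts, ends, r_start, r_end, bin_size) {
  nbins <- ceiling((r_end - r_start) / bin_size)
  vals <- numeric(nbins)
  s <- pmax(starts, r_start); e <- pmin(ends, r_end)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(vals)
  b0 <- floor((s - r_start) / bin_size)  # 0-based first bin
  b1 <- floor((e - 1 - r_start) / bin_size)
  for (i in seq_along(s)) {
    bins <- b0[i]:b1[i]
    bs <- r_start + bins * bin_size
    be <- bs + bin_size
    vals[bins + 1] <- vals[bins + 1] +
      (pmin(e[i], be) - pmax(s[i], bs)) / bin_size
  }
  vals
}

#' Pearson correlation between two profiles
#'
#' Both profiles must share region and bin size; bins where both profiles are
#' zero are retained.
#'
#' @param p1,p2 `profile1d` objects.
#' @return Pearson coefficient, or `NA` (with a warning) when a profile is
#'   constant.
#' @export
profile_correlation <- function(p1, p2) {
  stopifnot(inherits(p1, "profile1d"), inherits(p2, "profile1d"))
  if (p1$chrom != p2$chrom || p1$start != p2$start || p1$end != p2$end ||
        p1$bin_size != p2$bin_size)
    stop("profiles must share region and bin size")
  if (sd(p1$values) == 0 || sd(p2$values) == 0) {
    warning("constant profile; correlation undefined")
    return(NA_real_)
  }
  cor(p1$values, p2$values)
}

#' Montage interaction-density table
#'
#' For a set of named, non-overlapping regions on one chromosome,
#' `density[i, j]` is the number of PETs with one end midpoint in region i
#' and the other in region j, normalised per million total cis PETs. With
#' `viewpoints` set, only pairs touching a named viewpoint region are kept
#' (other cells zeroed).
#'
#' @param index A `pet_index`.
#' @param regions `data.table` with `chrom`, `start`, `end`, `name`.
#' @param viewpoints Optional character vector of region names.
#' @return A list of class `montage_table` with `regions` and the symmetric
#'   `density` matrix.
#' @export
montage_densities <- function(index, regions, viewpoints = NULL) {
  stopifnot(nrow(regions) >= 2L)
  if (length(unique(regions$chrom)) != 1L)
    stop("montage regions must be on one chromosome")
  if (!"name" %in% names(regions))
    regions <- copy(regions)[, name := sprintf("region_%d", .I)]
  setorderv(regions <- copy(regions), "start")
  if (any(regions$start[-1] < regions$end[-nrow(regions)]))
    stop("montage regions must not overlap (ambiguous assignment)")
  if (!is.null(viewpoints) && !all(viewpoints %in% regions$name))
    stop("unknown viewpoint name(s)")
  n <- nrow(regions)
  dens <- matrix(0, n, n, dimnames = list(regions$name, regions$name))
  ch <- regions$chrom[1]
  store <- index$chrs[[ch]]
  if (!is.null(store) && index$cis_count > 0) {
    # assign each PET end midpoint to a region (or none)
    br <- c(rbind(regions$start, regions$end))
    fx <- findInterval(store$x, br)
    fy <- findInterval(store$y, br)
    rx <- ifelse(fx %% 2L == 1L, (fx + 1L) %/% 2L, NA_integer_)
    ry <- ifelse(fy %% 2L == 1L, (fy + 1L) %/% 2L, NA_integer_)
    ok <- !is.na(rx) & !is.na(ry)
    if (any(ok)) {
      tab <- data.table(i = pmin(rx[ok], ry[ok]), j = pmax(rx[ok], ry[ok]))
      cnt <- tab[, .N, by = .(i, j)]
      for (k in seq_len(nrow(cnt))) {
        dens[cnt$i[k], cnt$j[k]] <- dens[cnt$i[k], cnt$j[k]] + cnt$N[k]
        if (cnt$i[k] != cnt$j[k])
          dens[cnt$j[k], cnt$i[k]] <- dens[cnt$j[k], cnt$i[k]] + cnt$N[k]
      }
      dens <- dens / index$cis_count * 1e6
    }
  }
  if (!is.null(viewpoints)) {
    keep <- regions$name %in% viewpoints
    mask <- outer(keep, keep, `|`)
    dens[!mask] <- 0
  }
  structure(list(regions = regions, density = dens, viewpoints = viewpoints),
            class = "montage_table")
}

#' @export
print.montage_table <- function(x, ...) {
  cat("montage_table over", nrow(x$regions), "regions\n")
  print(round(x$density, 3))
  invisible(x)
}
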