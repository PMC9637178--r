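# Data model and I/O.
#
# Conventions used throughout the package:
#  * all coordinates are 0-based, half-open (BED/BEDPE);
#  * a PET table is a data.table with columns
#      chrom1, start1, end1, chrom2, start2, end2, mapq, linker1, linker2
#    where end1/end2 are exclusive; after canonicalisation the left end is the
#    one with the smaller midpoint;
#  * a loop table is a data.table with columns
#      chrom, start1, end1, start2, end2, pet_count, p_value,
#      enrichment_score, distance, id
#    with anchor 1 strictly preceding anchor 2 on the same chromosome.

PET_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
              "mapq", "linker1", "linker2")

LOOP_COLS <- c("chrom", "start1", "end1", "start2", "end2", "pet_count",
               "p_value", "enrichment_score", "distance", "id")

#' Construct a PET table
#'
#' Builds and canonicalises a table of paired-end tags (PETs). Ends are
#' reordered per row so that the left end has the smaller midpoint; for
#' intra-chromosomal (cis) PETs this guarantees `mid1 <= mid2`.
#'
#' @param chrom1,start1,end1 First end (chromosome, 0-based start, exclusive
#'   end).
#' @param chrom2,start2,end2 Second end.
#' @param mapq Integer mapping quality (scalar or vector); defaults to 60.
#' @param linker1,linker2 Logical, whether the bridging linker was found in
#'   the corresponding mate during trimming; default `TRUE`.
#' @return A `data.table` with the canonical PET columns.
#' @export
pets <- function(chrom1, start1, end1, chrom2, start2, end2,
                 mapq = 60L, linker1 = TRUE, linker2 = TRUE) {
  dt <- data.table(chrom1 = as.character(chrom1),
                   start1 = as.integer(start1), end1 = as.integer(end1),
                   chrom2 = as.character(chrom2),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   mapq = as.integer(mapq),
                   linker1 = as.logical(linker1),
                   linker2 = as.logical(linker2))
  validate_pets(dt)
  canonicalize_pets(dt)
}

validate_pets <- function(dt) {
  if (any(dt$start1 < 0L) || any(dt$start2 < 0L))
    stop("PET start coordinates must be >= 0")
  bad <- which(dt$end1 <= dt$start1 | dt$end2 <= dt$start2)
  if (length(bad))
    stop("PET intervals must satisfy end > start (row ", bad[1], ")")
  invisible(dt)
}

canonicalize_pets <- function(dt) {
  m1 <- pet_mid(dt$start1, dt$end1)
  m2 <- pet_mid(dt$start2, dt$end2)
  swap <- (dt$chrom1 > dt$chrom2) | (dt$chrom1 == dt$chrom2 & m1 > m2)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, start1, end1, linker1)]
    dt[swap, `:=`(chrom1 = chrom2, start1 = start2, end1 = end2,
                  linker1 = linker2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, start2 = tmp$start1,
                  end2 = tmp$end1, linker2 = tmp$linker1)]
  }
  dt[]
}

pet_mid <- function(start, end) floor((as.numeric(start) + as.numeric(end)) / 2)

#' PET genomic distance
#'
#' Distance between the two end midpoints; defined (and >= 0) for cis PETs.
#'
#' @param dt A PET table.
#' @return Numeric vector of distances in bp.
#' @export
pet_distance <- function(dt) {
  pet_mid(dt$start2, dt$end2) - pet_mid(dt$start1, dt$end1)
}

is_cis <- function(dt) dt$chrom1 == dt$chrom2

#' Read PETs from a BEDPE file
#'
#' Reads tab-separated BEDPE
#' (`chrom1 start1 end1 chrom2 start2 end2 [name score strand1 strand2]`).
#' The score column, when present, is interpreted as the pair's mapping
#' quality; records with `mapq < mapq_min` are dropped. Ends are reordered so
#' the left end comes first; trans (inter-chromosomal) PETs are stored
#' separately from cis PETs.
#'
#' @param path Path to a BEDPE file.
#' @param mapq_min Minimum mapping quality to retain a record (default 10).
#' @return A list with elements `cis` (PET table), `trans` (PET table) and
#'   `n_dropped_mapq`.
#' @export
read_bedpe <- function(path, mapq_min = 10L) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    empty <- pets(character(), integer(), integer(), character(),
                  integer(), integer())
    return(list(cis = empty, trans = empty[0], n_dropped_mapq = 0L))
  }
  if (ncol(dt) < 6L)
    stop("BEDPE must have at least 6 columns: ", path)
  setnames(dt, 1:6, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
  for (cn in c("start1", "end1", "start2", "end2")) {
    v <- suppressWarnings(as.integer(dt[[cn]]))
    if (anyNA(v))
      stop("malformed BEDPE line ", which(is.na(v))[1], " in ", path,
           " (non-integer ", cn, ")")
    data.table::set(dt, j = cn, value = v)
  }
  bad <- which(dt$end1 <= dt$start1 | dt$end2 <= dt$start2 |
                 dt$start1 < 0L | dt$start2 < 0L)
  if (length(bad))
    stop("malformed BEDPE line ", bad[1], " in ", path,
         " (requires 0 <= start < end)")
  mq <- if (ncol(dt) >= 8L) suppressWarnings(as.integer(dt[[8L]])) else
    rep(NA_integer_, nrow(dt))
  mq[is.na(mq)] <- 255L  # no score column: treated as passing
  dt <- dt[, .(chrom1 = as.character(chrom1), start1, end1,
               chrom2 = as.character(chrom2), start2, end2)]
  dt[, `:=`(mapq = mq, linker1 = TRUE, linker2 = TRUE)]
  n0 <- nrow(dt)
  dt <- dt[mapq >= mapq_min]
  dt <- canonicalize_pets(dt)
  cis <- dt[is_cis(dt)]
  trans <- dt[!is_cis(dt)]
  list(cis = cis[], trans = trans[], n_dropped_mapq = n0 - nrow(dt))
}

#' Write PETs to a BEDPE file
#'
#' @param dt PET table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(dt, path) {
  out <- dt[, .(chrom1, start1, end1, chrom2, start2, end2,
                name = ".", score = mapq,
                strand1 = ifelse(linker1, "+", "-"),
                strand2 = ifelse(linker2, "+", "-"))]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' Reads BED3/BED6 into a data.table with columns `chrom`, `start`, `end` and,
#' when present, `name`, `score`, `strand`.
#'
#' @param path Path to a BED file.
#' @return A `data.table`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), nms[seq_len(min(ncol(dt), 6L))])
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end))]
  if (any(dt$end <= dt$start)) stop("BED interval with end <= start in ", path)
  dt[]
}

#' Write a BED file
#' @param dt data.table with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(dt, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE,
         quote = FALSE)
  invisible(path)
}

# ---- PET 2D index -----------------------------------------------------------

#' Build a queryable 2D PET index
#'
#' Stores, per chromosome, the cis-PET 2D points (x = left-end midpoint,
#' y = right-end midpoint) sorted by x for fast rectangle counting, together
#' with the source end intervals (needed for virtual 4C pileups).
#'
#' @param dt PET table (only cis PETs are indexed; trans rows are counted).
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   flag out-of-bounds windows downstream.
#' @return An object of class `pet_index`.
#' @export
pet_index <- function(dt, chrom_lengths = NULL) {
  cis <- dt[is_cis(dt)]
  chrs <- list()
  if (nrow(cis)) {
    cis <- copy(cis)
    cis[, `:=`(mid1 = pet_mid(start1, end1), mid2 = pet_mid(start2, end2))]
    setorder(cis, chrom1, mid1, mid2)
    for (ch in unique(cis$chrom1)) {
      sub <- cis[chrom1 == ch]
      chrs[[ch]] <- list(x = as.numeric(sub$mid1), y = as.numeric(sub$mid2),
                         ends = sub[, .(start1, end1, start2, end2)])
    }
  }
  structure(list(chrs = chrs, cis_count = nrow(cis),
                 total_count = nrow(dt), chrom_lengths = chrom_lengths),
            class = "pet_index")
}

#' @export
print.pet_index <- function(x, ...) {
  cat("pet_index:", x$cis_count, "cis PETs on", length(x$chrs),
      "chromosome(s)\n")
  invisible(x)
}

index_chrom_len <- function(index, ch) {
  if (!is.null(index$chrom_lengths) && ch %in% names(index$chrom_lengths))
    return(as.numeric(index$chrom_lengths[[ch]]))
  Inf
}

# Vectorised rectangle counts on one chromosome; windows half-open.
rect_counts <- function(index, ch, x1, x2, y1, y2) {
  store <- index$chrs[[ch]]
  if (is.null(store)) return(integer(length(x1)))
  .count_rect(store$x, store$y, as.numeric(x1), as.numeric(x2),
              as.numeric(y1), as.numeric(y2))
}

#' Count PETs in a 2D rectangle window pair
#'
#' Counts PETs whose left-end midpoint falls in `win_x` and right-end midpoint
#' in `win_y` (both half-open).
#'
#' @param index A `pet_index`.
#' @param win_x,win_y Windows as `list(chrom =, start =, end =)` or
#'   3-element vectors `c(chrom, start, end)`.
#' @return Integer count.
#' @export
query_rectangle <- function(index, win_x, win_y) {
  wx <- as_interval(win_x); wy <- as_interval(win_y)
  if (wx$chrom != wy$chrom)
    stop("query_rectangle windows must be on the same chromosome")
  rect_counts(index, wx$chrom, wx$start, wx$end, wy$start, wy$end)
}

as_interval <- function(w) {
  if (is.list(w)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(w)))
    w <- list(chrom = as.character(w$chrom), start = as.numeric(w$start),
              end = as.numeric(w$end))
  } else {
    w <- list(chrom = as.character(w[1]), start = as.numeric(w[2]),
              end = as.numeric(w[3]))
  }
  if (w$end <= w$start) stop("interval requires end > start")
  w
}

# ---- Loop table I/O ---------------------------------------------------------

empty_loops <- function() {
  data.table(chrom = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(), pet_count = integer(),
             p_value = numeric(), enrichment_score = numeric(),
             distance = numeric(), id = character())
}

#' Write a loop table
#'
#' @param loops Loop table.
#' @param path Output path.
#' @param dialect `"tsv"` for the native tab-separated table with header, or
#'   `"washU"` for washU longrange text
#'   (`chr:start-end<TAB>chr:start-end,score`).
#' @return Invisibly, `path`.
#' @export
write_loops <- function(loops, path, dialect = c("tsv", "washU")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    fwrite(loops[, LOOP_COLS, with = FALSE], path, sep = "\t", quote = FALSE)
  } else {
    if (nrow(loops) == 0L) {
      writeLines(character(), path)
    } else {
      sc <- ifelse(loops$p_value > 0, -log10(loops$p_value), 320)
      out <- sprintf("%s:%d-%d\t%s:%d-%d,%.3f", loops$chrom, loops$start1,
                     loops$end1, loops$chrom, loops$start2, loops$end2, sc)
      writeLines(out, path)
    }
  }
  invisible(path)
}

#' Read a loop table written by [write_loops()] (tsv dialect)
#' @param path Path to a loop TSV.
#' @return Loop table.
#' @export
read_loops <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = c("chrom", "id")))
  if (nrow(dt) == 0L) return(empty_loops())
  dt[, LOOP_COLS, with = FALSE]
}

# ---- 1D profile -------------------------------------------------------------

#' Construct a binned 1D profile
#'
#' @param chrom Chromosome name.
#' @param start,end Region (0-based half-open).
#' @param bin_size Bin width in bp; number of bins is
#'   `ceiling((end - start) / bin_size)`.
#' @param values Optional non-negative bin values (default all zero).
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(chrom, start, end, bin_size, values = NULL) {
  stopifnot(end > start, bin_size > 0)
  nbins <- ceiling((end - start) / bin_size)
  if (is.null(values)) values <- numeric(nbins)
  stopifnot(length(values) == nbins, all(values >= 0))
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), bin_size = as.numeric(bin_size),
                 values = as.numeric(values)),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("profile1d %s:%d-%d bin %d bp (%d bins, mass %.2f)\n",
              x$chrom, x$start, x$end, x$bin_size, length(x$values),
              sum(x$values)))
  invisible(x)
}

#' Write a 1D profile as bedGraph
#'
#' Zero-valued bins are omitted, as usual for bedGraph.
#'
#' @param profile A `profile1d`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  nz <- which(profile$values > 0)
  starts <- profile$start + (nz - 1) * profile$bin_size
  ends <- pmin(starts + profile$bin_size, profile$end)
  dt <- data.table(chrom = profile$chrom, start = as.integer(starts),
                   end = as.integer(ends), value = profile$values[nz])
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph written by [write_profile()] back into a profile
#'
#' @param path bedGraph path.
#' @param chrom,start,end,bin_size Region/bin geometry of the profile the file
#'   was written from.
#' @return A `profile1d`.
#' @export
read_profile <- function(path, chrom, start, end, bin_size) {
  p <- profile1d(chrom, start, end, bin_size)
  dt <- tryCatch(fread(path, header = FALSE, sep = "\t"),
                 error = function(e) NULL)
  if (!is.null(dt) && nrow(dt)) {
    idx <- floor((dt[[2]] - start) / bin_size) + 1
    p$values[idx] <- dt[[4]]
  }
  p
}
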