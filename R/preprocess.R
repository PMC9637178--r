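# Read/PET cleaning: linker trimming, length filter, near-diagonal no-linker
# filter, PCR de-duplication, subsampling and QC bookkeeping.

#' Default bridging linker sequence
#' @export
DEFAULT_LINKER <- "CTGTCTCTTATACACATCT"

#' Trim the bridging linker from reads
#'
#' Truncates each read at the first exact occurrence of the linker substring.
#' A read is kept when its trimmed length is at least `min_len`; a read pair
#' should be retained only when both mates are kept (see [trim_fastq_pair()]).
#'
#' @param reads Character vector of read sequences over A/C/G/T/N.
#' @param linker Linker sequence searched as given (no mismatches, no reverse
#'   complement).
#' @param min_len Minimum trimmed length to keep a read (default 10).
#' @return A `data.table` with columns `sequence` (trimmed), `found_linker`,
#'   `kept` and `trim_len`.
#' @export
trim_linker <- function(reads, linker = DEFAULT_LINKER, min_len = 10L) {
  reads <- as.character(reads)
  pos <- regexpr(linker, reads, fixed = TRUE)
  found <- pos > 0L
  len <- ifelse(found, pos - 1L, nchar(reads))
  len[is.na(reads) | reads == ""] <- 0L
  seqs <- substr(reads, 1L, len)
  data.table(sequence = seqs, found_linker = found, kept = len >= min_len,
             trim_len = as.integer(len))
}

read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L)
    stop("FASTQ file ", path, " is not made of 4-line records")
  idx <- seq(1L, length(ln), by = 4L)
  data.table(name = ln[idx], sequence = ln[idx + 1L], quality = ln[idx + 3L])
}

write_fastq <- function(fq, path) {
  out <- character(4L * nrow(fq))
  idx <- seq(1L, length(out), by = 4L)
  out[idx] <- fq$name
  out[idx + 1L] <- fq$sequence
  out[idx + 2L] <- "+"
  out[idx + 3L] <- fq$quality
  writeLines(out, path)
  invisible(path)
}

#' Linker-trim a FASTQ read pair
#'
#' Applies [trim_linker()] to both mates independently (qualities are
#' truncated with the sequence) and keeps a pair only when both trimmed mates
#' have length >= `min_len`.
#'
#' @param fq1,fq2 Input FASTQ paths (mate 1 and mate 2).
#' @param out1,out2 Output FASTQ paths.
#' @param linker,min_len See [trim_linker()].
#' @return A list with `n_pairs`, `n_with_linker` (linker found in either
#'   mate), `n_kept`, and per-mate trim tables.
#' @export
trim_fastq_pair <- function(fq1, fq2, out1, out2, linker = DEFAULT_LINKER,
                            min_len = 10L) {
  r1 <- read_fastq(fq1); r2 <- read_fastq(fq2)
  if (nrow(r1) != nrow(r2)) stop("mate FASTQ files differ in read count")
  t1 <- trim_linker(r1$sequence, linker, min_len)
  t2 <- trim_linker(r2$sequence, linker, min_len)
  keep <- t1$kept & t2$kept
  o1 <- data.table(name = r1$name, sequence = t1$sequence,
                   quality = substr(r1$quality, 1L, t1$trim_len))[keep]
  o2 <- data.table(name = r2$name, sequence = t2$sequence,
                   quality = substr(r2$quality, 1L, t2$trim_len))[keep]
  write_fastq(o1, out1); write_fastq(o2, out2)
  list(n_pairs = nrow(r1), n_with_linker = sum(t1$found_linker |
                                                 t2$found_linker),
       n_kept = sum(keep), trim1 = t1, trim2 = t2, kept = keep)
}

#' Drop near-diagonal PETs that lack linker evidence
#'
#' Removes cis PETs with end-midpoint distance below `min_dist` in which the
#' linker was found in neither mate; such pairs are indistinguishable from
#' un-bridged genomic fragments. PETs with a linker in at least one end, or at
#' larger distance, are retained.
#'
#' @param dt PET table with `linker1`/`linker2` flags.
#' @param min_dist Distance threshold in bp (default 1000).
#' @return Filtered PET table.
#' @export
filter_close_nolinker <- function(dt, min_dist = 1000) {
  if (nrow(dt) == 0L) return(dt)
  d <- pet_distance(dt)
  drop <- is_cis(dt) & d < min_dist & !dt$linker1 & !dt$linker2
  dt[!drop]
}

#' Remove PCR duplicate PETs
#'
#' Keeps exactly one representative (the first occurrence) per identical
#' pair of end locations, i.e. identical
#' (chrom1, start1, end1, chrom2, start2, end2).
#'
#' @param dt PET table.
#' @return De-duplicated PET table in original first-occurrence order.
#' @export
dedup_pets <- function(dt) {
  unique(dt, by = c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
}

#' Uniform PET subsampling
#'
#' @param dt PET table.
#' @param n Number of PETs to sample without replacement.
#' @param seed Integer seed; the same seed always yields the same sample.
#' @return PET table with `n` rows (original order preserved).
#' @export
subsample_pets <- function(dt, n, seed = 1L) {
  if (n > nrow(dt)) stop("cannot subsample ", n, " from ", nrow(dt), " PETs")
  if (n == nrow(dt)) return(copy(dt))
  idx <- withr_seed(seed, sample.int(nrow(dt), n))
  dt[sort(idx)]
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Pipeline QC statistics
#'
#' Summarises counts along the cleaning pipeline. All counters are monotone
#' non-increasing downstream, and `redundancy = 1 - unique_cis / cis`.
#'
#' @param total_pairs Raw read pairs.
#' @param pairs_with_linker Pairs with the linker found in either mate.
#' @param mapped Mapped pairs.
#' @param mapq_pass Pairs passing the MAPQ filter.
#' @param cis,trans Intra-/inter-chromosomal PET counts after filtering.
#' @param unique_cis Unique cis PETs after de-duplication.
#' @return A list of class `qc_stats` (JSON-serialisable).
#' @export
compute_qc <- function(total_pairs, pairs_with_linker, mapped, mapq_pass,
                       cis, trans, unique_cis) {
  st <- list(total_pairs = total_pairs, pairs_with_linker = pairs_with_linker,
             mapped = mapped, mapq_pass = mapq_pass, cis = cis,
             trans = trans, unique_cis = unique_cis,
             redundancy = if (cis > 0) 1 - unique_cis / cis else 0)
  chain <- c(st$total_pairs, st$mapped, st$mapq_pass, st$cis + st$trans)
  if (any(diff(chain) > 0))
    stop("QC counters must be monotone non-increasing along the pipeline")
  if (st$unique_cis > st$cis) stop("unique_cis cannot exceed cis")
  structure(st, class = "qc_stats")
}

#' @export
print.qc_stats <- function(x, ...) {
  cat("QC:", x$total_pairs, "pairs;", x$cis, "cis /", x$trans, "trans;",
      x$unique_cis, sprintf("unique cis (redundancy %.3f)\n", x$redundancy))
  invisible(x)
}

#' Run the full PET cleaning pipeline on a BEDPE file
#'
#' MAPQ filter (at read time), near-diagonal no-linker filter, and PCR
#' de-duplication, with QC bookkeeping.
#'
#' @param path BEDPE path.
#' @param mapq_min MAPQ threshold (default 10).
#' @param min_dist No-linker distance filter in bp (default 1000).
#' @return A list with `pets` (unique cis PET table), `trans`, and `qc`.
#' @export
preprocess_bedpe <- function(path, mapq_min = 10L, min_dist = 1000) {
  rd <- read_bedpe(path, mapq_min = mapq_min)
  n_mapped <- nrow(rd$cis) + nrow(rd$trans) + rd$n_dropped_mapq
  cis <- filter_close_nolinker(rd$cis, min_dist = min_dist)
  uni <- dedup_pets(cis)
  qc <- compute_qc(total_pairs = n_mapped, pairs_with_linker = NA,
                   mapped = n_mapped, mapq_pass = nrow(rd$cis) +
                     nrow(rd$trans),
                   cis = nrow(cis), trans = nrow(rd$trans),
                   unique_cis = nrow(uni))
  list(pets = uni, trans = rd$trans, qc = qc)
}
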