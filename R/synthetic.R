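# Synthetic PET dataset generator with ground truth, emulating the
# statistical structure the pipeline assumes: accessible peaks, planted
# anchor-pair loops with Gaussian-scattered PET ends, power-law
# distance-decay background concentrated at peaks, PCR duplicates, linker
# flags, condition-B fold changes, and TF peak sets with controllable
# anchor co-binding.

#' Simulation configuration
#'
#' Defaults define the reference fixture: one 10 Mb chromosome, 300
#' accessible peaks of 1 kb, 50 loops of 25-80 PETs with 150 bp anchor
#' scatter, 200,000 background PETs with a d^-1 distance decay truncated to
#' \[1 kb, chromosome length\], 70% of background left ends on peaks, read
#' ends of 50 bp.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param n_peaks,peak_width Accessible peaks (placed uniformly, no overlap).
#' @param n_loops Planted loops (random peak pairs at distance >= 20 kb).
#' @param pets_per_loop Integer range (min, max) of PETs per loop.
#' @param anchor_sigma SD in bp of PET end scatter around anchor centres.
#' @param n_background_pets Background PET count.
#' @param decay_alpha Background distance density exponent
#'   (density ~ d^-alpha on \[d_min, chrom_length\]).
#' @param d_min Minimum background distance in bp.
#' @param peak_bias Fraction of background left ends placed on peaks.
#' @param read_len PET end (read) length in bp.
#' @param dup_rate Probability that a PET receives one PCR duplicate copy.
#' @param linker_rate Per-end probability of carrying the linker flag.
#' @param tf_specs List of `list(name =, p_cobind_true =,
#'   p_bind_background =)` per factor.
#' @param fold_changes Named or per-loop numeric multipliers applied to loop
#'   PET counts in condition B (default all 1 = null).
#' @param tss_fraction Fraction of peaks carrying a TSS at their centre.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom = "chrS", chrom_length = 1e7, n_peaks = 300L,
                       peak_width = 1000L, n_loops = 50L,
                       pets_per_loop = c(25L, 80L), anchor_sigma = 150,
                       n_background_pets = 200000L, decay_alpha = 1,
                       d_min = 1000, peak_bias = 0.7, read_len = 50L,
                       dup_rate = 0, linker_rate = 1,
                       tf_specs = list(), fold_changes = NULL,
                       tss_fraction = 0.3, seed = 42L) {
  stopifnot(decay_alpha > 0, d_min >= 1, dup_rate >= 0, dup_rate <= 1,
            linker_rate >= 0, linker_rate <= 1, peak_bias >= 0,
            peak_bias <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# inverse-CDF sampling from density ~ d^-alpha on [d_min, d_max]; d_max may
# be a vector (per-draw upper bound)
rpowerlaw <- function(n, alpha, d_min, d_max) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    d_min * (d_max / d_min)^u
  } else {
    a1 <- 1 - alpha
    (d_min^a1 + u * (d_max^a1 - d_min^a1))^(1 / a1)
  }
}

# non-overlapping uniform placement of n intervals of width w on [0, L)
place_peaks <- function(n, w, L) {
  free <- L - n * w
  if (free <= n) stop("cannot place ", n, " non-overlapping peaks")
  gaps <- sort(sample.int(free, n))
  starts <- gaps + (seq_len(n) - 1L) * w
  data.table(start = as.integer(starts), end = as.integer(starts + w))
}

#' Simulate a PET dataset with ground truth
#'
#' Generates accessible peaks (a subset carrying TSSs), planted loops
#' between peak pairs, loop PETs with Gaussian end scatter, background PETs
#' with truncated power-law distance decay (left ends biased to peaks), PCR
#' duplicates, linker flags, an optional condition B with per-loop fold
#' changes, and TF peak sets. All outputs carry truth tables.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, BEDPE/BED/TSV files are
#'   written there.
#' @return A list with `pets_a`, `pets_b` (PET tables, duplicates included),
#'   `peaks`, `tss`, `tf_peaks` (named list), and `truth` (loops with true
#'   counts and fold changes, per-factor anchor co-binding, unique PET
#'   tables per condition, background distances).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr_seed(cfg$seed, {
    peaks <- place_peaks(cfg$n_peaks, cfg$peak_width, cfg$chrom_length)
    peaks[, `:=`(chrom = cfg$chrom, name = sprintf("peak_%d", .I))]
    tss_idx <- sort(sample.int(cfg$n_peaks,
                               max(1L, round(cfg$tss_fraction * cfg$n_peaks))))
    centers <- floor((peaks$start + peaks$end) / 2)
    tss <- data.table(chrom = cfg$chrom, start = centers[tss_idx],
                      end = centers[tss_idx] + 1L,
                      name = sprintf("gene_%d", seq_along(tss_idx)))

    # loops: random peak pairs at distance >= 20 kb, no repeated pair
    loops <- data.table(peak1 = integer(), peak2 = integer())
    tries <- 0L
    pair_key <- character(0)
    while (nrow(loops) < cfg$n_loops) {
      tries <- tries + 1L
      if (tries > 50L * cfg$n_loops)
        stop("infeasible loop placement for this configuration")
      ij <- sort(sample.int(cfg$n_peaks, 2L))
      if (abs(centers[ij[2]] - centers[ij[1]]) < 20000) next
      key <- paste(ij, collapse = "_")
      if (key %in% pair_key) next
      pair_key <- c(pair_key, key)
      loops <- rbind(loops, data.table(peak1 = ij[1], peak2 = ij[2]))
    }
    loops[, `:=`(c1 = centers[peak1], c2 = centers[peak2])]
    loops[, true_count := sample(cfg$pets_per_loop[1]:cfg$pets_per_loop[2],
                                 .N, replace = TRUE)]
    fc <- cfg$fold_changes
    if (is.null(fc)) fc <- rep(1, nrow(loops))
    stopifnot(length(fc) == nrow(loops))
    loops[, fold_change := fc]
    loops[, id := sprintf("true_loop_%d", .I)]

    gen_condition <- function(counts) {
      lp <- loops[rep(seq_len(.N), counts)]
      e1 <- round(rnorm(nrow(lp), lp$c1, cfg$anchor_sigma))
      e2 <- round(rnorm(nrow(lp), lp$c2, cfg$anchor_sigma))
      half <- cfg$read_len %/% 2L
      lo <- half; hi <- cfg$chrom_length - cfg$read_len + half
      e1 <- pmin(pmax(e1, lo), hi); e2 <- pmin(pmax(e2, lo), hi)
      loop_pets <- data.table(m1 = pmin(e1, e2), m2 = pmax(e1, e2),
                              origin = lp$id)

      nb <- cfg$n_background_pets
      on_peak <- runif(nb) < cfg$peak_bias
      left <- ifelse(on_peak,
                     peaks$start[sample.int(nrow(peaks), nb,
                                            replace = TRUE)] +
                       sample.int(cfg$peak_width, nb, replace = TRUE) - 1L,
                     floor(runif(nb, 0, cfg$chrom_length)))
      dmax <- pmax(cfg$d_min + 1, cfg$chrom_length - left - cfg$read_len)
      d <- rpowerlaw(nb, cfg$decay_alpha, cfg$d_min, dmax)
      right <- pmin(left + round(d), cfg$chrom_length - cfg$read_len + half)
      bg_pets <- data.table(m1 = as.numeric(left), m2 = as.numeric(right),
                            origin = "background")
      all_p <- rbind(loop_pets, bg_pets)
      half <- cfg$read_len %/% 2L
      dt <- data.table(
        chrom1 = cfg$chrom, start1 = as.integer(all_p$m1 - half),
        end1 = as.integer(all_p$m1 - half + cfg$read_len),
        chrom2 = cfg$chrom, start2 = as.integer(all_p$m2 - half),
        end2 = as.integer(all_p$m2 - half + cfg$read_len),
        mapq = 60L,
        linker1 = runif(nrow(all_p)) < cfg$linker_rate,
        linker2 = runif(nrow(all_p)) < cfg$linker_rate,
        origin = all_p$origin)
      dt[start1 < 0L, `:=`(end1 = end1 - start1, start1 = 0L)]
      dt[start2 < 0L, `:=`(end2 = end2 - start2, start2 = 0L)]
      dt <- canonicalize_pets(dt)
      dup <- runif(nrow(dt)) < cfg$dup_rate
      emitted <- rbind(dt, dt[dup])
      list(unique_pets = dt, emitted = emitted,
           dup_multiplicity = 1L + as.integer(dup),
           bg_distances = bg_pets$m2 - bg_pets$m1)
    }

    cond_a <- gen_condition(loops$true_count)
    cond_b <- gen_condition(pmax(1L, round(loops$true_count *
                                             loops$fold_change)))

    # TF peak sets: planted co-binding at loop anchors + homogeneous decoy
    # peaks whose intensity hits an anchor-width window w.p.
    # p_bind_background
    tf_peaks <- list()
    tf_truth <- list()
    for (spec in cfg$tf_specs) {
      co <- runif(nrow(loops)) < spec$p_cobind_true
      pk <- list()
      if (any(co)) {
        lw <- cfg$peak_width
        pk[[1]] <- data.table(
          chrom = cfg$chrom,
          start = c(loops$c1[co] - lw %/% 2L, loops$c2[co] - lw %/% 2L),
          end = c(loops$c1[co] + lw %/% 2L, loops$c2[co] + lw %/% 2L))
      }
      p_bg <- spec$p_bind_background
      if (p_bg > 0) {
        pw <- 200L
        lam <- -log(1 - min(p_bg, 0.999)) / (cfg$peak_width + pw)
        n_decoy <- rpois(1, lam * cfg$chrom_length)
        if (n_decoy > 0) {
          st <- floor(runif(n_decoy, 0, cfg$chrom_length - pw))
          pk[[length(pk) + 1L]] <- data.table(chrom = cfg$chrom, start = st,
                                              end = st + pw)
        }
      }
      tab <- if (length(pk)) setorder(rbindlist(pk), start)
        else data.table(chrom = character(), start = integer(),
                        end = integer())
      tab[, `:=`(start = as.integer(start), end = as.integer(end))]
      tf_peaks[[spec$name]] <- tab
      tf_truth[[spec$name]] <- co
    }

    truth <- list(loops = loops[, .(id, chrom = cfg$chrom,
                                    start1 = peaks$start[peak1],
                                    end1 = peaks$end[peak1],
                                    start2 = peaks$start[peak2],
                                    end2 = peaks$end[peak2],
                                    c1, c2, true_count, fold_change)],
                  tf_cobind = tf_truth,
                  unique_pets_a = cond_a$unique_pets,
                  unique_pets_b = cond_b$unique_pets,
                  dup_multiplicity_a = cond_a$dup_multiplicity,
                  dup_multiplicity_b = cond_b$dup_multiplicity,
                  bg_distances_a = cond_a$bg_distances,
                  bg_distances_b = cond_b$bg_distances)

    out <- list(pets_a = cond_a$emitted[, !"origin"],
                pets_b = cond_b$emitted[, !"origin"],
                peaks = peaks[, .(chrom, start, end, name)],
                tss = tss, tf_peaks = tf_peaks, truth = truth,
                config = cfg)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_bedpe(out$pets_a, file.path(dir, "pets_a.bedpe"))
    write_bedpe(out$pets_b, file.path(dir, "pets_b.bedpe"))
    write_bed(out$peaks, file.path(dir, "peaks.bed"))
    write_bed(out$tss, file.path(dir, "tss.bed"))
    for (f in names(out$tf_peaks))
      write_bed(out$tf_peaks[[f]], file.path(dir, paste0("tf_", f, ".bed")))
    fwrite(out$truth$loops, file.path(dir, "truth_loops.tsv"), sep = "\t")
  }
  out
}

#' Check the background distance decay of a simulated dataset
#'
#' Fits the decay exponent alpha by log-log OLS on the background-distance
#' histogram (per-bp density over log-spaced bins) and compares with the
#' configured value.
#'
#' @param distances Background PET distances (>= 10,000 values).
#' @param config The generating [sim_config()] (optional, for reference).
#' @param n_bins Histogram bins (default 30).
#' @return A list with `alpha_hat` and, when `config` is given,
#'   `alpha_true`.
#' @export
background_distance_check <- function(distances, config = NULL,
                                      n_bins = 30L) {
  d <- distances[distances > 0]
  if (length(d) < 10000L)
    stop("need at least 10,000 background PETs to fit the decay")
  lg <- log10(d)
  # avoid the truncation edge: fit the central part of the support
  br <- seq(quantile(lg, 0.01), quantile(lg, 0.95), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(lg, br, rightmost.closed = TRUE), n_bins)
  width_bp <- 10^br[-1L] - 10^br[-(n_bins + 1L)]
  dens <- cnt / width_bp
  mid <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  ok <- dens > 0
  fit <- lm(log10(dens[ok]) ~ mid[ok])
  out <- list(alpha_hat = -unname(coef(fit)[2]))
  if (!is.null(config)) out$alpha_true <- config$decay_alpha
  out
}
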