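# Independent oracles used to pin expected values. These deliberately use
# naive algorithms (O(n^2) scans, direct PMF summation, textbook formulas)
# and stay independent of the implementation paths they check.

# textbook DBSCAN, O(n^2) distance matrix; identical deterministic rules to
# the grid implementation (points sorted by (x, y), neighbour lists in index
# order, FIFO seed expansion, border -> first discovered core's cluster)
dbscan_naive <- function(x, y, eps, minPts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  ord <- order(x, y)
  xs <- x[ord]; ys <- y[ord]
  d2 <- outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  lab <- rep(NA_integer_, n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    N <- nbr[[i]]
    if (length(N) < minPts) next
    cl <- cl + 1L
    lab[i] <- cl
    seeds <- N
    k <- 1L
    while (k <= length(seeds)) {
      q <- seeds[k]; k <- k + 1L
      if (is.na(lab[q])) lab[q] <- cl
      if (!visited[q]) {
        visited[q] <- TRUE
        Nq <- nbr[[q]]
        if (length(Nq) >= minPts) seeds <- c(seeds, Nq)
      }
    }
  }
  out <- rep(NA_integer_, n)
  out[ord] <- lab
  out
}

# O(n) rectangle-count scan over a PET table (midpoint semantics, half-open)
rect_count_naive <- function(pets_dt, chrom, x1, x2, y1, y2) {
  m1 <- floor((pets_dt$start1 + pets_dt$end1) / 2)
  m2 <- floor((pets_dt$start2 + pets_dt$end2) / 2)
  sum(pets_dt$chrom1 == chrom & pets_dt$chrom2 == chrom &
        m1 >= x1 & m1 < x2 & m2 >= y1 & m2 < y2)
}

# phi coefficient on paired binary vectors
phi_coefficient <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# literal term-by-term evaluation of the differential Poisson formula
poisson_diff_p_naive <- function(fg, lambda) {
  if (fg <= 1) return(1)
  1 - sum(dpois(seq_len(fg - 1), lambda))
}

# upper Poisson tail P(X >= k) by direct summation (bounded support scan)
poisson_tail_naive <- function(k, lambda, upper = 10000L) {
  if (k <= 0) return(1)
  1 - sum(dpois(0:(k - 1), lambda))
}

# evaluate expr under a local seed (does not disturb the global RNG stream)
with_seed <- function(seed, expr) petloops:::withr_seed(seed, expr)

# random PET table on one chromosome for property tests
random_pets <- function(n, chrom = "chrT", L = 1e6, seed = 1) {
  with_seed(seed, {
    a <- floor(runif(n, 0, L - 100))
    b <- floor(runif(n, 0, L - 100))
    pets(chrom1 = chrom, start1 = pmin(a, b), end1 = pmin(a, b) + 50,
         chrom2 = chrom, start2 = pmax(a, b), end2 = pmax(a, b) + 50)
  })
}

tmpf <- function() tempfile(fileext = ".txt")
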