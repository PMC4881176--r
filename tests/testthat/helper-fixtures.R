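# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# A probe profile of Gaussian noise with optional planted segments.
# segments: list of list(chrom=, from=, to= (probe indices), height=)
noise_profile <- function(id = "s1", n = 300L, chroms = "chr1",
                          spacing = 1000L, sd = 0.2, segments = list(),
                          tissue = "tumor", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- rep(chroms, each = n)
  pos <- rep((seq_len(n) - 1L) * spacing + 1L, times = length(chroms))
  x <- stats::rnorm(n * length(chroms), 0, sd)
  for (seg in segments) {
    rows <- which(chrom == seg$chrom)[seg$from:seg$to]
    x[rows] <- x[rows] + seg$height
  }
  probe_profile(id, chrom, pos, x, tissue = tissue)
}

# A decomposed_profile fabricated directly from an fcnv vector, for tests of
# operations that consume the documented shape (calling, CNP counting).
fake_decomposed <- function(fcnv, epsilon, id = "s1", chrom = "chr1",
                            pos = NULL, bcnv = NULL, tissue = "tumor") {
  if (is.null(pos)) pos <- seq_along(fcnv) * 1000L
  if (is.null(bcnv)) bcnv <- rep(0, length(fcnv))
  d <- data.frame(chrom = chrom, pos = as.integer(pos),
                  reduced = bcnv + fcnv, bcnv = bcnv, fcnv = fcnv,
                  stringsAsFactors = FALSE)
  structure(d, sample_id = id, tissue = tissue, w = 51L, wb = 641L,
            step = 17L, epsilon = epsilon,
            class = c("decomposed_profile", "data.frame"))
}

# A call_track fabricated from a state character vector.
fake_calls <- function(states, id = "s1", chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_along(states) * 1000L
  ct <- data.frame(chrom = chrom, pos = as.integer(pos),
                   state = factor(states, levels = c("loss", "neutral", "gain")),
                   stringsAsFactors = FALSE)
  structure(ct, sample_id = id, k = 3, epsilon = 0.1,
            class = c("call_track", "data.frame"))
}

# A frequency_track fabricated from count vectors.
fake_track <- function(n_gain, n_loss = rep(0L, length(n_gain)),
                       chrom = "chr1", pos = NULL, n_samples = NULL) {
  if (is.null(pos)) pos <- seq_along(n_gain) * 1000L
  if (is.null(n_samples)) n_samples <- max(n_gain + n_loss, 1L)
  ft <- data.frame(chrom = chrom, pos = as.integer(pos),
                   n_gain = as.integer(n_gain), n_loss = as.integer(n_loss),
                   stringsAsFactors = FALSE)
  structure(ft, n_samples = n_samples,
            class = c("frequency_track", "data.frame"))
}

# Independent running-median oracle for interior sites (full centered
# windows); boundary sites are end-rule territory and are checked separately
# for their qualitative properties.
oracle_runmed_interior <- function(y, k) {
  n <- length(y)
  half <- (k - 1L) %/% 2L
  vapply((half + 1L):(n - half), function(i)
    stats::median(y[(i - half):(i + half)]), 1.0)
}

# Exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum the hypergeometric probabilities of those no more probable
# than the observed table.
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(a, m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
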