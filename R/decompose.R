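#' Mode of a signal distribution via kernel density
#'
#' Estimates the mode as the argmax of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth, 512-point grid spanning the data
#' range). For a log-ratio profile the mode is the signal level of the
#' dominant (copy-neutral) state, which mode normalization maps to zero.
#' Ties on the grid resolve to the smaller value.
#'
#' @param values Numeric vector of at least 10 finite values.
#' @return The estimated mode (same units as `values`).
#' @export
estimate_mode <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("estimate_mode needs >= 10 finite values")
  if (stats::sd(values) == 0) return(values[1])
  d <- stats::density(values, bw = "nrd0", n = 512L)
  d$x[which.max(d$y)]
}

#' Mode-normalize a probe profile
#'
#' Subtracts the genome-wide mode of the log2 signals so the dominant copy
#' state sits at zero. Normalization is idempotent up to the density-grid
#' resolution.
#'
#' @param profile A [probe_profile].
#' @return The profile with centered signals.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "probe_profile"))
  profile$log2 <- profile$log2 - estimate_mode(profile$log2)
  profile
}

#' Running median with Tukey end rule
#'
#' Order-statistic smoother: each value is replaced by the median of the
#' odd-width window centered on it. The `(w-1)/2` sites at each boundary use
#' symmetric windows of decreasing odd width (Tukey's end rule), so output
#' length equals input length. Robust to isolated spikes and preserves step
#' edges, which makes it suited to piecewise-constant copy-number signals.
#'
#' @param values Numeric vector (one chromosome's worth of signal).
#' @param w Odd window width in sites, `1 <= w <= length(values)`.
#' @return Numeric vector of the same length.
#' @export
running_median <- function(values, w) {
  if (length(w) != 1L || w %% 2L == 0L)
    stop("window width w must be a single odd integer")
  if (w < 1L || w > length(values))
    stop("window width w must satisfy 1 <= w <= length(values)")
  if (w == 1L) return(values)
  as.numeric(stats::runmed(values, k = w, endrule = "median"))
}

#' Reduced-grid indices for downsampling a smoothed profile
#'
#' After smoothing with window `w` neighboring sites are nearly redundant, so
#' the smoothed profile is retained only at indices `1, 1+s, 1+2s, ...` with
#' step `s = round(w/3)` (round-half-to-even), and the final index `n` is
#' appended when not already retained.
#'
#' @param n Chromosome length in probes.
#' @param w Odd smoothing window in probes (`w >= 3`).
#' @return Integer vector of retained indices.
#' @export
downsample_indices <- function(n, w) {
  if (w < 3L) stop("downsampling requires w >= 3")
  s <- max(1L, as.integer(round(w / 3)))
  if (n <= s) return(unique(c(1L, as.integer(n))))
  idx <- seq.int(1L, n, by = s)
  if (idx[length(idx)] != n) idx <- c(idx, as.integer(n))
  idx
}

odd_window <- function(k) {
  k <- max(1L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Convert a physical window span to an odd probe-count window
#'
#' @param span_bp Window span in base pairs.
#' @param spacing_bp Median probe spacing in base pairs.
#' @return Nearest odd probe count covering `span_bp`.
#' @export
window_from_span <- function(span_bp, spacing_bp) odd_window(span_bp / spacing_bp)

#' Split a reduced profile into broad and focal components
#'
#' The broad component is the running median of the reduced profile with a
#' long window `wb` (per chromosome); the focal component is the exact
#' difference, so `bcnv + fcnv == reduced` at every site. Events spanning
#' fewer than `wb/2` reduced sites cannot move the broad track (away from
#' chromosome ends), which is what isolates focal changes. On chromosomes
#' with fewer than `wb` reduced sites the window is clipped to the largest
#' odd value that fits.
#'
#' @param reduced Data frame with columns `chrom`, `pos`, `reduced`.
#' @param wb Odd broad window in reduced sites.
#' @return `reduced` with added columns `bcnv`, `fcnv`.
#' @export
split_broad_focal <- function(reduced, wb) {
  if (wb %% 2L == 0L) stop("broad window wb must be odd")
  parts <- lapply(split(reduced, factor(reduced$chrom, unique(reduced$chrom))),
                  function(d) {
    w_eff <- min(wb, if (nrow(d) %% 2L == 1L) nrow(d) else nrow(d) - 1L)
    d$bcnv <- running_median(d$reduced, max(1L, w_eff))
    d$fcnv <- d$reduced - d$bcnv
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Robust noise level of a focal track
#'
#' The per-sample noise of the focal component is estimated as
#' `1.4826 * MAD` of the genome-wide focal values about their median — the
#' normal-consistent scaled median absolute deviation. True focal events are
#' rare and extreme, so the MAD ignores them where a plain standard deviation
#' would inflate.
#'
#' @param fcnv Numeric vector of focal values (>= 30 finite values).
#' @return The noise estimate (log2 units, > 0).
#' @export
estimate_epsilon <- function(fcnv) {
  fcnv <- fcnv[is.finite(fcnv)]
  if (length(fcnv) < 30L)
    stop("estimate_epsilon needs >= 30 finite focal values")
  eps <- stats::mad(fcnv)
  if (eps <= 0)
    stop("degenerate focal track (all values equal); input looks corrupt")
  eps
}

# Vector-level decomposition core for one chromosome of an already
# mode-normalized signal: smooth, downsample, split broad/focal.
decompose_chrom <- function(xnorm, w, wb) {
  n <- length(xnorm)
  w_small <- if (n >= w) w else if (n %% 2L == 1L) n else n - 1L
  sm <- running_median(xnorm, w_small)
  idx <- downsample_indices(n, w)
  red <- sm[idx]
  m <- length(red)
  w_broad <- max(1L, min(wb, if (m %% 2L == 1L) m else m - 1L))
  b <- running_median(red, w_broad)
  list(idx = idx, reduced = red, bcnv = b, fcnv = red - b)
}

#' Decompose a probe profile into broad and focal components
#'
#' Full chain: mode normalization of the raw profile; per-chromosome running
#' median with the small window `w` (noise suppression — events narrower than
#' `w/2` probes are removed); downsampling to a reduced grid with step
#' `round(w/3)`; per-chromosome running median with the long window `wb` to
#' obtain the broad component; focal component by exact subtraction; robust
#' noise estimate of the focal track.
#'
#' Windows may be given as probe/site counts (`w`, `wb`) or as physical
#' spans (`w_bp`, `wb_bp`) converted through the profile's median probe
#' spacing; counts win when both are supplied.
#'
#' @param profile A [probe_profile].
#' @param w Odd small window in probes (default 51).
#' @param wb Odd broad window in reduced sites (default 641).
#' @param w_bp,wb_bp Optional physical window spans in base pairs.
#' @return A `decomposed_profile`: data frame with columns `chrom`, `pos`,
#'   `reduced`, `bcnv`, `fcnv` on the reduced grid, and attributes
#'   `sample_id`, `tissue`, `w`, `wb`, `step`, `epsilon`.
#' @export
decompose_profile <- function(profile, w = 51L, wb = 641L,
                              w_bp = NULL, wb_bp = NULL) {
  stopifnot(inherits(profile, "probe_profile"))
  spacing <- stats::median(unlist(lapply(split(profile$pos, profile$chrom), diff)))
  if (missing(w) && !is.null(w_bp)) w <- window_from_span(w_bp, spacing)
  step <- max(1L, as.integer(round(w / 3)))
  if (missing(wb) && !is.null(wb_bp)) wb <- window_from_span(wb_bp, spacing * step)
  if (w %% 2L == 0L || wb %% 2L == 0L) stop("windows w and wb must be odd")

  xnorm <- profile$log2 - estimate_mode(profile$log2)
  chr_rows <- split(seq_len(nrow(profile)),
                    factor(profile$chrom, unique(profile$chrom)))
  parts <- lapply(chr_rows, function(rows) {
    dc <- decompose_chrom(xnorm[rows], w, wb)
    data.frame(chrom = profile$chrom[rows[1]], pos = profile$pos[rows][dc$idx],
               reduced = dc$reduced, bcnv = dc$bcnv, fcnv = dc$fcnv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out,
            sample_id = attr(profile, "sample_id"),
            tissue = attr(profile, "tissue"),
            w = as.integer(w), wb = as.integer(wb), step = step,
            epsilon = estimate_epsilon(out$fcnv),
            class = c("decomposed_profile", "data.frame"))
}

#' @export
print.decomposed_profile <- function(x, ...) {
  cat(sprintf(
    "decomposed_profile: sample %s (%s), %d reduced sites, w=%d wb=%d, epsilon=%.4g\n",
    attr(x, "sample_id"), attr(x, "tissue"), nrow(x),
    attr(x, "w"), attr(x, "wb"), attr(x, "epsilon")))
  invisible(x)
}

#' Decompose every profile in a cohort
#'
#' @param profiles List of [probe_profile] objects.
#' @param ... Passed to [decompose_profile].
#' @return Named list of `decomposed_profile` objects.
#' @export
decompose_cohort <- function(profiles, ...) {
  out <- lapply(profiles, decompose_profile, ...)
  names(out) <- vapply(out, function(d) attr(d, "sample_id"), "")
  out
}
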