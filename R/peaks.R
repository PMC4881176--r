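# Local maxima of a count vector under a centered scanning window (clipped
# at the ends). Runs of consecutive tied qualifying sites collapse to their
# middle site: a plateau has no unique apex.
local_peak_sites <- function(v, window, min_height) {
  m <- length(v)
  half <- (window - 1L) %/% 2L
  qual <- logical(m)
  for (i in seq_len(m)) {
    if (v[i] < min_height) next
    lo <- max(1L, i - half)
    hi <- min(m, i + half)
    qual[i] <- v[i] == max(v[lo:hi])
  }
  idx <- which(qual)
  if (!length(idx)) return(integer(0))
  grp <- cumsum(c(TRUE, diff(idx) != 1L | diff(v[idx]) != 0))
  vapply(split(idx, grp), function(g) g[ceiling(length(g) / 2)], 1L)
}

#' Locate recurrence peaks in a cohort frequency track
#'
#' A site is a peak when its gain (or loss) count equals the maximum over
#' the scanning window centered on it and reaches the minimum height; peaks
#' below the height floor are discarded. Scanning is independent per
#' chromosome and per direction, and ties along a plateau collapse to the
#' middle site.
#'
#' @param track A `frequency_track` from [aggregate_frequency_track].
#' @param direction `"gain"`, `"loss"`, or `"both"`.
#' @param window Odd scanning window in reduced sites (default 41).
#' @param min_height Minimum peak height in samples (default 8).
#' @return A `peak_set` data frame: `chrom`, `site`, `pos`, `direction`,
#'   `height`.
#' @export
find_peaks <- function(track, direction = c("gain", "loss", "both"),
                       window = 41L, min_height = 8L) {
  direction <- match.arg(direction)
  if (window %% 2L == 0L) stop("scanning window must be odd")
  if (nrow(track) == 0L) stop("empty frequency track")
  dirs <- if (direction == "both") c("gain", "loss") else direction
  out <- list()
  for (dir in dirs) {
    col <- if (dir == "gain") "n_gain" else "n_loss"
    for (chr in unique(track$chrom)) {
      d <- track[track$chrom == chr, , drop = FALSE]
      sites <- local_peak_sites(d[[col]], window, min_height)
      if (length(sites))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, site = sites, pos = d$pos[sites], direction = dir,
          height = d[[col]][sites], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), site = integer(), pos = integer(),
                  direction = character(), height = integer(),
                  stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, window = as.integer(window), min_height = min_height,
            class = c("peak_set", "data.frame"))
}

#' Bootstrap confidence intervals for peak positions
#'
#' Resamples patient profiles with replacement (cohort size preserved) `B`
#' times; for each replicate the frequency track and its peaks are recomputed
#' with identical parameters, and each original peak is matched to the
#' nearest replicate peak on the same chromosome and direction (base-pair
#' distance, ties toward the smaller position). The interval is the
#' `[2.5, 97.5]` percentile range (type-1 quantiles, so `B = 2` degenerates
#' to `[min, max]`) of the matched positions, clamped to the chromosome's
#' probed range. A replicate with no peak on a chromosome contributes no
#' matched position for that peak; when more than half the replicates
#' contribute none the interval is marked undefined.
#'
#' @param calls Cohort of `call_track`s (or a prebuilt call matrix).
#' @param peaks A `peak_set` derived from these calls.
#' @param B Number of bootstrap resamples (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for reproducibility.
#' @return `peaks` with columns `ci_lo`, `ci_hi`, `n_boot` (matched
#'   replicates) and `ci_defined` added.
#' @export
bootstrap_peak_ci <- function(calls, peaks, B = 500L, level = 0.95,
                              seed = NULL) {
  if (B < 2L) stop("need at least 2 bootstrap resamples")
  cm <- as_call_matrix(calls)
  window <- attr(peaks, "window")
  min_height <- attr(peaks, "min_height")
  if (is.null(window)) window <- 41L
  if (is.null(min_height)) min_height <- 8L
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(cm$states)
  G <- (cm$states == 1L) * 1
  L <- (cm$states == -1L) * 1
  chroms <- unique(cm$sites$chrom)
  chr_idx <- lapply(chroms, function(ch) which(cm$sites$chrom == ch))
  names(chr_idx) <- chroms
  need_dir <- unique(peaks$direction)

  matched <- matrix(NA_real_, nrow = nrow(peaks), ncol = B)
  for (b in seq_len(B)) {
    wts <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    cg <- if ("gain" %in% need_dir) as.vector(G %*% wts)
    cl <- if ("loss" %in% need_dir) as.vector(L %*% wts)
    for (p in seq_len(nrow(peaks))) {
      ci <- chr_idx[[peaks$chrom[p]]]
      v <- if (peaks$direction[p] == "gain") cg[ci] else cl[ci]
      sites <- local_peak_sites(v, window, min_height)
      if (!length(sites)) next
      bp <- cm$sites$pos[ci][sites]
      dist <- abs(bp - peaks$pos[p])
      matched[p, b] <- min(bp[dist == min(dist)])
    }
  }
  alpha <- (1 - level) / 2
  peaks$ci_lo <- NA_integer_
  peaks$ci_hi <- NA_integer_
  peaks$n_boot <- as.integer(rowSums(!is.na(matched)))
  peaks$ci_defined <- peaks$n_boot > B / 2
  for (p in seq_len(nrow(peaks))) {
    if (!peaks$ci_defined[p]) next
    q <- stats::quantile(matched[p, ], c(alpha, 1 - alpha),
                         na.rm = TRUE, type = 1, names = FALSE)
    rng <- range(cm$sites$pos[chr_idx[[peaks$chrom[p]]]])
    # interval always contains the original apex and stays in probed range
    peaks$ci_lo[p] <- as.integer(min(max(q[1], rng[1]), peaks$pos[p]))
    peaks$ci_hi[p] <- as.integer(max(min(q[2], rng[2]), peaks$pos[p]))
  }
  n_none <- sum(!peaks$ci_defined)
  if (n_none > 0L)
    message(sprintf(
      "bootstrap_peak_ci: %d peak(s) matched in <= half the replicates; CI undefined",
      n_none))
  peaks
}
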