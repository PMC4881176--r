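#' Count copy-number polymorphisms per normal sample
#'
#' Germline copy-number polymorphisms (CNPs) are detected in normal-tissue
#' focal tracks as sites with `|fcnv| > k * epsilon`. A stringent multiplier
#' (default 5) keeps the per-sample count near zero for clean noise-only
#' profiles, so elevated counts flag either real polymorphism load or
#' contaminated / poor-quality samples.
#'
#' @param decomposed_normals List of `decomposed_profile` objects with
#'   tissue `"normal"`.
#' @param k Threshold multiplier (default 5).
#' @return A `cnp_summary` data frame: `sample_id`, `n_cnp`.
#' @export
count_cnp_per_normal_sample <- function(decomposed_normals, k = 5) {
  if (inherits(decomposed_normals, "decomposed_profile"))
    decomposed_normals <- list(decomposed_normals)
  bad <- vapply(decomposed_normals,
                function(d) !identical(attr(d, "tissue"), "normal"), TRUE)
  if (any(bad))
    stop("count_cnp_per_normal_sample expects normal-tissue profiles only")
  out <- data.frame(
    sample_id = vapply(decomposed_normals,
                       function(d) as.character(attr(d, "sample_id")), ""),
    n_cnp = vapply(decomposed_normals, function(d)
      sum(abs(d$fcnv) > k * attr(d, "epsilon")), 1L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, k = k, class = c("cnp_summary", "data.frame"))
}

#' Flag CNP-outlier normal samples
#'
#' Normals with an excessive CNP count (suggesting tumor contamination or
#' poor data quality) are flagged by an upper Tukey fence,
#' `count > Q3 + rule * IQR`, and should be excluded from polymorphism
#' filtering.
#'
#' @param summary A `cnp_summary` from [count_cnp_per_normal_sample] with at
#'   least 5 samples.
#' @param rule Fence multiplier (default 3; `Inf` flags none).
#' @return The summary with a logical `outlier` column.
#' @export
flag_cnp_outliers <- function(summary, rule = 3) {
  if (nrow(summary) < 5L)
    stop("outlier fencing needs >= 5 normal samples")
  q <- stats::quantile(summary$n_cnp, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + rule * (q[2] - q[1])
  summary$outlier <- summary$n_cnp > fence
  if (any(summary$outlier))
    message(sprintf("flag_cnp_outliers: %d of %d normal sample(s) flagged",
                    sum(summary$outlier), nrow(summary)))
  summary
}

#' Number of normal samples with an event inside an interval
#'
#' Counts the retained normal samples having at least one gain-or-loss call
#' at any reduced site within `[start, end]` on `chrom`. Samples are counted
#' once regardless of how many sites their event spans.
#'
#' @param normal_calls List of normal-tissue `call_track`s (outliers already
#'   removed).
#' @param chrom Chromosome of the interval.
#' @param start,end Interval bounds, 1-based inclusive.
#' @return Integer count of affected samples.
#' @export
normal_event_count_in_interval <- function(normal_calls, chrom, start, end) {
  if (inherits(normal_calls, "call_track")) normal_calls <- list(normal_calls)
  in_any <- vapply(normal_calls, function(ct) {
    hit <- ct$chrom == chrom & ct$pos >= start & ct$pos <= end
    if (!any(hit)) return(FALSE)
    any(ct$state[hit] != "neutral")
  }, TRUE)
  covered <- any(vapply(normal_calls, function(ct)
    any(ct$chrom == chrom & ct$pos >= start & ct$pos <= end), TRUE))
  if (length(normal_calls) && !covered)
    warning("interval outside the probed range; normal event count is 0")
  sum(in_any)
}

#' Exact test for gain/loss count asymmetry
#'
#' Recurrent driver regions should be dominated by one direction of change;
#' under the no-preference null each affected sample is equally likely to
#' carry a gain or a loss. An exact binomial (sign) test against p = 0.5 is
#' applied to the counts: two-sided for region selection ("significantly
#' different"), one-sided for testing an excess of gains.
#'
#' @param n_gain,n_loss Non-negative counts with `n_gain + n_loss >= 1`.
#' @param sided `"two"` or `"one"` (one-sided tests gain > loss).
#' @return The p-value.
#' @export
gain_loss_asymmetry_test <- function(n_gain, n_loss, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_gain + n_loss < 1) {
    warning("no gains or losses; asymmetry test undefined, returning p = 1")
    return(1)
  }
  alt <- if (sided == "two") "two.sided" else "greater"
  stats::binom.test(n_gain, n_gain + n_loss, p = 0.5,
                    alternative = alt)$p.value
}

#' Select recurrent focal regions from peaks
#'
#' Applies the four selection criteria to bootstrap-annotated peaks:
#' (1) peak height at least `min_height` samples; (2) confidence-interval
#' width under `max_ci_width` base pairs; (3) fewer than `max_normal_events`
#' retained normal samples with an event inside the interval (skipped and
#' reported as not evaluated when no normals are supplied); (4) gain and
#' loss counts at the peak site significantly asymmetric at level `alpha`.
#' A region is selected iff all evaluated criteria hold.
#'
#' @param peaks A `peak_set` with `ci_lo`/`ci_hi` from [bootstrap_peak_ci].
#' @param track The cohort `frequency_track` (supplies the opposite-direction
#'   count at each peak site for the asymmetry test).
#' @param normal_calls Optional list of retained normal `call_track`s.
#' @param alpha Significance level for criterion 4 (default 0.05).
#' @param max_ci_width Maximum CI width in base pairs (default 1e6).
#' @param max_normal_events Criterion-3 cap: the normal-sample event count
#'   must be strictly below this (default 4).
#' @param min_height Criterion-1 floor (default 8).
#' @param sided Sidedness of the asymmetry test (default two-sided).
#' @return A `focal_regions` data frame with per-criterion flags
#'   (`flag_height`, `flag_ci_width`, `flag_normal`, `flag_asymmetry`),
#'   `normal_evaluated`, `n_gain`, `n_loss`, `n_normal_events`,
#'   `p_asymmetry` and `selected`.
#' @export
select_focal_regions <- function(peaks, track, normal_calls = NULL,
                                 alpha = 0.05, max_ci_width = 1e6,
                                 max_normal_events = 4, min_height = 8,
                                 sided = c("two", "one")) {
  sided <- match.arg(sided)
  rg <- as.data.frame(peaks)
  if (!all(c("ci_lo", "ci_hi") %in% names(rg)))
    stop("peaks must carry bootstrap confidence intervals")
  n <- nrow(rg)
  rg$n_gain <- rg$n_loss <- integer(n)
  rg$p_asymmetry <- numeric(n)
  rg$n_normal_events <- NA_integer_
  rg$normal_evaluated <- !is.null(normal_calls) && length(normal_calls) > 0
  for (i in seq_len(n)) {
    at <- which(track$chrom == rg$chrom[i] & track$pos == rg$pos[i])
    rg$n_gain[i] <- track$n_gain[at[1]]
    rg$n_loss[i] <- track$n_loss[at[1]]
    rg$p_asymmetry[i] <- gain_loss_asymmetry_test(rg$n_gain[i], rg$n_loss[i],
                                                  sided = sided)
    if (rg$normal_evaluated[i] && !is.na(rg$ci_lo[i]))
      rg$n_normal_events[i] <- normal_event_count_in_interval(
        normal_calls, rg$chrom[i], rg$ci_lo[i], rg$ci_hi[i])
  }
  rg$flag_height <- rg$height >= min_height
  rg$flag_ci_width <- !is.na(rg$ci_lo) & (rg$ci_hi - rg$ci_lo) < max_ci_width
  rg$flag_normal <- ifelse(rg$normal_evaluated,
                           rg$n_normal_events < max_normal_events, TRUE)
  rg$flag_asymmetry <- rg$p_asymmetry < alpha
  rg$selected <- rg$flag_height & rg$flag_ci_width & rg$flag_normal &
    rg$flag_asymmetry
  structure(rg, alpha = alpha, max_ci_width = max_ci_width,
            max_normal_events = max_normal_events, min_height = min_height,
            class = c("focal_regions", "data.frame"))
}
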