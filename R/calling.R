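#' Classify focal values into gain / neutral / loss
#'
#' A site is a gain when the focal value exceeds `k * epsilon`, a loss when
#' it falls below `-k * epsilon`, and neutral otherwise. Inequalities are
#' strict, so a value exactly at the threshold is neutral.
#'
#' @param fcnv Numeric vector of focal values.
#' @param epsilon Noise level of the focal track (> 0).
#' @param k Threshold multiplier (default 3).
#' @return Factor with levels `loss`, `neutral`, `gain`.
#' @export
classify_fcnv <- function(fcnv, epsilon, k = 3) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  state <- rep("neutral", length(fcnv))
  state[fcnv > k * epsilon] <- "gain"
  state[fcnv < -k * epsilon] <- "loss"
  factor(state, levels = c("loss", "neutral", "gain"))
}

#' Three-state calls for a decomposed profile
#'
#' @param decomposed A `decomposed_profile` (see [decompose_profile]).
#' @param k Threshold multiplier in units of the sample's focal noise
#'   `epsilon` (default 3; germline-polymorphism screening of normals uses 5).
#' @return A `call_track`: data frame with `chrom`, `pos`, `state` and
#'   attributes `sample_id`, `k`, `epsilon`.
#' @export
call_states <- function(decomposed, k = 3) {
  stopifnot(inherits(decomposed, "decomposed_profile"))
  eps <- attr(decomposed, "epsilon")
  ct <- data.frame(chrom = decomposed$chrom, pos = decomposed$pos,
                   state = classify_fcnv(decomposed$fcnv, eps, k),
                   stringsAsFactors = FALSE)
  structure(ct, sample_id = attr(decomposed, "sample_id"),
            tissue = attr(decomposed, "tissue"), k = k, epsilon = eps,
            class = c("call_track", "data.frame"))
}

#' Call states for every decomposed profile in a cohort
#'
#' @param decomposed_list List of `decomposed_profile` objects.
#' @param k Threshold multiplier.
#' @return Named list of `call_track` objects.
#' @export
call_cohort <- function(decomposed_list, k = 3) {
  out <- lapply(decomposed_list, call_states, k = k)
  names(out) <- vapply(out, function(d) attr(d, "sample_id"), "")
  out
}

# Dense cohort representation: sites data frame + integer state matrix
# (sites x samples; -1 loss, 0 neutral, +1 gain). All tracks must share one
# reduced grid.
as_call_matrix <- function(calls) {
  if (inherits(calls, "call_matrix")) return(calls)
  if (inherits(calls, "call_track")) calls <- list(calls)
  ref <- calls[[1]]
  for (i in seq_along(calls)) {
    ct <- calls[[i]]
    if (nrow(ct) != nrow(ref) || any(ct$chrom != ref$chrom) ||
        any(ct$pos != ref$pos)) {
      j <- if (nrow(ct) == nrow(ref))
        which(ct$chrom != ref$chrom | ct$pos != ref$pos)[1] else 1L
      stop(sprintf(
        "call tracks are not on a common site grid (sample %d, first mismatch at site %d)",
        i, j))
    }
  }
  states <- vapply(calls, function(ct) unclass(ct$state) - 2L,
                   integer(nrow(ref)))
  structure(list(sites = data.frame(chrom = ref$chrom, pos = ref$pos,
                                    stringsAsFactors = FALSE),
                 states = states,
                 sample_ids = vapply(calls, function(ct)
                   as.character(attr(ct, "sample_id")), "")),
            class = "call_matrix")
}

#' Per-site cohort counts of gains and losses
#'
#' Aggregates a cohort of call tracks into the per-site numbers of samples
#' called gain and called loss — the cohort's focal-variation landscape.
#'
#' @param calls List of `call_track` objects on a common reduced grid (a
#'   mismatch raises an error naming the first differing site).
#' @return A `frequency_track`: data frame with `chrom`, `pos`, `n_gain`,
#'   `n_loss` and attribute `n_samples`.
#' @export
aggregate_frequency_track <- function(calls) {
  cm <- as_call_matrix(calls)
  ft <- data.frame(cm$sites,
                   n_gain = as.integer(rowSums(cm$states == 1L)),
                   n_loss = as.integer(rowSums(cm$states == -1L)),
                   stringsAsFactors = FALSE)
  structure(ft, n_samples = ncol(cm$states),
            class = c("frequency_track", "data.frame"))
}
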