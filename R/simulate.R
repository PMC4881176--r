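#' Simulation configuration
#'
#' Describes a synthetic cohort used to assess detection sensitivity and
#' specificity: one synthetic chromosome of `L` equally spaced probes per
#' profile, `N` patients each with a normal and a tumor profile of iid
#' Gaussian probe noise (sd `noise_sd`), and — in a fraction `f` of patients
#' — a single amplicon of height `h` log2 units over `n_amp` probes centered
#' at probe `L/2` of the tumor profile. Defaults reflect the study design
#' this harness emulates: 16,000 probes, 500 patients, unit probe noise.
#'
#' @param L Probes per profile (default 16000).
#' @param N Patients (default 500).
#' @param noise_sd Raw probe noise standard deviation (default 1).
#' @param f Carrier fraction in `[0, 1]`.
#' @param h Amplicon height in log2 units.
#' @param n_amp Amplicon width in probes (`< L`).
#' @param w,wb Pipeline windows (defaults 51 / 641; `wb` is clipped per
#'   chromosome when the reduced grid is shorter).
#' @param spacing_bp Physical probe spacing in base pairs (default 3000,
#'   typical of a ~1M-probe whole-genome array; the simulated chromosome
#'   then spans `L * spacing_bp` base pairs).
#' @param reps Replicate cohorts for [run_simulation].
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(L = 16000L, N = 500L, noise_sd = 1, f = 0.1, h = 1,
                       n_amp = 50L, w = 51L, wb = 641L, spacing_bp = 3000L,
                       reps = 1L, seed = 1L) {
  stopifnot(f >= 0, f <= 1, n_amp < L, w %% 2L == 1L, wb %% 2L == 1L)
  structure(list(L = as.integer(L), N = as.integer(N), noise_sd = noise_sd,
                 f = f, h = h, n_amp = as.integer(n_amp), w = as.integer(w),
                 wb = as.integer(wb), spacing_bp = as.integer(spacing_bp),
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sim_config")
}

amplicon_probes <- function(config) {
  start <- as.integer(floor(config$L / 2 - config$n_amp / 2)) + 1L
  seq.int(start, length.out = config$n_amp)
}

#' Simulate a cohort of paired normal/tumor profiles
#'
#' Carrier patients are drawn without replacement (`floor(f * N)` of them);
#' their tumor profiles carry the amplicon, all other signal is iid Gaussian
#' noise. Probe positions are `1, 1 + spacing, 1 + 2*spacing, ...`.
#'
#' @param config A [sim_config].
#' @param seed Overrides `config$seed` when given.
#' @return A `sim_cohort` list: `tumor` and `normal` (L x N matrices),
#'   `pos`, `chrom`, `carrier` (logical N), `center_probe`, `center_pos`,
#'   `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- config$L; N <- config$N
  normal <- matrix(stats::rnorm(L * N, 0, config$noise_sd), L, N)
  tumor <- matrix(stats::rnorm(L * N, 0, config$noise_sd), L, N)
  n_carrier <- floor(config$f * N)
  if (config$f > 0 && n_carrier == 0L)
    warning("carrier fraction f > 0 but floor(f * N) = 0; no carriers realized")
  carrier <- logical(N)
  if (n_carrier > 0L) {
    carrier[sample.int(N, n_carrier)] <- TRUE
    amp <- amplicon_probes(config)
    tumor[amp, carrier] <- tumor[amp, carrier] + config$h
  }
  pos <- (seq_len(L) - 1L) * config$spacing_bp + 1L
  center_probe <- as.integer(round(L / 2))
  structure(list(tumor = tumor, normal = normal, pos = pos, chrom = "chr1",
                 carrier = carrier, center_probe = center_probe,
                 center_pos = pos[center_probe], config = config,
                 seed = as.integer(seed)),
            class = "sim_cohort")
}

#' Extract probe profiles from a simulated cohort
#'
#' @param cohort A `sim_cohort`.
#' @param tissue `"tumor"` or `"normal"`.
#' @return Named list of [probe_profile] objects.
#' @export
sim_profiles <- function(cohort, tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  m <- cohort[[tissue]]
  out <- lapply(seq_len(ncol(m)), function(j)
    probe_profile(sprintf("%s_%03d", tissue, j), cohort$chrom, cohort$pos,
                  m[, j], tissue = tissue))
  names(out) <- vapply(out, function(p) attr(p, "sample_id"), "")
  out
}

# Decompose + call one simulated signal vector on the single synthetic
# chromosome, staying at the vector level for speed. Numerically identical
# to call_states(decompose_profile(...)) on the same data.
sim_call_track <- function(x, cohort, k = 3) {
  xnorm <- x - estimate_mode(x)
  dc <- decompose_chrom(xnorm, cohort$config$w, cohort$config$wb)
  eps <- estimate_epsilon(dc$fcnv)
  list(pos = cohort$pos[dc$idx],
       state = classify_fcnv(dc$fcnv, eps, k))
}

#' Measure detection performance on one simulated cohort
#'
#' Runs decomposition (windows from the cohort's config) and 3-epsilon
#' calling on every tumor profile, classifies each patient at the reduced
#' site nearest the amplicon center (a carrier called gain is a true
#' positive, a non-carrier called gain a false positive), and tests at that
#' locus whether focal gains significantly outnumber focal losses across the
#' cohort (one-sided exact binomial).
#'
#' @param cohort A `sim_cohort`.
#' @return List with `tpr`, `fnr`, `fpr`, `tnr` (NA when the relevant group
#'   is empty), `n_gain`, `n_loss`, `p_one_sided`, `center_site_pos` and the
#'   per-sample `states` at the center site.
#' @export
evaluate_detection <- function(cohort) {
  cfg <- cohort$config
  states <- character(cfg$N)
  center_site <- NA_integer_
  for (j in seq_len(cfg$N)) {
    ct <- sim_call_track(cohort$tumor[, j], cohort)
    if (is.na(center_site)) {
      dist <- abs(ct$pos - cohort$center_pos)
      center_site <- which(dist == min(dist))[1]
      if (ct$pos[center_site] != cohort$center_pos)
        message(sprintf(
          "evaluate_detection: center probe not on reduced grid; using nearest site at %d bp",
          ct$pos[center_site]))
    }
    states[j] <- as.character(ct$state[center_site])
    center_pos_used <- ct$pos[center_site]
  }
  carrier <- cohort$carrier
  gain <- states == "gain"
  tpr <- if (any(carrier)) mean(gain[carrier]) else NA_real_
  fpr <- if (any(!carrier)) mean(gain[!carrier]) else NA_real_
  n_gain <- sum(gain)
  n_loss <- sum(states == "loss")
  p <- if (n_gain + n_loss >= 1)
    stats::binom.test(n_gain, n_gain + n_loss, 0.5,
                      alternative = "greater")$p.value
  else 1
  list(tpr = tpr, fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
       fpr = fpr, tnr = if (is.na(fpr)) NA_real_ else 1 - fpr,
       n_gain = n_gain, n_loss = n_loss, p_one_sided = p,
       center_site_pos = center_pos_used, states = states)
}

#' Run replicate simulations and summarize detection rates
#'
#' Simulates `config$reps` independent cohorts (seeds `seed, seed + 1, ...`)
#' and evaluates each with [evaluate_detection]. Rates are averaged over
#' replicates with the relevant group present; the locus-level p-value is
#' summarized by its median.
#'
#' @param config A [sim_config].
#' @return A `sim_result` list: averaged `tpr`, `fpr`, `tnr`, `fnr`,
#'   `p_median`, per-replicate data frame `replicates`, and the `config`.
#' @export
run_simulation <- function(config) {
  reps <- lapply(seq_len(config$reps), function(r) {
    res <- evaluate_detection(simulate_cohort(config, seed = config$seed + r - 1L))
    data.frame(rep = r, tpr = res$tpr, fpr = res$fpr, tnr = res$tnr,
               fnr = res$fnr, n_gain = res$n_gain, n_loss = res$n_loss,
               p_one_sided = res$p_one_sided)
  })
  reps <- do.call(rbind, reps)
  structure(list(tpr = mean(reps$tpr, na.rm = TRUE),
                 fpr = mean(reps$fpr, na.rm = TRUE),
                 tnr = mean(reps$tnr, na.rm = TRUE),
                 fnr = mean(reps$fnr, na.rm = TRUE),
                 p_median = stats::median(reps$p_one_sided),
                 replicates = reps, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result (%d replicate(s), N=%d, L=%d, f=%.3g, h=%.3g, n_amp=%d):\n",
    x$config$reps, x$config$N, x$config$L, x$config$f, x$config$h,
    x$config$n_amp))
  cat(sprintf("  TPR=%.4f FNR=%.4f FPR=%.4f TNR=%.4f  median one-sided p=%.4g\n",
              x$tpr, x$fnr, x$fpr, x$tnr, x$p_median))
  invisible(x)
}
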