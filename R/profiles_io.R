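#' Construct a probe-level copy-number profile
#'
#' A probe profile holds log2-transformed probe signals ordered along the
#' genome for one sample. Positions are 1-based base pairs and must be
#' strictly increasing within each chromosome.
#'
#' @param sample_id Sample identifier.
#' @param chrom Character vector of chromosome names, one per probe.
#' @param pos Integer vector of 1-based probe positions.
#' @param log2 Numeric vector of log2-transformed probe signals.
#' @param tissue Either `"tumor"` or `"normal"`.
#' @return A `probe_profile`: a data frame with columns `chrom`, `pos`,
#'   `log2` and attributes `sample_id` and `tissue`.
#' @export
probe_profile <- function(sample_id, chrom, pos, log2, tissue = "tumor") {
  tissue <- match.arg(tissue, c("tumor", "normal"))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(log2))
  if (any(!is.finite(log2)))
    stop("probe signals must be finite; drop missing probes before construction")
  pos <- as.integer(pos)
  if (any(pos < 1L))
    stop("probe positions are 1-based; found position < 1")
  df <- data.frame(chrom = as.character(chrom), pos = pos, log2 = as.numeric(log2),
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  by_chr <- split(df$pos, df$chrom)
  for (chr in names(by_chr)) {
    p <- by_chr[[chr]]
    if (anyDuplicated(p))
      stop(sprintf("duplicate position on %s for sample %s", chr, sample_id))
  }
  if (max(vapply(by_chr, length, 1L)) < 3L)
    stop("profile needs at least one chromosome with >= 3 probes")
  structure(df, sample_id = sample_id, tissue = tissue,
            class = c("probe_profile", "data.frame"))
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("probe_profile: sample %s (%s), %d probes on %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "tissue"), nrow(x),
              length(unique(x$chrom))))
  invisible(x)
}

sample_id <- function(x) attr(x, "sample_id")
tissue_of <- function(x) attr(x, "tissue")

#' Read probe profiles from a tab-delimited file
#'
#' Two dialects are accepted. The long dialect has columns
#' `sample_id`, (optional) `tissue`, `chrom`, `pos`, `log2` — one row per
#' probe per sample. The wide dialect has columns `chrom`, `pos` followed by
#' one column of log2 values per sample; all samples are then assumed to be
#' tumor tissue unless `tissue` says otherwise.
#'
#' Rows with missing signal values are dropped with a message reporting the
#' count. The Y chromosome is dropped by default, matching common practice
#' for mixed-sex copy-number cohorts.
#'
#' @param path Path to a tab-delimited text file with a header line.
#' @param dialect `"long"` or `"wide"`.
#' @param tissue Tissue label applied to every sample in the wide dialect.
#' @param drop_y Drop chromosomes named `Y`/`chrY` on load (default `TRUE`).
#' @return A named list of [probe_profile] objects, one per sample.
#' @export
read_profiles <- function(path, dialect = c("long", "wide"), tissue = "tumor",
                          drop_y = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "chrom", "pos", "log2")
    if (!all(need %in% names(raw)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    if (!("tissue" %in% names(raw))) raw$tissue <- tissue
    long <- raw[, c("sample_id", "tissue", "chrom", "pos", "log2")]
  } else {
    if (!all(c("chrom", "pos") %in% names(raw)))
      stop("wide dialect requires leading columns chrom, pos")
    samples <- setdiff(names(raw), c("chrom", "pos"))
    if (length(samples) == 0L) stop("wide file contains no sample columns")
    long <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample_id = s, tissue = tissue, chrom = raw$chrom,
                 pos = raw$pos, log2 = raw[[s]], stringsAsFactors = FALSE)
    }))
  }
  long$pos <- suppressWarnings(as.integer(long$pos))
  if (any(is.na(long$pos)))
    stop("non-integer probe position in ", path)
  if (is.character(long$log2)) {
    val <- suppressWarnings(as.numeric(long$log2))
    bad <- which(!is.na(long$log2) & long$log2 != "NA" & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric signal value at data line %d of %s", bad[1], path))
    long$log2 <- val
  }
  if (any(long$pos < 1L))
    stop("probe positions are 1-based; found position < 1 in ", path)
  n_missing <- sum(!is.finite(long$log2))
  if (n_missing > 0L) {
    message(sprintf("read_profiles: dropped %d probe(s) with missing signal", n_missing))
    long <- long[is.finite(long$log2), , drop = FALSE]
  }
  if (drop_y)
    long <- long[!(long$chrom %in% c("Y", "chrY")), , drop = FALSE]
  key <- paste(long$sample_id, long$chrom, long$pos, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (sample, chrom, pos) row in %s: sample %s, %s:%d",
                 path, long$sample_id[dup[1]], long$chrom[dup[1]], long$pos[dup[1]]))
  out <- lapply(split(long, long$sample_id), function(d) {
    probe_profile(d$sample_id[1], d$chrom, d$pos, d$log2, tissue = d$tissue[1])
  })
  out[unique(long$sample_id)]
}

#' Write three-state call tracks as SEG-format text
#'
#' Consecutive sites of one sample on one chromosome sharing the same state
#' are merged into a single segment. Columns are `sample`, `chrom`,
#' `loc.start`, `loc.end`, `num.mark`, `state` (SEG convention, with the
#' categorical state in place of a segment mean).
#'
#' @param calls A single call track (see [call_states]) or a list of them.
#' @param path Output file path.
#' @export
write_calls_seg <- function(calls, path) {
  if (inherits(calls, "call_track")) calls <- list(calls)
  rows <- lapply(calls, function(ct) {
    do.call(rbind, lapply(split(ct, ct$chrom), function(d) {
      r <- rle(as.character(d$state))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      data.frame(sample = attr(ct, "sample_id"),
                 chrom = d$chrom[1],
                 loc.start = d$pos[starts],
                 loc.end = d$pos[ends],
                 num.mark = r$lengths,
                 state = r$values,
                 stringsAsFactors = FALSE)
    }))
  })
  seg <- do.call(rbind, rows)
  rownames(seg) <- NULL
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(seg)
}

#' Read SEG-format calls back onto a site grid
#'
#' Expands segments written by [write_calls_seg] to per-site states on the
#' reduced site grid `sites` (a data frame with columns `chrom`, `pos`).
#'
#' @param path SEG file written by [write_calls_seg].
#' @param sites Data frame with columns `chrom` and `pos` giving the reduced
#'   site grid the calls were made on.
#' @return A named list of call tracks.
#' @export
read_calls_seg <- function(path, sites) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "loc.start", "loc.end", "state")
  if (!all(need %in% names(seg)))
    stop("SEG file must contain columns: ", paste(need, collapse = ", "))
  lapply(split(seg, seg$sample), function(d) {
    state <- rep(NA_character_, nrow(sites))
    for (i in seq_len(nrow(d))) {
      hit <- sites$chrom == d$chrom[i] &
        sites$pos >= d$loc.start[i] & sites$pos <= d$loc.end[i]
      state[hit] <- d$state[i]
    }
    if (anyNA(state))
      stop("site grid contains positions not covered by SEG segments")
    ct <- data.frame(chrom = sites$chrom, pos = sites$pos,
                     state = factor(state, levels = c("loss", "neutral", "gain")),
                     stringsAsFactors = FALSE)
    structure(ct, sample_id = d$sample[1],
              class = c("call_track", "data.frame"))
  })
}

#' Read a gene annotation table
#'
#' Tab-delimited with header: `gene_symbol`, `chrom`, `start`, `end` and an
#' optional `driver_class` column with values `oncogene`, `TSG` or `other`.
#' Coordinates are 1-based inclusive.
#'
#' @param path Path to the annotation file.
#' @return A data frame with a `driver_class` factor column.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "chrom", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene annotation requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_symbol))
    stop("gene symbols must be unique")
  if (any(g$start > g$end)) stop("gene start must be <= end")
  if (!("driver_class" %in% names(g))) g$driver_class <- "other"
  g$driver_class <- factor(g$driver_class, levels = c("oncogene", "TSG", "other"))
  g$driver_class[is.na(g$driver_class)] <- "other"
  g
}

#' Write selected focal regions as BED4+ text
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so `start_bed = ci_lo - 1` and `end_bed = ci_hi`. Extra columns
#' carry direction, peak height, the confidence bounds (1-based), the
#' asymmetry p-value and the selection flags.
#'
#' @param regions A `focal_regions` data frame from [select_focal_regions].
#' @param path Output file path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$ci_lo - 1L,
                    end = regions$ci_hi,
                    name = sprintf("%s_%s_%d", regions$direction,
                                   regions$chrom, regions$pos),
                    direction = regions$direction,
                    height = regions$height,
                    ci_lo = regions$ci_lo,
                    ci_hi = regions$ci_hi,
                    p_asymmetry = regions$p_asymmetry,
                    flags = paste0("height=", as.integer(regions$flag_height),
                                   ";ci=", as.integer(regions$flag_ci_width),
                                   ";normal=", as.integer(regions$flag_normal),
                                   ";asym=", as.integer(regions$flag_asymmetry),
                                   ";selected=", as.integer(regions$selected)),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
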