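mk_regions <- function(chrom, ci_lo, ci_hi, direction = "gain") {
  data.frame(chrom = chrom, pos = as.integer((ci_lo + ci_hi) / 2),
             direction = direction, ci_lo = as.integer(ci_lo),
             ci_hi = as.integer(ci_hi), stringsAsFactors = FALSE)
}

mk_genes <- function(symbol, chrom, start, end, driver = "other") {
  data.frame(gene_symbol = symbol, chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             driver_class = factor(driver, levels = c("oncogene", "TSG", "other")),
             stringsAsFactors = FALSE)
}

test_that("genes map to regions by >= 1 bp overlap of 1-based intervals", {
  rg <- mk_regions("chr1", 10000, 20000)
  genes <- mk_genes(c("inside", "left_abut", "right_abut", "one_bp", "span"),
                    "chr1",
                    start = c(12000, 8000, 20001, 9000, 5000),
                    end   = c(13000, 9999, 22000, 10000, 30000))
  m <- map_genes_to_regions(rg, genes)
  expect_setequal(m$gene_symbol, c("inside", "one_bp", "span"))

  expect_error(map_genes_to_regions(mk_regions("chrX", 1, 10), genes),
               "chrX")
})

test_that("region-gene mapping agrees with brute-force interval intersection", {
  set.seed(61)
  for (i in 1:10) {
    rg <- mk_regions(sample(c("chr1", "chr2"), 3, replace = TRUE),
                     ci_lo = sample(1:50000, 3), ci_hi = 0)
    rg$ci_hi <- rg$ci_lo + sample(1000:20000, 3)
    genes <- mk_genes(paste0("g", 1:12),
                      sample(c("chr1", "chr2"), 12, replace = TRUE),
                      start = sample(1:60000, 12), end = 0)
    genes$end <- genes$start + sample(100:15000, 12)
    got <- map_genes_to_regions(rg, genes)
    expected <- do.call(rbind, lapply(seq_len(3), function(r) {
      hit <- genes$chrom == rg$chrom[r] & genes$start <= rg$ci_hi[r] &
        genes$end >= rg$ci_lo[r]
      if (any(hit)) data.frame(region = r, gene_symbol = genes$gene_symbol[hit])
    }))
    got_key <- sort(paste(got$region, got$gene_symbol))
    exp_key <- if (is.null(expected)) character(0)
               else sort(paste(expected$region, expected$gene_symbol))
    expect_identical(got_key, exp_key)
  }
})

test_that("driver contingency test reproduces exact-test closed forms", {
  flat <- driver_contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_value, 1)

  diag3 <- driver_contingency_test(matrix(c(3, 0, 0, 3), 2))
  expect_equal(diag3$p_value, 0.1)   # 2 / choose(6, 3)

  # ratio fold undefined when a denominator cell is zero; p still computed
  z <- driver_contingency_test(matrix(c(3, 0, 0, 3), 2))
  expect_true(is.na(z$ratio_fold))
})

test_that("Fisher p agrees with exhaustive enumeration and is swap-invariant", {
  set.seed(62)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    p_pkg <- driver_contingency_test(tab)$p_value
    expect_equal(p_pkg, oracle_fisher_two_sided(tab), tolerance = 1e-10)
    swapped <- tab[2:1, 2:1]
    expect_equal(driver_contingency_test(swapped)$p_value, p_pkg,
                 tolerance = 1e-12)
  }
})

test_that("contingency table building counts distinct driver genes", {
  mapping <- data.frame(
    region = c(1, 1, 1, 2, 2, 3),
    chrom = "chr1",
    direction = c("gain", "gain", "gain", "loss", "loss", "gain"),
    gene_symbol = c("ONC1", "TSG1", "OTH1", "TSG2", "TSG2", "ONC1"),
    driver_class = c("oncogene", "TSG", "other", "TSG", "TSG", "oncogene"),
    stringsAsFactors = FALSE)
  tab <- driver_contingency(mapping)
  # ONC1 appears in two gain regions but counts once; TSG2 duplicated rows
  expect_identical(tab, matrix(c(1L, 0L, 1L, 1L), 2,
                               dimnames = list(c("gain", "loss"),
                                               c("oncogene", "TSG"))))
})

test_that("expression effects have the dosage sign convention", {
  n_samp <- 12
  ids <- sprintf("s%02d", 1:n_samp)
  carrier <- 1:n_samp <= 6
  s_gain <- rep("neutral", 30); s_gain[15] <- "gain"
  s_loss <- rep("neutral", 30); s_loss[15] <- "loss"
  calls_gain <- lapply(1:n_samp, function(i)
    fake_calls(if (carrier[i]) s_gain else rep("neutral", 30), id = ids[i]))
  calls_loss <- lapply(1:n_samp, function(i)
    fake_calls(if (carrier[i]) s_loss else rep("neutral", 30), id = ids[i]))

  expr <- matrix(5, nrow = 2, ncol = n_samp,
                 dimnames = list(c("gA", "gB"), ids))
  expr["gA", carrier] <- 6   # planted 2-fold (1 log2 unit) increase
  genes <- mk_genes(c("gA", "gB"), "chr1", c(14000, 14500), c(16000, 15500))

  rg_gain <- mk_regions("chr1", 14000, 16000, "gain")
  eff_gain <- expression_effect_size(expr, calls_gain, rg_gain, genes)
  expect_equal(eff_gain$effect[eff_gain$gene_symbol == "gA"], 1.0)
  expect_equal(eff_gain$effect[eff_gain$gene_symbol == "gB"], 0.0)

  # the same expression pattern interpreted as a loss region flips sign
  rg_loss <- mk_regions("chr1", 14000, 16000, "loss")
  eff_loss <- expression_effect_size(expr, calls_loss, rg_loss, genes)
  expect_equal(eff_loss$effect[eff_loss$gene_symbol == "gA"], -1.0)
})

test_that("driver-effect comparison is calibrated under the null and symmetric", {
  set.seed(63)
  p_null <- replicate(20, {
    eff <- rnorm(60, 0.4, 0.3)
    compare_driver_effects(eff, seq_along(eff) <= 15)
  })
  expect_gt(median(p_null), 0.2)
  expect_lt(median(p_null), 0.8)

  # a planted shift like the driver/non-driver effect gap is detectable
  set.seed(64)
  p_shift <- replicate(10, {
    eff <- c(rnorm(50, 0.54, 0.3), rnorm(500, 0.39, 0.3))
    compare_driver_effects(eff, seq_along(eff) <= 50)
  })
  expect_lt(median(p_shift), 0.05)

  eff <- rnorm(40)
  drv <- seq_along(eff) <= 10
  expect_equal(compare_driver_effects(eff, drv),
               compare_driver_effects(eff, !drv))
  expect_error(compare_driver_effects(rnorm(5), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               ">= 3")
})
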