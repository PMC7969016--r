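test_that("cleavage ratio is reads starting at i+1 over depth at i+1", {
  starts <- c(0L, 5L, 0L, 0L)
  depth <- c(20L, 10L, 40L, 0L)
  r <- cleavage_ratio_profile(starts, depth)
  expect_length(r, 3)          # position L has no ratio
  expect_equal(r[[1]], 0.5)
  expect_equal(r[[2]], 0.0)
  expect_true(is.na(r[[3]]))   # zero depth: undefined, not an error
})

test_that("pooled t-test matches the reference implementation", {
  set.seed(42)
  for (k in 1:100) {
    a <- round(runif(sample(2:5, 1)), 3)
    b <- round(runif(sample(2:5, 1)), 3)
    if (isTRUE(all.equal(var(a) + var(b), 0))) next
    ref <- t.test(a, b, var.equal = TRUE)$p.value
    expect_equal(ttest_unpaired(a, b), ref, tolerance = 1e-9)
  }
})

test_that("t-test degenerate rules keep two-replicate contrasts decisive", {
  expect_equal(ttest_unpaired(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(ttest_unpaired(c(0.8, 0.8), c(0.1, 0.1)), 0)
  expect_true(is.na(ttest_unpaired(0.8, c(0.1, 0.2))))       # untestable
  expect_true(is.na(ttest_unpaired(c(0.8, NA), c(0.1, 0.2))))
  # textbook pooled t with 2 df
  a <- c(0.8, 0.9); b <- c(0.1, 0.2)
  sp2 <- (var(a) + var(b)) / 2
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(ttest_unpaired(a, b), 2 * pt(-abs(tstat), 2), tolerance = 1e-12)
})

test_that("band intensity ratio is cleaved over total signal", {
  expect_equal(band_cleavage_ratio(1, 1), 0.5)
  expect_equal(band_cleavage_ratio(0, 7), 0)
  expect_equal(band_cleavage_ratio(3, 1), 0.75)
  expect_error(band_cleavage_ratio(0, 0), "no signal")
})

test_that("the three criteria decide sites as specified", {
  ts <- single_tx_set(L = 60L, site = 30L)
  z <- function(a, b) c(a, b)

  # strong site: passes every criterion by a large margin
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = z(0.02, 0.03), HAC = z(0.80, 0.82), `DM-HAC` = z(0.02, 0.04)))
  calls <- call_sites(nest, calling_config(), ts)
  row <- calls[calls$position == 30, ]
  expect_true(row$called && row$c1 && row$c2 && row$c3)
  expect_equal(row$mean_hac, 0.81, tolerance = 0.01)

  # sub-cutoff ratio: criterion (i) fails alone
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = z(0.02, 0.03), HAC = z(0.34, 0.36), `DM-HAC` = z(0.02, 0.04)))
  row <- call_sites(nest, calling_config(), ts)
  row <- row[row$position == 30, ]
  expect_false(row$called)
  expect_false(row$c1)
  expect_true(row$c2 && row$c3)

  # demethylase-resistant site: criterion (iii) fails alone
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = z(0.02, 0.03), HAC = z(0.80, 0.82), `DM-HAC` = z(0.75, 0.78)))
  row <- call_sites(nest, calling_config(), ts)
  row <- row[row$position == 30, ]
  expect_false(row$called)
  expect_false(row$c3)
  expect_true(row$c1 && row$c2)
})

test_that("zero-denominator folds pass only with positive HAC signal", {
  ts <- single_tx_set(L = 60L, site = 30L)
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = c(0, 0), HAC = c(0.7, 0.75), `DM-HAC` = c(0, 0)))
  row <- call_sites(nest, calling_config(), ts)
  row <- row[row$position == 30, ]
  expect_true(row$called)      # ideal positive: absent from both controls
  expect_true(is.infinite(row$fold_increase))

  # flat zero everywhere stays uncalled
  nest0 <- profiles_from_ratios(60L, 30L, list(
    Ctrl = c(0, 0), HAC = c(0, 0), `DM-HAC` = c(0, 0)))
  row0 <- call_sites(nest0, calling_config(), ts)
  expect_false(any(row0$called))
})

test_that("group structure is validated", {
  ts <- single_tx_set()
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = c(0, 0), HAC = c(0.7, 0.75), `DM-HAC` = c(0, 0)))
  expect_error(call_sites(nest[c("Ctrl", "HAC")], calling_config(), ts),
               "missing group")
  uneq <- nest
  uneq$Ctrl <- uneq$Ctrl[1]
  expect_error(call_sites(uneq, calling_config(), ts), "unequal replicate")
  single <- lapply(nest, `[`, 1)
  expect_error(call_sites(single, calling_config(), ts), "2 replicates")
})

test_that("low-depth positions are reported as untestable, never called", {
  ts <- single_tx_set(L = 60L, site = 30L)
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = c(0.02, 0.03), HAC = c(0.8, 0.82), `DM-HAC` = c(0.02, 0.04)),
    depth = 10L)
  calls <- call_sites(nest, calling_config(min_depth = 20), ts)
  expect_true(all(calls$status == "low_depth"))
  expect_false(any(calls$called))
  expect_true(all(is.na(calls$c1)))
  expect_equal(nrow(calls), 59)  # every position reported
})

test_that("calling is invariant to replicate order", {
  ts <- single_tx_set(L = 60L, site = 30L)
  nest <- profiles_from_ratios(60L, 30L, list(
    Ctrl = c(0.05, 0.01), HAC = c(0.9, 0.7), `DM-HAC` = c(0.02, 0.08)))
  flipped <- lapply(nest, rev)
  a <- call_sites(nest, calling_config(), ts)
  b <- call_sites(flipped, calling_config(), ts)
  keep <- c("mean_ctrl", "mean_hac", "mean_dmhac", "p_inc", "p_dec",
            "c1", "c2", "c3", "called")
  expect_equal(a[keep], b[keep])
})

test_that("BH adjustment and base filtering only remove calls", {
  ts <- synthetic_trna_set()
  sim <- simulate_experiment(ts, synthetic_m3c_truth(),
                             sim_config(molecules = 150, seed = 12))
  nest <- lapply(split(names(sim$reads), sub("\\..*", "", names(sim$reads))),
                 function(k) lapply(sim$reads[k], count_reads, ts = ts))
  raw <- call_sites(nest, calling_config(), ts)
  bh <- call_sites(nest, calling_config(p_adjust = "BH"), ts)
  expect_true(all(which(bh$called) %in% which(raw$called)))
  cf <- call_sites(nest, calling_config(base_filter = TRUE), ts)
  expect_true(all(cf$ref_base[cf$called] == "C"))
  expect_true(all(which(cf$called) %in% which(raw$called)))
})
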