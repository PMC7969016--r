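test_that("without fragmentation, full penetrance cleavage is exact", {
  ts <- single_tx_set(L = 80L, site = 40L)
  truth <- modification_truth("tx1", 40L, stoichiometry = 1)
  cfg <- sim_config(replicates = 1, molecules = 200, lambda = 0, cleavage = 1,
                    seed = 5)
  sim <- simulate_experiment(ts, truth, cfg)

  ctrl <- sim$reads[["Ctrl.1"]]
  expect_equal(nrow(ctrl), 200)
  expect_true(all(ctrl$start == 1L & ctrl$end == 80L))

  hac <- sim$reads[["HAC.1"]]
  expect_true(all(hac$start == 41L & hac$end == 80L))
  cov <- count_reads(hac, ts)
  ratio <- cleavage_ratio_profile(cov$tx1)
  expect_identical(ratio[[40]], 1.0)
})

test_that("cleavage ratio concentrates on s*c within binomial error", {
  ts <- single_tx_set(L = 80L, site = 40L)
  N <- 3000
  for (s in c(0.3, 0.8)) for (cl in c(0.5, 1)) {
    truth <- modification_truth("tx1", 40L, stoichiometry = s)
    cfg <- sim_config(replicates = 1, molecules = N, lambda = 0,
                      cleavage = cl, seed = 99)
    sim <- simulate_experiment(ts, truth, cfg)
    cov <- count_reads(sim$reads[["HAC.1"]], ts)
    r <- cleavage_ratio_profile(cov$tx1)[[40]]
    expect_lt(abs(r - s * cl), 3 * sqrt(s * cl * (1 - s * cl) / N))
  }
})

test_that("unmodified and fully demethylated molecules behave like controls", {
  ts <- single_tx_set(L = 80L, site = 40L)
  # s = 0: no molecule carries a mark, HAC reads are indistinguishable from Ctrl
  sim0 <- simulate_experiment(ts, modification_truth("tx1", 40L, 0),
                              sim_config(replicates = 1, molecules = 500,
                                         lambda = 0.01, seed = 3))
  p_hac <- count_reads(sim0$reads[["HAC.1"]], ts)$tx1
  expect_lt(cleavage_ratio_profile(p_hac)[[40]], 0.05)

  # d = 1: DM-HAC profile has no cleavage signature at the site
  sim1 <- simulate_experiment(ts, modification_truth("tx1", 40L, 0.9,
                                                     demethylation = 1),
                              sim_config(replicates = 1, molecules = 500,
                                         lambda = 0.01, seed = 3))
  p_dm <- count_reads(sim1$reads[["DM-HAC.1"]], ts)$tx1
  p_h <- count_reads(sim1$reads[["HAC.1"]], ts)$tx1
  expect_lt(cleavage_ratio_profile(p_dm)[[40]], 0.05)
  expect_gt(cleavage_ratio_profile(p_h)[[40]], 0.7)
})

test_that("emitted reads respect transcript bounds and the size window", {
  set.seed(21)
  ts <- random_transcript_set(4, min_len = 60, max_len = 150)
  lens <- transcript_lengths(ts)
  # plant a site on some C of the first transcript
  cpos <- gregexpr("C", ts$sequences[[1]])[[1]]
  truth <- modification_truth(transcript_ids(ts)[1], cpos[length(cpos) %/% 2],
                              stoichiometry = 0.6)
  cfg <- sim_config(replicates = 2, molecules = 300, lambda = 0.02,
                    frag_min = 10, frag_max = 120, seed = 77)
  sim <- simulate_experiment(ts, truth, cfg)
  expect_named(sim$reads, c("Ctrl.1", "Ctrl.2", "HAC.1", "HAC.2",
                            "DM-HAC.1", "DM-HAC.2"))
  for (df in sim$reads) {
    expect_true(all(df$start >= 1L))
    expect_true(all(df$end <= lens[df$transcript_id]))
    len <- df$end - df$start + 1L
    expect_true(all(len >= 10L & len <= 120L))
  }
})

test_that("Ctrl-arm fragments partition the molecule before size selection", {
  # with the size window wide open and no cleavage arm effects, every
  # molecule's fragment lengths must sum to L
  ts <- single_tx_set(L = 50L, site = 25L)
  cfg <- sim_config(replicates = 1, molecules = 200, lambda = 0.08,
                    frag_min = 1, frag_max = 50, seed = 13)
  sim <- simulate_experiment(ts, modification_truth("tx1", 25L, 0), cfg)
  ctrl <- sim$reads[["Ctrl.1"]]
  expect_equal(nrow(ctrl) >= 200, TRUE)  # fragmentation only adds reads
  expect_equal(sum(ctrl$end - ctrl$start + 1L), 200L * 50L)
})

test_that("simulation is deterministic given the seed", {
  ts <- synthetic_trna_set()
  truth <- synthetic_m3c_truth()
  cfg <- sim_config(molecules = 100, seed = 31)
  s1 <- simulate_experiment(ts, truth, cfg)
  s2 <- simulate_experiment(ts, truth, cfg)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_experiment(ts, truth, sim_config(molecules = 100, seed = 32))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("truth validation rejects bad sites", {
  ts <- single_tx_set(L = 40L, site = 20L)
  cfg <- sim_config(molecules = 10, seed = 1)
  expect_error(simulate_experiment(ts, modification_truth("nope", 5, 1), cfg),
               "unknown transcript")
  expect_error(simulate_experiment(ts, modification_truth("tx1", 99, 1), cfg),
               "outside")
  # default requires a C at the planted position; overridable
  expect_error(simulate_experiment(ts, modification_truth("tx1", 5, 1), cfg),
               "expected C")
  expect_silent(simulate_experiment(ts, modification_truth("tx1", 5, 1), cfg,
                                    require_c = FALSE))
  expect_error(modification_truth("tx1", 20, 1.2), "\\[0,1\\]")
})

test_that("residual RT stops truncate reads at surviving marks", {
  ts <- single_tx_set(L = 80L, site = 40L)
  truth <- modification_truth("tx1", 40L, stoichiometry = 1)
  cfg <- sim_config(replicates = 1, molecules = 400, lambda = 0, cleavage = 0,
                    rt_stop = 1, seed = 8)
  sim <- simulate_experiment(ts, truth, cfg)
  # cleavage never fires, but every surviving mark hard-stops RT in all arms
  expect_true(all(sim$reads[["Ctrl.1"]]$start == 41L))
  expect_true(all(sim$reads[["HAC.1"]]$start == 41L))
})
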