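test_that("identical configurations give byte-identical output", {
  man <- make_manifest(30, 5, 10)
  cfg <- sim_config(seed = 9, coverage = 200)
  s1 <- simulate_screen(man, cfg)
  s2 <- simulate_screen(man, cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_screen(man, sim_config(seed = 10, coverage = 200))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("a neutral screen is symmetric between bins", {
  man <- make_manifest(200, 5, 20)
  sim <- simulate_screen(man, sim_config(seed = 21))
  norm <- normalize_counts(sim$counts)
  sg <- sgrna_log2fc(norm, sim$sheet, "sim", "facs", man)
  expect_lt(abs(mean(sg$log2fc)), 0.02)
  expect_gt(mean(sg$log2fc > 0), 0.4)
  expect_lt(mean(sg$log2fc > 0), 0.6)
})

test_that("a fully blocked gene depletes from the responder bin, in both modes", {
  man <- make_manifest(20, 5, 10)
  blocked <- sprintf("g%04d", 1)
  for (mode in c("aggregate", "percell")) {
    for (seed in c(31, 32, 33)) {
      cfg <- sim_config(seed = seed, effects = setNames(0, blocked),
                        kd_range = c(1, 1))
      sim <- simulate_screen(man, cfg, mode = mode)
      cm <- sim$counts$counts
      sg_rows <- which(man$gene == blocked)
      expect_true(all(cm[sg_rows, "facs_high"] < cm[sg_rows, "facs_low"]),
                  label = sprintf("mode %s seed %d", mode, seed))
      expect_equal(sim$truth$sgrnas$responder_prob[sg_rows], rep(0, 5))
    }
  }
})

test_that("aggregate and per-cell modes agree on bin shares", {
  man <- make_manifest(20, 5, 10)
  cfg <- sim_config(seed = 41, coverage = 2000,
                    effects = setNames(0.2, "g0001"), kd_range = c(1, 1))
  agg <- simulate_screen(man, cfg, mode = "aggregate")
  pc <- simulate_screen(man, cfg, mode = "percell")
  f_agg <- agg$counts$counts[, "facs_high"] / sum(agg$counts$counts[, "facs_high"])
  f_pc <- pc$counts$counts[, "facs_high"] / sum(pc$counts$counts[, "facs_high"])
  # both modes see the same overall responder fraction and gate cuts
  expect_equal(agg$provenance$responder_fraction,
               pc$provenance$responder_fraction, tolerance = 0.02)
  expect_equal(agg$provenance$hi_cut, pc$provenance$hi_cut, tolerance = 0.05)
  # the affected gene is depleted from the responder bin to the same degree
  hit <- man$gene == "g0001"
  dep_agg <- mean(f_agg[hit]) / mean(f_agg[!hit])
  dep_pc <- mean(f_pc[hit]) / mean(f_pc[!hit])
  expect_lt(dep_agg, 0.8)
  expect_lt(dep_pc, 0.8)
  expect_lt(abs(log(dep_agg / dep_pc)), 0.3)
})

test_that("expected responder-bin share rises monotonically with the odds multiplier", {
  man <- make_manifest(5, 5, 5)
  grid <- c(0.05, 0.2, 1, 5, 20)
  shares <- vapply(grid, function(mult) {
    cfg <- sim_config(seed = 51, coverage = 20000,
                      effects = setNames(mult, "g0001"), kd_range = c(1, 1))
    sim <- simulate_screen(man, cfg)
    cm <- sim$counts$counts
    hit <- man$gene == "g0001"
    sum(cm[hit, "facs_high"]) / sum(cm[hit, c("facs_high", "facs_low")])
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("dropout-arm abundance follows fitness^doublings", {
  man <- make_manifest(100, 5, 20)
  cfg <- sim_config(seed = 61, fitness = setNames(0.5, "g0001"),
                    reads_per_sample = 5e6)
  sim <- simulate_screen(man, cfg)
  norm <- normalize_counts(sim$counts)
  ratio <- norm$freq[, "endpoint"] / norm$freq[, "day0"]
  hit <- man$gene == "g0001"
  observed <- mean(ratio[hit]) / mean(ratio[!hit])
  expect_lt(abs(log(observed / 0.5^6)), 0.3)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(gate_quantile = 0.6), "gate_quantile")
  expect_error(sim_config(moi = 0.01), "moi")
  expect_error(sim_config(doublings = 2), "doublings")
  man <- make_manifest(5, 5, 0)
  expect_warning(simulate_screen(man, sim_config(seed = 1, reads_per_sample = 10)),
                 "coverage")
})

test_that("flow-event simulation produces the stated mixture", {
  ev0 <- simulate_flow_events(2000, 0, seed = 71)
  expect_false(any(ev0$truth_responder))
  ev1 <- simulate_flow_events(2000, 1, seed = 71)
  expect_gt(median(ev1$red / ev1$green), median(ev0$red / ev0$green))
  ev <- simulate_flow_events(10000, 0.3, seed = 72)
  expect_equal(nrow(ev), 10000)
  expect_true(all(ev$green > 0))
})

test_that("trace simulation and dose-response generation match their closed forms", {
  tr <- simulate_traces(3, peak_dff = 2, noise_sd = 0, seed = 81)
  pk <- dff_traces(tr)
  expect_equal(pk$peaks$peak_dff, rep(2, 3))

  flat <- simulate_traces(50, peak_dff = 0, noise_sd = 0.05, seed = 82)
  pk0 <- dff_traces(flat)
  expect_true(all(abs(pk0$peaks$peak_dff) < 3 * 0.05))

  # midpoint and asymptote identities of the 4PL
  d <- simulate_dose_response(c(0.01, 0.1, 1, 1e6), bottom = 0.5, top = 2.5,
                              ec50 = 1, hill = 1.3, noise_sd = 0, seed = 83)
  expect_equal(d$response[d$dose == 1], (2.5 + 0.5) / 2)
  expect_equal(d$response[d$dose == 1e6], 2.5, tolerance = 1e-6)
})
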