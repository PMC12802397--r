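test_that("tail gating cuts floor(q*n) events and keeps ties together", {
  ev10 <- data.frame(green = rep(1, 10), red = 1:10)
  g <- gate_tails(ev10, q = 0.35)
  expect_equal(sort(g$low$red), 1:3)
  expect_equal(sort(g$high$red), 8:10)

  set.seed(3)
  evbig <- data.frame(green = rep(1, 10000), red = sample(1e7, 10000))
  gb <- gate_tails(evbig, q = 0.35)
  expect_equal(nrow(gb$high), 3500)
  expect_equal(nrow(gb$low), 3500)

  tied <- data.frame(green = rep(1, 20), red = rep(2, 20))
  expect_warning(gt <- gate_tails(tied, q = 0.35), "no separable tails")
  expect_equal(nrow(gt$high), 0)
  expect_equal(nrow(gt$low), 0)

  expect_error(gate_tails(ev10, q = 0.6), "0, 0.5")

  # bins disjoint and ordered on random data
  set.seed(4)
  ev <- data.frame(green = runif(500, 0.5, 2), red = runif(500, 0, 5))
  gr <- gate_tails(ev, q = 0.2)
  rh <- gr$high$red / gr$high$green
  rl <- gr$low$red / gr$low$green
  expect_equal(nrow(gr$high) + nrow(gr$low), 200)
  expect_gt(min(rh), max(rl))
})

test_that("integrated calcium activity is median-based, reference-anchored and scale-free", {
  ev <- rbind(
    data.frame(sample_id = "ntc_1", condition = "NTC", green = 1, red = c(1, 2, 100)),
    data.frame(sample_id = "ntc_2", condition = "NTC", green = 1, red = c(2, 2, 2)),
    data.frame(sample_id = "kd_1", condition = "KD", green = 1, red = c(8, 9, 10)),
    data.frame(sample_id = "kd_2", condition = "KD", green = 1, red = c(9, 9, 9)))
  act <- integrated_activity(ev, "NTC")
  expect_equal(act$samples$median_ratio[act$samples$sample_id == "ntc_1"], 2)
  expect_equal(act$conditions$relative[act$conditions$condition == "NTC"], 1)
  expect_equal(act$conditions$relative[act$conditions$condition == "KD"],
               mean(c(9, 9)) / mean(c(2, 2)))
  scaled <- ev; scaled$red <- scaled$red * 37; scaled$green <- scaled$green * 37
  act2 <- integrated_activity(scaled, "NTC")
  expect_equal(act2$conditions$relative, act$conditions$relative)

  withbad <- rbind(ev, data.frame(sample_id = "ntc_1", condition = "NTC",
                                  green = 0, red = 5))
  act3 <- integrated_activity(withbad, "NTC")
  expect_equal(act3$samples$n_dropped[act3$samples$sample_id == "ntc_1"], 1)
  allbad <- data.frame(sample_id = "x", condition = "NTC", green = 0, red = 1)
  expect_error(integrated_activity(rbind(ev, allbad), "NTC"), "x")
})

test_that("dF/F0 arithmetic and exclusions are exact", {
  mk <- function(F_by_cell) {
    frames <- seq_along(F_by_cell[[1]])
    list(traces = data.frame(
           cell_id = rep(names(F_by_cell), each = length(frames)),
           frame = rep(frames, length(F_by_cell)),
           F = unlist(F_by_cell, use.names = FALSE)),
         stim_frame = 11L, baseline_window = c(1L, 10L))
  }
  flat <- rep(100, 30)
  stepped <- c(rep(100, 10), rep(300, 10), rep(150, 10))
  neg <- rep(-5, 30)
  res <- dff_traces(mk(list(c1 = flat, c2 = stepped, c3 = neg)))
  expect_equal(res$peaks$peak_dff[res$peaks$cell_id == "c1"], 0)
  expect_equal(res$peaks$peak_dff[res$peaks$cell_id == "c2"], 2)
  expect_equal(res$excluded$cell_id, "c3")
  expect_false("c3" %in% res$peaks$cell_id)
})

test_that("normalized responses and percent change follow their definitions", {
  a <- data.frame(cell_id = c("c1", "c2", "c3"), peak_dff = c(1.5, 0.4, 2))
  b <- data.frame(cell_id = c("c1", "c2", "c3"), peak_dff = c(1.5, 0.8, 0))
  nr <- normalized_response(a, b)
  expect_equal(nr$normalized[nr$cell_id == "c1"], 1)
  expect_equal(nr$normalized[nr$cell_id == "c2"], 0.5)
  expect_false("c3" %in% nr$cell_id)    # reference peak <= 0 excluded
  expect_equal(percent_change(0.8, 0.2), -75)
})

test_that("4PL fitting is an exact fixed point on noiseless data", {
  doses <- 10^seq(-2, 2, length.out = 9)
  truth <- list(bottom = 0.3, top = 2.8, ec50 = 0.7, hill = 1.4)
  d <- simulate_dose_response(doses, truth$bottom, truth$top, truth$ec50,
                              truth$hill, noise_sd = 0, seed = 1)
  f <- fit_4pl(d$dose, d$response)
  expect_true(f$converged)
  expect_lt(abs(f$bottom - truth$bottom), 1e-6 * truth$bottom + 1e-8)
  expect_lt(abs(f$top / truth$top - 1), 1e-6)
  expect_lt(abs(f$ec50 / truth$ec50 - 1), 1e-6)
  expect_lt(abs(f$hill / truth$hill - 1), 1e-6)
  # midpoint identity
  expect_equal(f$fitted(f$ec50), (f$top + f$bottom) / 2, tolerance = 1e-8)
  # inverted data is flagged, not hidden
  inv <- simulate_dose_response(doses, bottom = 0.2, top = 2, ec50 = 1,
                                hill = -1.2, noise_sd = 0, seed = 2)
  fi <- fit_4pl(inv$dose, inv$response)
  expect_true(fi$negative_hill)
  expect_error(fit_4pl(c(1, 2, 3), c(1, 2, 3)), "4 distinct doses")
})

test_that("ddCt arithmetic equals its closed form", {
  ct <- rbind(
    data.frame(condition = "ctl", gene = "Tgt", ct = c(20, 20, 20)),
    data.frame(condition = "ctl", gene = "Gapdh", ct = c(15, 15, 15)),
    data.frame(condition = "kd", gene = "Tgt", ct = c(22, 22, 22)),
    data.frame(condition = "kd", gene = "Gapdh", ct = c(15, 15, 15)))
  res <- ddct_knockdown(ct, target = "Tgt", control = "ctl")
  kd <- res[res$condition == "kd", ]
  expect_equal(kd$ddct, 2)
  expect_equal(kd$relative_expression, 0.25)
  expect_equal(kd$knockdown_pct, 75)
  ctl <- res[res$condition == "ctl", ]
  expect_equal(ctl$relative_expression, 1)
  expect_equal(ctl$knockdown_pct, 0)

  # closed form 2^-ddct for arbitrary inputs
  set.seed(9)
  ct2 <- data.frame(condition = rep(c("ctl", "x"), each = 2),
                    gene = rep(c("Tgt", "Gapdh"), 2),
                    ct = runif(4, 14, 30))
  r2 <- ddct_knockdown(ct2, "Tgt", control = "ctl")
  dct <- with(ct2, ct[3] - ct[4] - (ct[1] - ct[2]))
  expect_equal(r2$relative_expression[r2$condition == "x"], 2^(-dct))

  noisy <- rbind(ct, data.frame(condition = "kd", gene = "Tgt", ct = 24))
  expect_true(ddct_knockdown(noisy, "Tgt", control = "ctl")$flag_high_sd[
    ddct_knockdown(noisy, "Tgt", control = "ctl")$condition == "kd"])
  expect_error(ddct_knockdown(ct, "Tgt", reference = "Actb", control = "ctl"),
               "Actb")
})

test_that("relative secretion folds are reference-anchored and homogeneous", {
  wells <- data.frame(condition = rep(c("basal", "tryptone"), each = 3),
                      value = c(10, 10, 10, 70, 70, 70))
  rs <- relative_secretion(wells, "basal")
  expect_equal(rs$conditions$mean_fold[rs$conditions$condition == "basal"], 1)
  expect_equal(rs$conditions$mean_fold[rs$conditions$condition == "tryptone"], 7)
  scaled <- wells; scaled$value <- scaled$value * 0.123
  rs2 <- relative_secretion(scaled, "basal")
  expect_equal(rs2$conditions$mean_fold, rs$conditions$mean_fold)
  zero <- data.frame(condition = "basal", value = 0)
  expect_error(relative_secretion(zero, "basal"), "positive")
})
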