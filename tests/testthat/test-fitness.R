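# Relative-fitness estimation, the start-frequency filter, effect
# aggregation, bias diagnostics and copy-number math.

test_that("relative fitness matches direct evaluation of the formula", {
  # neutral: both competitors stay at 0.5 -> W = 1
  r <- record_from_props(0.5, 0.5)
  expect_equal(relative_fitness(r)$W, 1)

  # test rises 0.5 -> 0.6: W = ln(120)/ln(80)
  r <- record_from_props(0.5, 0.6)
  expect_equal(relative_fitness(r)$W, log(120) / log(80), tolerance = 1e-12)
  expect_equal(relative_fitness(r)$W, 1.09253, tolerance = 1e-5)

  # symmetric decline 0.5 -> 0.4: W = ln(80)/ln(120)
  r <- record_from_props(0.5, 0.4)
  expect_equal(relative_fitness(r)$W, log(80) / log(120), tolerance = 1e-12)
  expect_equal(relative_fitness(r)$W, 0.91530, tolerance = 1e-5)

  # oracle helper agrees across a sweep of proportions
  for (p1 in c(0.2, 0.45, 0.5, 0.7, 0.9)) {
    r <- record_from_props(0.5, p1, n = 10000)
    expect_equal(relative_fitness(r)$W, w_oracle(0.5, p1),
                 tolerance = 1e-9, info = paste("p1 =", p1))
  }
})

test_that("W is invariant to total event count and swaps to 1/W", {
  r1 <- record_from_props(0.5, 0.6, n = 1000)
  r7 <- record_from_props(0.5, 0.6, n = 7000)
  expect_equal(relative_fitness(r1)$W, relative_fitness(r7)$W,
               tolerance = 1e-12)

  # swapping test/reference labels at the symmetric inputs maps W -> 1/W
  swapped <- r1
  swapped[, c("test_day0", "ref_day0", "test_day1", "ref_day1")] <-
    r1[, c("ref_day0", "test_day0", "ref_day1", "test_day1")]
  expect_equal(relative_fitness(swapped)$W, 1 / relative_fitness(r1)$W,
               tolerance = 1e-12)
})

test_that("degenerate proportions are flagged, not pseudocounted", {
  r <- record_from_props(0.5, 1.0)   # test fixed at day 1
  w <- relative_fitness(r)
  expect_false(w$W_ok)
  expect_true(is.na(w$W))
  expect_match(w$W_note, "0 or 1")
})

test_that("start-frequency filter keeps [0.35, 0.65] inclusively", {
  recs <- do.call(rbind, lapply(c(0.30, 0.35, 0.50, 0.65, 0.66),
                                function(p) record_from_props(p, 0.5)))
  recs <- as_competition_records(recs)
  flt <- filter_start_frequency(recs)
  p0 <- recs$test_day0 / (recs$test_day0 + recs$ref_day0)
  expect_equal(flt$reasons == "ok", abs(p0 - 0.5) <= 0.15 + 1e-12)
  expect_equal(nrow(flt$retained), 3)
  expect_equal(nrow(flt$removed), 2)
  expect_match(flt$reasons[1], "0.300")

  expect_error(filter_start_frequency(recs, tolerance = 0), "tolerance")
  expect_error(filter_start_frequency(recs, tolerance = 0.5), "tolerance")

  # relative mode: 15% of 0.5 = 0.075 absolute
  flt_rel <- filter_start_frequency(recs, tolerance = 0.15, relative = TRUE)
  expect_equal(sum(flt_rel$reasons == "ok"), 1)
})

test_that("filter agrees with a brute-force row-by-row recount", {
  cfg <- synth_config(n_strains = 4, n_args = 3, replicates = 40, seed = 77)
  recs <- gen_competitions(gen_effect_matrix(cfg)$truth, cfg)
  flt <- filter_start_frequency(recs)
  recount <- sum(vapply(seq_len(nrow(recs)), function(i) {
    p <- recs$test_day0[i] / (recs$test_day0[i] + recs$ref_day0[i])
    abs(p - 0.5) <= 0.15 + 1e-12
  }, logical(1)))
  expect_equal(nrow(flt$retained), recount)
  expect_gt(nrow(flt$removed), 0)
})

test_that("arg_effect returns ratio, difference and pairing errors", {
  eq <- arg_effect(c(0.98, 1.0, 1.02), c(0.98, 1.0, 1.02))
  expect_equal(eq$effect_ratio, 1)
  expect_equal(eq$effect_diff, 0)

  e <- arg_effect(rep(1.05, 5), rep(1.00, 5))
  expect_equal(e$effect_ratio, 1.05)
  expect_equal(e$effect_diff, 0.05)

  e2 <- arg_effect(rep(0.973, 4), rep(1.0, 4))
  expect_equal(e2$cost_pct, 2.7, tolerance = 1e-9)

  wa <- structure(c(1, 1), strain = "S1")
  wv <- structure(c(1, 1), strain = "S2")
  expect_error(arg_effect(wa, wv), "pairing error")
  expect_error(arg_effect(numeric(0), c(1)), "nonempty")
})

test_that("aggregation gives t-based intervals and flags n = 1 cells", {
  w <- c(0.96, 0.98, 1.00, 1.02, 1.04)
  fitness <- relative_fitness(as_competition_records(rbind(
    do.call(rbind, lapply(seq_along(w), function(i) {
      record_from_props(0.5, 0.5, arg = "ARG1", block = paste0("B", i))
    })),
    record_from_props(0.5, 0.5, arg = "VECTOR")
  )))
  # override W to the hand-constructed replicate values (vector W = 1)
  fitness$W <- c(w, 1)
  eff <- aggregate_effects(fitness)
  row <- eff[eff$arg_id == "ARG1", ]
  expect_equal(row$effect_ratio, 1.00)
  hand_halfwidth <- qt(0.975, 4) * sd(w) / sqrt(5)
  expect_equal(hand_halfwidth, 0.0393, tolerance = 1e-3)
  expect_equal(row$ci_high - row$effect_ratio, hand_halfwidth,
               tolerance = 1e-9)

  # identical values -> zero-width interval
  fitness$W <- c(rep(1.01, 5), 1)
  eff <- aggregate_effects(fitness)
  row <- eff[eff$arg_id == "ARG1", ]
  expect_equal(row$ci_low, row$ci_high)

  # single replicate -> CI flagged absent, mean still present
  one <- relative_fitness(as_competition_records(rbind(
    record_from_props(0.5, 0.52, arg = "ARG9"),
    record_from_props(0.5, 0.5, arg = "VECTOR"),
    record_from_props(0.5, 0.5, arg = "VECTOR", block = "B2")
  )))
  eff1 <- aggregate_effects(one)
  r9 <- eff1[eff1$arg_id == "ARG9", ]
  expect_equal(r9$n, 1)
  expect_false(is.na(r9$effect_ratio))
  expect_true(is.na(r9$ci_low) && is.na(r9$ci_high))
  expect_match(r9$note, "single replicate")
})

test_that("plasmid-loss inflation follows the closed form", {
  expect_equal(plasmid_loss_inflation(0, 100), 0)
  expect_equal(plasmid_loss_inflation(0.004, 100),
               log(1.004) / log(100), tolerance = 1e-12)
  expect_lt(plasmid_loss_inflation(0.004, 100), 0.001)
  expect_equal(plasmid_loss_inflation(0.01, 100), 2.161e-3,
               tolerance = 1e-3)
  expect_error(plasmid_loss_inflation(-0.1), "f_loss")
})

test_that("mutant trajectory equals the iterated per-generation map", {
  expect_equal(mutant_trajectory(0.3, 0, c(0, 5, 50)), rep(0.3, 3))

  # discrete selection with per-generation growth factor e^s composes
  # exactly to the closed form
  discrete <- function(p0, s, t) {
    p <- p0
    for (i in seq_len(t)) p <- p * exp(s) / (1 - p + p * exp(s))
    p
  }
  expect_equal(mutant_trajectory(0.01, 0.15, 10), discrete(0.01, 0.15, 10),
               tolerance = 1e-12)
  expect_equal(mutant_trajectory(0.01, 0.15, 10), 0.04331, tolerance = 1e-4)

  # a strongly beneficial contaminant from ~10 cells stays ~1e-4 over a
  # whole assay (outgrowth + acclimation + competition, ~60 generations)
  p60 <- mutant_trajectory(1.2e-8, 0.15, 60)
  expect_gt(p60, 0.9e-4)
  expect_lt(p60, 1.1e-4)

  # monotone in t for s > 0
  traj <- mutant_trajectory(0.01, 0.15, 0:60)
  expect_true(all(diff(traj) > 0))
  expect_error(mutant_trajectory(0, 0.1, 1), "p0")
})

test_that("copy number normalizes to the reference strain", {
  m <- data.frame(strain_id = c("REL606", "X"),
                  ct_plasmid = c(20, 19), ct_chromosome = c(20, 21))
  cn <- copy_number(m, "REL606")
  expect_equal(cn$delta_ct_ratio, c(1, 4))
  expect_equal(cn$ddct, c(1, 4))
  expect_error(copy_number(m, "missing"), "reference strain")
})
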