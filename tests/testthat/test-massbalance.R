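test_that("SRT matches hand-computed values on the example plant", {
  p <- paper_plant()
  # equal proportions cancel: theta = M / (J_ES + J_EF)
  expect_equal(compute_srt(0.01, 0.01, 0.01, p), 55972 / 3433,
               tolerance = 1e-12)
  expect_equal(compute_srt(0.05, 0.02, 0.001, p),
               (0.05 * 55972) / (0.02 * 2177 + 0.001 * 1256),
               tolerance = 1e-12)
  expect_identical(compute_srt(0.05, 0, 0, p), Inf)
  expect_error(compute_srt(0, 0.01, 0.01, p), "p_ags")
})

test_that("net growth rate matches hand arithmetic and its SRT identity", {
  p <- paper_plant()
  # no immigration: mu = 1/theta exactly
  mu <- compute_net_growth(0.03, 0.01, 0.002, 0, p)
  expect_equal(mu, 1 / compute_srt(0.03, 0.01, 0.002, p), tolerance = 1e-12)
  expect_gt(mu, 0)
  # inflow exactly balances wastage
  p_ww0 <- 0.01 * 3433 / 4122.5
  expect_equal(compute_net_growth(0.01, 0.01, 0.01, p_ww0, p), 0,
               tolerance = 1e-15)
  expect_equal(compute_net_growth(0.01, 0.01, 0.01, 0.10, p),
               (0.01 * 3433 - 0.10 * 4122.5) / (0.01 * 55972),
               tolerance = 1e-12)
})

test_that("mu is invariant to a common scaling of one MAG's profile", {
  p <- paper_plant()
  set.seed(11)
  for (i in 1:20) {
    v <- runif(4, 1e-4, 0.05)
    cc <- runif(1, 0.1, 10)
    expect_equal(compute_net_growth(v[1], v[2], v[3], v[4], p),
                 compute_net_growth(cc * v[1], cc * v[2], cc * v[3],
                                    cc * v[4], p),
                 tolerance = 1e-12)
  }
})

test_that("SRT increases strictly as wastage fractions decrease", {
  p <- paper_plant()
  th <- sapply(c(0.02, 0.01, 0.005, 0.001), function(pe)
    compute_srt(0.03, pe, 0.002, p))
  expect_true(all(diff(th) > 0))
})

test_that("whole-system balance assigns classes and flags from the profiles", {
  p <- paper_plant()
  pm <- whole_profile(p_ww = c(0.10, 0, 0.05, 0.02),
                      p_ags = c(0.01, 0.02, 0, 0.02),
                      p_es = c(0.01, 0.02, 0, 0.02),
                      p_ef = c(0.01, 0.02, 0, 0.02),
                      c("dec", "res", "gone", "grow"))
  gr <- run_mass_balance(pm, p)
  rec <- function(id) gr[gr$mag_id == id, ]
  expect_equal(rec("dec")$growth_class, "negative")
  # resident: absent from influent, positive by construction, mu = 1/theta
  expect_equal(rec("res")$flags, "resident_only")
  expect_equal(rec("res")$growth_class, "positive")
  expect_equal(rec("res")$mu_per_day, 1 / rec("res")$theta_days)
  # washed out: in influent, absent from reactor, class undefined
  expect_equal(rec("gone")$flags, "washed_out")
  expect_equal(rec("gone")$growth_class, "undefined")
  expect_true(is.na(rec("gone")$mu_per_day))
})

test_that("metatranscriptomic reactor profiles average the two phases", {
  p <- paper_plant()
  cols <- list(
    influent.rep1 = 0.01,
    AGS.mixed.aerobic.rep1 = 0.02,
    AGS.mixed.anaerobic.rep1 = 0.04,
    excess_sludge.rep1 = 0.01,
    effluent.rep1 = 0.01)
  pm <- make_profile(cols, "MAG1", kind = "metatranscriptomics")
  gr <- run_mass_balance(pm, p)
  expect_equal(gr$theta_days, 0.03 * 55972 / (0.01 * 3433), tolerance = 1e-12)
})

test_that("per-class balance is symmetric when classes are interchangeable", {
  p <- uniform_plant()
  q <- c(0.02, 0.01)
  cols <- list(influent.rep1 = c(0.05, 0.001),
               excess_sludge.rep1 = q, effluent.rep1 = q,
               AGS.FL.rep1 = q, AGS.SG.rep1 = q, AGS.LG.rep1 = q)
  pm <- make_profile(cols, c("a", "b"))
  gr <- run_mass_balance_by_class(pm, p, influent_split = "mlss")
  for (id in c("a", "b")) {
    mus <- gr$mu_per_day[gr$mag_id == id]
    expect_equal(max(mus) - min(mus), 0, tolerance = 1e-12)
  }
})

test_that("default effluent apportionment sends no effluent loss to granules", {
  p <- paper_plant()  # ef_fractions = FL only
  cols <- list(influent.rep1 = 0.01, excess_sludge.rep1 = 0.01,
               effluent.rep1 = 0.5,
               AGS.FL.rep1 = 0.02, AGS.SG.rep1 = 0.02, AGS.LG.rep1 = 0.02)
  pm <- make_profile(cols, "M")
  gr <- run_mass_balance_by_class(pm, p)
  sg <- gr[gr$scope == "SG", ]
  # wastage term contains only the excess-sludge contribution
  expect_equal(1 / sg$theta_days,
               (0.01 * 0.45 * 2177) / (0.02 * 0.53 * 55972),
               tolerance = 1e-12)
})

test_that("dominance threshold is inclusive at 0.1% mean reactor abundance", {
  p <- paper_plant()
  pm <- whole_profile(p_ww = rep(0.01, 5),
                      p_ags = c(0.05, 0.002, 0.001, 0.00099, 0),
                      p_es = rep(0.001, 5), p_ef = rep(0.001, 5),
                      paste0("m", 1:5))
  dom <- classify_dominance(pm, plant = p)
  expect_equal(unname(dom[c("m1", "m2", "m3")]), rep("dominant", 3))
  expect_equal(unname(dom[c("m4", "m5")]), rep("rare", 2))
  expect_equal(sum(dom == "dominant"), 3L)
})

test_that("immigration summary cumulates group shares per replicate", {
  p <- paper_plant()
  # two decliners (AGS 2% and 1%; influent 20% and 25%) and one grower
  pm <- whole_profile(p_ww = c(0.20, 0.25, 1e-4),
                      p_ags = c(0.02, 0.01, 0.10),
                      p_es = c(0.001, 0.001, 0.10),
                      p_ef = c(0.001, 0.001, 0.10),
                      c("n1", "n2", "pos"))
  gr <- run_mass_balance(pm, p)
  expect_equal(gr$growth_class, c("negative", "negative", "positive"))
  s <- summarize_immigration(gr, pm, p)
  neg <- s$shares[s$shares$group == "negative", ]
  expect_equal(neg$ags_mean_pct, 3.0, tolerance = 1e-12)
  expect_equal(neg$influent_mean_pct, 45, tolerance = 1e-12)
  expect_equal(unname(s$immigration_rate_pct["whole"]), 3.0,
               tolerance = 1e-12)
})

test_that("replicate spread is reported as mean and sample sd", {
  p <- paper_plant()
  ags <- c(0.03, 0.04, 0.05)
  cols <- list()
  for (r in 1:3) {
    cols[[sprintf("influent.rep%d", r)]] <- c(0.30, 0.001)
    cols[[sprintf("AGS.mixed.rep%d", r)]] <- c(ags[r], 0.10)
    cols[[sprintf("excess_sludge.rep%d", r)]] <- c(0.001, 0.10)
    cols[[sprintf("effluent.rep%d", r)]] <- c(0.001, 0.10)
  }
  pm <- make_profile(cols, c("neg", "pos"))
  gr <- run_mass_balance(pm, p)
  s <- summarize_immigration(gr, pm, p)
  neg <- s$shares[s$shares$group == "negative", ]
  expect_equal(neg$ags_mean_pct, 4, tolerance = 1e-12)
  expect_equal(neg$ags_sd_pct, 1, tolerance = 1e-12)
})

test_that("immigration rate is zero when every immigrant grows", {
  p <- paper_plant()
  pm <- whole_profile(p_ww = c(1e-4, 1e-4), p_ags = c(0.1, 0.2),
                      p_es = c(0.1, 0.2), p_ef = c(0.1, 0.2),
                      c("a", "b"))
  gr <- run_mass_balance(pm, p)
  s <- summarize_immigration(gr, pm, p)
  expect_equal(unname(s$immigration_rate_pct["whole"]), 0)
})

test_that("daily biomass load ratio follows the plant fluxes", {
  p <- paper_plant()
  expect_equal(daily_load_ratio(p), 100 * 4122.5 / 55972, tolerance = 1e-12)
  expect_equal(round_half_percent(daily_load_ratio(p)), 7.5)
  p2 <- plant_parameters(1000, 10, 5, 1000,
                         c(FL = .3, SG = .4, LG = .3),
                         c(FL = .3, SG = .4, LG = .3))
  expect_equal(daily_load_ratio(p2), 100)
  p3 <- plant_parameters(1000, 10, 5, 100,
                         c(FL = .3, SG = .4, LG = .3),
                         c(FL = .3, SG = .4, LG = .3))
  expect_equal(daily_load_ratio(p3), 10)
})

test_that("missing compartment columns raise a configuration error", {
  p <- paper_plant()
  pm <- make_profile(list(influent.rep1 = 0.1, AGS.mixed.rep1 = 0.1), "M")
  expect_error(run_mass_balance(pm, p), "excess sludge")
})
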