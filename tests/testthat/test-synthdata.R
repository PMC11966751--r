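# Single-guild config helper with full control over the draws.
one_guild_cfg <- function(n, mu_min, mu_max, alpha_meanlog = 0,
                          alpha_sdlog = 0, aff = c(1, 1, 1) / 3, ...) {
  g <- data.frame(guild = "only", n = as.integer(n),
                  mu_min = mu_min, mu_max = mu_max,
                  alpha_meanlog = alpha_meanlog, alpha_sdlog = alpha_sdlog,
                  influent_scale = 1, influent_sdlog = 1,
                  aff_FL = aff[1], aff_SG = aff[2], aff_LG = aff[3])
  synthetic_config(n_mags = n, guilds = g, ...)
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_mags = 40, guilds = default_guilds(40),
                          noise = "multinomial", depth = 1e5, seed = 3)
  a <- emit_profiles(generate_truth(cfg))
  b <- emit_profiles(generate_truth(cfg))
  expect_identical(a$dna$values, b$dna$values)
  expect_identical(a$counts_rna, b$counts_rna)
})

test_that("a zero-growth MAG is in exact influent/wastage balance", {
  cfg <- one_guild_cfg(1, 0, 0, seed = 5)
  tr <- generate_truth(cfg)$truth
  plant <- generate_truth(cfg)$plant
  expect_equal(tr$p_ww * plant$J_WW,
               tr$p_es * plant$J_ES + tr$p_ef * plant$J_EF,
               tolerance = 1e-12)
  expect_equal(tr$p_ags, 1)
})

test_that("equal growth rates reproduce the influent composition in the reactor", {
  cfg <- one_guild_cfg(30, 0.02, 0.02, seed = 6)
  tr <- generate_truth(cfg)$truth
  expect_equal(tr$p_ags, tr$p_ww, tolerance = 1e-12)
})

test_that("growers are enriched in the reactor relative to the influent", {
  g <- data.frame(
    guild = c("fermenter", "PAO"), n = c(30L, 10L),
    mu_min = c(-0.4, 0.02), mu_max = c(-0.1, 0.05),
    alpha_meanlog = 0, alpha_sdlog = 0,
    influent_scale = c(5, 0.2), influent_sdlog = c(1, 1),
    aff_FL = c(.6, .1), aff_SG = c(.3, .4), aff_LG = c(.1, .5))
  cfg <- synthetic_config(n_mags = 40, guilds = g, seed = 7)
  tr <- generate_truth(cfg)$truth
  pao <- tr$guild == "PAO"
  expect_gt(sum(tr$p_ags[pao]), sum(tr$p_ww[pao]))
  expect_true(all(tr$p_ags[pao] > tr$p_ww[pao]))
})

test_that("growth rates above the washout bound are rejected", {
  expect_error(one_guild_cfg(5, 0.05, 0.07, seed = 1), "washout")
})

test_that("the steady-state identity holds exactly on the emitted truth", {
  cfg <- synthetic_config(n_mags = 80, guilds = default_guilds(80), seed = 8)
  out <- generate_truth(cfg)
  tr <- out$truth; plant <- out$plant
  lhs <- tr$p_es * plant$J_ES + tr$p_ef * plant$J_EF - tr$p_ww * plant$J_WW
  rhs <- tr$mu_true * tr$p_ags * plant$M_AGS
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  # class masses respect both per-MAG totals and MLSS class totals
  q <- as.matrix(tr[, c("q_FL", "q_SG", "q_LG")])
  expect_equal(unname(colSums(q)), c(1, 1, 1), tolerance = 1e-9)
  mix <- q %*% plant$mlss_fractions
  expect_lt(max(abs(mix - tr$p_ags)), 1e-9)
})

test_that("noise-free profiles are identical across replicates and consistent", {
  cfg <- synthetic_config(n_mags = 30, guilds = default_guilds(30),
                          n_replicates = 3, seed = 9)
  tr <- generate_truth(cfg)
  pr <- emit_profiles(tr)
  v <- pr$dna$values
  expect_identical(v[, "AGS.mixed.rep1"], v[, "AGS.mixed.rep3"])
  # mixed column equals the MLSS-weighted class columns
  f <- tr$plant$mlss_fractions
  mix <- f[["FL"]] * v[, "AGS.FL.rep1"] + f[["SG"]] * v[, "AGS.SG.rep1"] +
    f[["LG"]] * v[, "AGS.LG.rep1"]
  expect_lt(max(abs(mix - v[, "AGS.mixed.rep1"])), 1e-12)
  # unmapped pseudo-bin: columns sum to the mapped share
  expect_equal(unname(colSums(v)), rep(0.7, ncol(v)), tolerance = 1e-9)
  expect_equal(unname(colSums(pr$rna$values)),
               rep(0.6, ncol(pr$rna$values)), tolerance = 1e-9)
})

test_that("unit activity factors make RNA equal DNA profiles", {
  cfg <- one_guild_cfg(20, -0.3, 0.04, alpha_meanlog = 0, alpha_sdlog = 0,
                       unmapped_dna = 0.3, unmapped_rna = 0.3, seed = 10)
  pr <- emit_profiles(generate_truth(cfg))
  expect_lt(max(abs(pr$rna$values[, "influent.rep1"] -
                      pr$dna$values[, "influent.rep1"])), 1e-12)
  expect_lt(max(abs(pr$rna$values[, "AGS.FL.aerobic.rep1"] -
                      pr$dna$values[, "AGS.FL.rep1"])), 1e-12)
})

test_that("per-MAG RNA/DNA ratios recover relative activity factors", {
  # no unmapped reads: ratio_x = alpha_x / sum_j p_j alpha_j in the reactor
  cfg <- synthetic_config(n_mags = 25, guilds = default_guilds(25),
                          unmapped_dna = 0, unmapped_rna = 0, seed = 11)
  out <- generate_truth(cfg)
  pr <- emit_profiles(out)
  act <- relative_activity(pr$dna, pr$rna, aggregate_class = "mixed")
  tr <- out$truth[match(act$mag_id, out$truth$mag_id), ]
  expected <- tr$alpha / sum(tr$p_ags * tr$alpha)
  expect_lt(max(abs(act$rna_dna_ratio - expected)), 1e-9)
  # constant alpha: slope cutoff is exactly 1
  cfg2 <- one_guild_cfg(15, -0.3, 0.04, unmapped_dna = 0, unmapped_rna = 0,
                        seed = 12)
  pr2 <- emit_profiles(generate_truth(cfg2))
  expect_equal(estimate_cutoff(pr2$dna, pr2$rna, method = "slope"), 1,
               tolerance = 1e-9)
})

test_that("multinomial sampling error scales like the binomial sd", {
  cfg <- synthetic_config(n_mags = 100, guilds = default_guilds(100),
                          noise = "multinomial", depth = 1e6,
                          n_replicates = 3, seed = 13)
  tr <- generate_truth(cfg)
  pr <- emit_profiles(tr)
  p_true <- tr$truth$p_ags * 0.7
  obs <- pr$dna$values[, grep("AGS.mixed", colnames(pr$dna$values))]
  z <- (rowMeans(obs) - p_true) /
    sqrt(p_true * (1 - p_true) / (3 * cfg$depth))
  # standardized errors should look standard normal, not systematically off
  expect_lt(abs(mean(z)), 0.5)
  expect_lt(max(abs(z)), 6)
})

test_that("mass balance on noise-free data recovers stored truth to 1e-9", {
  cfg <- synthetic_config(n_mags = 100, guilds = default_guilds(100),
                          seed = 14)
  out <- generate_truth(cfg)
  pr <- emit_profiles(out)
  gr <- run_mass_balance(pr$dna, out$plant)
  m <- merge(gr, out$truth[, c("mag_id", "mu_true", "theta_true")],
             by = "mag_id")
  expect_lt(max(abs(m$mu_per_day - m$mu_true)), 1e-9)
  expect_lt(max(abs(m$theta_days - m$theta_true) / m$theta_true), 1e-9)
  # per-class recovery against the class-equation truth
  grc <- run_mass_balance_by_class(pr$dna, out$plant)
  for (a in c("FL", "SG", "LG")) {
    mc <- merge(grc[grc$scope == a, ],
                out$truth[, c("mag_id", paste0("mu_", a))], by = "mag_id")
    expect_lt(max(abs(mc$mu_per_day - mc[[paste0("mu_", a)]])), 1e-9)
  }
})

test_that("a written dataset reads back into an equivalent analysis", {
  dir <- tempfile("synthds")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- synthetic_config(n_mags = 20, guilds = default_guilds(20), seed = 15)
  out <- generate_truth(cfg)
  write_synthetic_dataset(out, dir)
  expect_true(all(file.exists(file.path(dir,
    c("profiles_dna.tsv", "profiles_rna.tsv", "counts_dna.tsv",
      "counts_rna.tsv", "plant.yaml", "mags.tsv", "truth.tsv")))))
  plant <- read_plant_config(file.path(dir, "plant.yaml"))
  dna <- read_profile_table(file.path(dir, "profiles_dna.tsv"))
  gr <- run_mass_balance(dna, plant)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  m <- merge(gr, truth[, c("mag_id", "mu_true")], by = "mag_id")
  # percent round trip through text keeps recovery tight
  expect_lt(max(abs(m$mu_per_day - m$mu_true)), 1e-6)
})
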