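#' Default guild palette for the plant simulator
#'
#' Four functional guilds spanning the qualitative structure of an AGS
#' community. Fermenters (including sulfate reducers) decline in the reactor
#' (negative net growth), are abundant in the influent, favor flocs and show
#' elevated RNA/DNA ratios; polyphosphate- and glycogen-accumulating
#' organisms (PAO/GAO) and nitrifiers grow in the reactor, are rare in the
#' influent and favor granules. Positive growth rates are capped well below
#' the washout bound `(J_ES + J_EF) / M_AGS` (about 0.061 1/d for the
#' example plant). Guild names are labels only; no physiology is simulated.
#'
#' @param n_mags Total number of MAGs to distribute over the guilds.
#' @return A data.frame with one row per guild: `guild`, `n`, `mu_min`,
#'   `mu_max`, `alpha_meanlog`, `alpha_sdlog`, `influent_scale`,
#'   `influent_sdlog`, `aff_FL`, `aff_SG`, `aff_LG`.
#' @export
default_guilds <- function(n_mags = 300) {
  n <- c(fermenter = 0.45, nitrifier = 0.25, PAO = 0.15, GAO = 0.15)
  n <- round(n * n_mags)
  n[1] <- n_mags - sum(n[-1])
  data.frame(
    guild = names(n), n = as.integer(n),
    mu_min = c(-0.50, 0.005, 0.010, 0.005),
    mu_max = c(-0.05, 0.050, 0.055, 0.050),
    alpha_meanlog = log(c(2.0, 0.6, 0.8, 0.7)),
    alpha_sdlog = c(0.4, 0.3, 0.3, 0.3),
    influent_scale = c(8.0, 0.4, 0.3, 0.5),
    influent_sdlog = c(1.5, 1.0, 1.0, 1.0),
    aff_FL = c(0.60, 0.30, 0.10, 0.15),
    aff_SG = c(0.30, 0.40, 0.40, 0.45),
    aff_LG = c(0.10, 0.30, 0.50, 0.40),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Configuration of the synthetic plant simulator
#'
#' @param n_mags Number of MAGs.
#' @param guilds Guild table as from [default_guilds()].
#' @param plant Plant template ([plant_parameters]); `J_WW` is recalibrated
#'   during generation (see [generate_truth()]).
#' @param n_replicates Number of replicate sampling weeks (default 3).
#' @param depth Reads per sample for the count noise models.
#' @param noise `"none"`, `"multinomial"` or `"dirichlet_multinomial"`.
#' @param overdispersion Dirichlet precision for the Dirichlet-multinomial
#'   model (larger = closer to multinomial).
#' @param unmapped_dna,unmapped_rna Fraction of reads absorbed by an
#'   explicit unmapped pseudo-bin, so that column sums stay below 1 as in
#'   real profiles (defaults 30% DNA / 40% RNA).
#' @param affinity_jitter Dirichlet precision of per-MAG jitter around the
#'   guild aggregate-affinity weights; `Inf` disables jitter.
#' @param seed RNG seed used for generation.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mags = 300, guilds = default_guilds(n_mags),
                             plant = example_plant(), n_replicates = 3,
                             depth = 1e6,
                             noise = c("none", "multinomial",
                                       "dirichlet_multinomial"),
                             overdispersion = 200,
                             unmapped_dna = 0.30, unmapped_rna = 0.40,
                             affinity_jitter = 100, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(inherits(plant, "plant_parameters"),
            sum(guilds$n) == n_mags, n_replicates >= 1, depth > 0,
            unmapped_dna >= 0, unmapped_dna < 1,
            unmapped_rna >= 0, unmapped_rna < 1,
            all(guilds$aff_FL >= 0), all(guilds$aff_SG >= 0),
            all(guilds$aff_LG >= 0))
  washout <- (plant$J_ES + plant$J_EF) / plant$M_AGS
  if (any(guilds$mu_max >= washout))
    stop(sprintf("guild mu upper bound must stay below the washout bound %.4g 1/d",
                 washout), call. = FALSE)
  structure(list(n_mags = n_mags, guilds = guilds, plant = plant,
                 n_replicates = n_replicates, depth = depth, noise = noise,
                 overdispersion = overdispersion,
                 unmapped_dna = unmapped_dna, unmapped_rna = unmapped_rna,
                 affinity_jitter = affinity_jitter, seed = seed),
            class = "synthetic_config")
}

# Iterative proportional fitting of a positive matrix to given row and
# column totals (Sinkhorn balancing).
ipf_balance <- function(m, row_totals, col_totals, tol = 1e-13,
                        max_iter = 200) {
  for (it in seq_len(max_iter)) {
    m <- m * (row_totals / rowSums(m))
    m <- sweep(m, 2, col_totals / colSums(m), "*")
    if (max(abs(rowSums(m) - row_totals) / row_totals) < tol) break
  }
  m
}

#' Generate the ground truth of a steady-state synthetic plant
#'
#' Draws per-MAG influent abundances, target net growth rates and activity
#' factors guild by guild, then solves the steady-state plant. With wastage
#' assumed well mixed, a MAG with influent fraction `p_WW` and rate `mu`
#' holds reactor mass `m = p_WW * J_WW / ((J_ES + J_EF)/M_AGS - mu)`; the
#' influent flux `J_WW` is recalibrated by the unique scalar making the
#' masses sum to `M_AGS`, so reactor fractions obey the steady-state balance
#' exactly. Each MAG's mass is then spread over FL/SG/LG by its aggregate
#' affinities and reconciled to both the per-MAG totals and the plant's MLSS
#' class totals by iterative proportional fitting, making the mixed profile
#' exactly the MLSS-weighted sum of the class profiles. Excess-sludge and
#' effluent compositions are the es-/ef-fraction weighted class profiles.
#' Because class-structured wastage reweights what each MAG loses, the
#' stored whole-system truth (`mu_true`, `theta_true`) is the exact rate
#' implied by the final compartment profiles - the drawn rates are
#' construction targets (`mu_target`), equal to `mu_true` when wastage
#' composition matches the reactor's.
#'
#' @param cfg A [synthetic_config].
#' @return A list of class `synthetic_truth`: `truth` (per-MAG data.frame
#'   with influent/reactor/class fractions, `mu_true`, `theta_true`,
#'   per-class `mu_*`/`theta_*`, `alpha`, guild), `plant` (calibrated),
#'   `cfg`, `seed`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  plant <- cfg$plant
  g <- cfg$guilds
  guild <- rep(g$guild, g$n)
  idx <- rep(seq_len(nrow(g)), g$n)
  n <- cfg$n_mags
  ids <- sprintf("MAG%04d", seq_len(n))

  w <- g$influent_scale[idx] *
    stats::rlnorm(n, meanlog = 0, sdlog = g$influent_sdlog[idx])
  p_ww <- w / sum(w)
  mu_target <- stats::runif(n, g$mu_min[idx], g$mu_max[idx])
  alpha <- stats::rlnorm(n, g$alpha_meanlog[idx], g$alpha_sdlog[idx])

  b <- (plant$J_ES + plant$J_EF) / plant$M_AGS
  m_raw <- p_ww * plant$J_WW / (b - mu_target)
  j_ww_cal <- plant$J_WW * plant$M_AGS / sum(m_raw)
  plant_cal <- plant_parameters(plant$M_AGS, plant$J_ES, plant$J_EF,
                                j_ww_cal, plant$mlss_fractions,
                                plant$es_fractions, plant$ef_fractions)
  m <- m_raw * plant$M_AGS / sum(m_raw)      # masses now sum to M_AGS
  p_ags <- m / plant$M_AGS

  aff <- cbind(g$aff_FL[idx], g$aff_SG[idx], g$aff_LG[idx])
  aff <- aff / rowSums(aff)
  if (is.finite(cfg$affinity_jitter)) {
    jit <- matrix(stats::rgamma(3 * n, shape = aff * cfg$affinity_jitter,
                                rate = 1), n, 3)
    # guard against degenerate zero draws at tiny shapes
    jit[jit <= 0] <- .Machine$double.eps
    aff <- jit / rowSums(jit)
  }
  raw <- m * aff                              # per-MAG class masses
  class_tot <- plant$mlss_fractions * plant$M_AGS
  m_cls <- ipf_balance(raw, row_totals = m, col_totals = class_tot)
  colnames(m_cls) <- AGG_CLASSES
  q <- sweep(m_cls, 2, class_tot, "/")        # class profiles (fractions)

  p_es <- as.numeric(q %*% plant$es_fractions)
  p_ef <- as.numeric(q %*% plant$ef_fractions)

  wastage <- p_es * plant$J_ES + p_ef * plant$J_EF
  inflow <- p_ww * j_ww_cal
  mu_true <- (wastage - inflow) / (p_ags * plant$M_AGS)
  theta_true <- ifelse(wastage == 0, Inf, p_ags * plant$M_AGS / wastage)

  # per-class truth via the class equations with the default mlss split
  f <- plant$mlss_fractions; s <- f
  cls <- lapply(AGG_CLASSES, function(a) {
    wa <- p_es * plant$es_fractions[[a]] * plant$J_ES +
      p_ef * plant$ef_fractions[[a]] * plant$J_EF
    ba <- q[, a] * f[[a]] * plant$M_AGS
    list(theta = ifelse(wa == 0, Inf, ba / wa),
         mu = (wa - p_ww * s[[a]] * j_ww_cal) / ba)
  })
  names(cls) <- AGG_CLASSES

  truth <- data.frame(
    mag_id = ids, guild = guild,
    p_ww = p_ww, p_ags = p_ags,
    q_FL = q[, "FL"], q_SG = q[, "SG"], q_LG = q[, "LG"],
    p_es = p_es, p_ef = p_ef,
    mu_target = mu_target, mu_true = mu_true, theta_true = theta_true,
    mu_FL = cls$FL$mu, mu_SG = cls$SG$mu, mu_LG = cls$LG$mu,
    theta_FL = cls$FL$theta, theta_SG = cls$SG$theta,
    theta_LG = cls$LG$theta,
    alpha = alpha, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(truth = truth, plant = plant_cal, cfg = cfg,
                 seed = cfg$seed),
            class = "synthetic_truth")
}

# One sample's observed fractions of total reads under the configured noise
# model. 'fractions' are mapped fractions summing to 1; 'mapped' is the
# mapped share of the library.
sample_fractions <- function(fractions, mapped, cfg) {
  probs <- c(fractions * mapped, 1 - mapped)
  if (cfg$noise == "none") return(probs[-length(probs)])
  if (cfg$noise == "dirichlet_multinomial") {
    a <- probs * cfg$overdispersion
    gam <- stats::rgamma(length(a), shape = pmax(a, 1e-12), rate = 1)
    probs <- gam / sum(gam)
  }
  cnt <- stats::rmultinom(1, size = cfg$depth, prob = probs)[, 1]
  (cnt / cfg$depth)[-length(probs)]
}

# Counts backing the fractions (integer; used for the count tables).
sample_counts <- function(fractions, mapped, cfg) {
  probs <- c(fractions * mapped, 1 - mapped)
  if (cfg$noise == "none") {
    cnt <- round(probs * cfg$depth)
  } else {
    if (cfg$noise == "dirichlet_multinomial") {
      a <- probs * cfg$overdispersion
      gam <- stats::rgamma(length(a), shape = pmax(a, 1e-12), rate = 1)
      probs <- gam / sum(gam)
    }
    cnt <- stats::rmultinom(1, size = cfg$depth, prob = probs)[, 1]
  }
  cnt[-length(probs)]
}

#' Emit profile and count tables from a synthetic truth
#'
#' Produces the full set of tables the analysis pipeline consumes: a
#' metagenomic profile (influent, per-class and mixed AGS, excess sludge,
#' effluent, per replicate), a metatranscriptomic profile (with aerobic and
#' anaerobic AGS phase columns, equal in the default generator), and the
#' matching mapped-read count tables. RNA fractions are proportional to
#' `alpha * DNA` renormalized per sample. An explicit unmapped share keeps
#' column sums below 1; it is identical across samples, so mass-balance
#' results are unaffected. Under `noise = "none"` all replicates are
#' identical and fractions are exact; the count noise models resample each
#' replicate at the configured depth.
#'
#' @param truth A [synthetic_truth] from [generate_truth()].
#' @param cfg Optional [synthetic_config]; defaults to the one stored in
#'   `truth`.
#' @return A list with [profile_matrix] elements `dna`, `rna` and integer
#'   count matrices `counts_dna`, `counts_rna`.
#' @export
emit_profiles <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(cfg$seed + 1L)
  tr <- truth$truth
  n <- nrow(tr)
  rna_of <- function(p) {
    tot <- sum(p * tr$alpha)
    if (tot == 0) p else p * tr$alpha / tot
  }
  # base mapped compositions per compartment (each sums to 1 over MAGs)
  dna_base <- list(influent = tr$p_ww,
                   AGS.mixed = tr$p_ags, AGS.FL = tr$q_FL,
                   AGS.SG = tr$q_SG, AGS.LG = tr$q_LG,
                   excess_sludge = tr$p_es, effluent = tr$p_ef)
  rna_base <- lapply(dna_base, rna_of)

  dna_cols <- list(); rna_cols <- list()
  cnt_dna <- list(); cnt_rna <- list()
  for (r in seq_len(cfg$n_replicates)) {
    for (nm in names(dna_base)) {
      key <- sprintf("%s.rep%d", nm, r)
      dna_cols[[key]] <- sample_fractions(dna_base[[nm]],
                                          1 - cfg$unmapped_dna, cfg)
      cnt_dna[[key]] <- sample_counts(dna_base[[nm]],
                                      1 - cfg$unmapped_dna, cfg)
      if (grepl("^AGS", nm)) {
        for (ph in c("aerobic", "anaerobic")) {
          pkey <- sprintf("%s.%s.rep%d", nm, ph, r)
          rna_cols[[pkey]] <- sample_fractions(rna_base[[nm]],
                                               1 - cfg$unmapped_rna, cfg)
          cnt_rna[[pkey]] <- sample_counts(rna_base[[nm]],
                                           1 - cfg$unmapped_rna, cfg)
        }
      } else {
        rna_cols[[key]] <- sample_fractions(rna_base[[nm]],
                                            1 - cfg$unmapped_rna, cfg)
        cnt_rna[[key]] <- sample_counts(rna_base[[nm]],
                                        1 - cfg$unmapped_rna, cfg)
      }
    }
  }
  to_mat <- function(cols) {
    m <- do.call(cbind, cols)
    rownames(m) <- tr$mag_id
    m
  }
  list(dna = profile_matrix(to_mat(dna_cols), names(dna_cols),
                            kind = "metagenomics"),
       rna = profile_matrix(to_mat(rna_cols), names(rna_cols),
                            kind = "metatranscriptomics"),
       counts_dna = to_mat(cnt_dna),
       counts_rna = to_mat(cnt_rna))
}

#' Synthetic MAG metadata
#'
#' Completeness and contamination drawn to exercise the genome-quality
#' filter (some MAGs fall below the MIMAG-style thresholds), with synthetic
#' lineage strings and the generator's guild labels.
#'
#' @param truth A [synthetic_truth].
#' @return A MAG metadata data.frame (see [read_mag_metadata()]).
#' @export
synthetic_mag_metadata <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 2L)
  tr <- truth$truth
  n <- nrow(tr)
  data.frame(
    mag_id = tr$mag_id,
    taxonomy = sprintf("d__Bacteria;p__SimPhylum%02d;g__SimGenus%03d",
                       (seq_len(n) %% 12) + 1, seq_len(n)),
    completeness = round(stats::runif(n, 30, 100), 1),
    contamination = round(stats::rexp(n, rate = 1 / 4), 2),
    guild = tr$guild, stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every input file of the analysis in the package's external formats:
#' `profiles_dna.tsv`, `profiles_rna.tsv`, `counts_dna.tsv`,
#' `counts_rna.tsv`, `plant.yaml` (the calibrated plant), `mags.tsv` and
#' `truth.tsv`.
#'
#' @param truth A [synthetic_truth].
#' @param dir Output directory (created if needed).
#' @param profiles Optional pre-computed output of [emit_profiles()].
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir, profiles = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(profiles)) profiles <- emit_profiles(truth)
  write_profile_table(profiles$dna, file.path(dir, "profiles_dna.tsv"))
  write_profile_table(profiles$rna, file.path(dir, "profiles_rna.tsv"))
  wr <- function(m, path) {
    df <- data.frame(mag_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(profiles$counts_dna, file.path(dir, "counts_dna.tsv"))
  wr(profiles$counts_rna, file.path(dir, "counts_rna.tsv"))
  write_plant_config(truth$plant, file.path(dir, "plant.yaml"))
  utils::write.table(synthetic_mag_metadata(truth),
                     file.path(dir, "mags.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
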