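#' Run the full immigration analysis
#'
#' Orchestrates every stage over one dataset: whole-system and per-class
#' mass balance on the metagenomic and metatranscriptomic profiles,
#' immigration summaries, RNA/DNA relative activity with an estimated
#' cutoff, differential expression of reactor versus influent with
#' growth-by-activity quadrant counts, and the beta-diversity statistics
#' (Bray-Curtis, PCoA, ANOSIM, UPGMA dendrogram). All result tables are
#' written to `outdir` as TSV plus a plain-text `summary.txt` with the
#' headline quantities. Outputs are deterministic for a fixed seed; partial
#' outputs are removed if any stage fails.
#'
#' @param dna,rna [profile_matrix] inputs (paths to TSVs are also accepted).
#' @param plant A [plant_parameters] object or path to a plant YAML.
#' @param counts_rna Optional RNA count matrix (MAGs x samples) or TSV path
#'   for the differential-expression stage.
#' @param mags Optional MAG metadata data.frame or TSV path; when given, the
#'   quadrant classification is restricted to MAGs passing [filter_mags()].
#' @param outdir Output directory.
#' @param influent_split Influent apportionment for the per-class balance
#'   (see [run_mass_balance_by_class()]).
#' @param cutoff_method Activity-cutoff estimator (see [estimate_cutoff()]).
#' @param seed Seed for the stochastic steps (ANOSIM permutations).
#' @param n_perm ANOSIM permutation count.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(dna, rna, plant, counts_rna = NULL, mags = NULL,
                         outdir, influent_split = "mlss",
                         cutoff_method = "slope", seed = 1, n_perm = 999) {
  if (is.character(dna)) dna <- read_profile_table(dna, "metagenomics")
  if (is.character(rna)) rna <- read_profile_table(rna, "metatranscriptomics")
  if (is.character(plant)) plant <- read_plant_config(plant)
  if (is.character(counts_rna)) {
    df <- utils::read.delim(counts_rna, check.names = FALSE)
    counts_rna <- as.matrix(df[, -1]); rownames(counts_rna) <- df[[1]]
  }
  if (is.character(mags)) mags <- read_mag_metadata(mags)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name, ...) {
    path <- file.path(outdir, name)
    fn(..., path = path)
    written <<- c(written, path)
    path
  }
  res <- tryCatch({
    growth <- list(
      metagenomics = run_mass_balance(dna, plant),
      metatranscriptomics = run_mass_balance(rna, plant))
    growth_cls <- list(
      metagenomics = run_mass_balance_by_class(dna, plant,
                                               influent_split = influent_split),
      metatranscriptomics = run_mass_balance_by_class(rna, plant,
                                                      influent_split = influent_split))
    imm <- lapply(c(metagenomics = "metagenomics",
                    metatranscriptomics = "metatranscriptomics"),
                  function(k) {
      prof <- if (k == "metagenomics") dna else rna
      summarize_immigration(rbind(growth[[k]], growth_cls[[k]]), prof, plant)
    })
    for (k in names(growth)) {
      emit(function(x, path) write_growth_records(x, path),
           sprintf("growth_%s.tsv", k), rbind(growth[[k]], growth_cls[[k]]))
      emit(function(x, path) utils::write.table(
             x, path, sep = "\t", quote = FALSE, row.names = FALSE),
           sprintf("immigration_%s.tsv", k),
           merge(imm[[k]]$counts, imm[[k]]$shares, by = c("scope", "group")))
    }

    # prefer the whole-reactor (mixed) profile for activity ratios
    mixed_cls <- if (length(profile_columns(dna, "AGS", "mixed")) &&
                     length(profile_columns(rna, "AGS", "mixed")))
      "mixed" else NULL
    act <- relative_activity(dna, rna, scope = "AGS",
                             aggregate_class = mixed_cls)
    cutoff <- estimate_cutoff(dna, rna, scope = "AGS",
                              aggregate_class = mixed_cls,
                              method = cutoff_method)
    act <- classify_relative_activity(act, cutoff)

    de <- quad <- NULL
    if (!is.null(counts_rna)) {
      keys <- parse_sample_keys(colnames(counts_rna))
      ga <- colnames(counts_rna)[keys$compartment == "influent"]
      gb <- colnames(counts_rna)[keys$compartment == "AGS" &
                                   keys$aggregate_class == "mixed"]
      if (length(ga) >= 2 && length(gb) >= 2) {
        de <- de_test(counts_rna, ga, gb, seed = seed)
        keep <- if (is.null(mags)) NULL else filter_mags(mags)
        quad <- classify_quadrants(growth$metagenomics, de,
                                   mag_subset = keep)
        act <- merge(act, de[, c("mag_id", "log2fc", "p_value", "q_value",
                                 "tier")], by = "mag_id", all.x = TRUE)
        act$activity_class <- ifelse(is.na(act$log2fc), NA_character_,
                                     ifelse(act$log2fc > 0, "active",
                                            "inactive"))
        emit(function(x, path) write_de_results(x, path), "de_results.tsv",
             de)
      }
    }
    emit(function(x, path) write_activity_records(x, path),
         "activity.tsv", act)

    bc <- bray_curtis(dna)
    ord <- pcoa(bc)
    keys <- dna$keys
    grp <- ifelse(keys$aggregate_class %in% c("FL", "SG", "LG"),
                  keys$aggregate_class, keys$compartment)
    ano <- tryCatch(anosim(bc, grp, n_perm = n_perm, seed = seed),
                    error = function(e) NULL)
    dend <- hclust_average(bc)
    emit(function(x, path) write_dist_matrix(x, path),
         "bray_curtis_dna.tsv", bc)
    emit(function(x, path) utils::write.table(
           data.frame(sample = rownames(x$coordinates), x$coordinates,
                      check.names = FALSE),
           path, sep = "\t", quote = FALSE, row.names = FALSE),
         "pcoa_dna.tsv", ord)
    emit(function(x, path) as_newick(x, path), "dendrogram_dna.nwk", dend)

    summary_path <- file.path(outdir, "summary.txt")
    written <- c(written, summary_path)
    write_summary(summary_path, plant, growth, imm, cutoff, cutoff_method,
                  act, quad, ano, seed)
    list(growth = growth, growth_by_class = growth_cls, immigration = imm,
         activity = act, cutoff = cutoff, de = de, quadrants = quad,
         bray_curtis = bc, pcoa = ord, anosim = ano, dendrogram = dend)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

pm_sd <- function(m, s) sprintf("%.2f +/- %.2f", m, ifelse(is.na(s), 0, s))

write_summary <- function(path, plant, growth, imm, cutoff, cutoff_method,
                          act, quad, ano, seed) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("AGS immigration mass-balance summary")
  w("seed: %d", seed)
  dl <- daily_load_ratio(plant)
  w("daily influent biomass load: %.2f%% of reactor biomass (%.1f%% to nearest 0.5%%)",
    dl, round_half_percent(dl))
  for (k in names(imm)) {
    w("")
    w("[%s]", k)
    cs <- imm[[k]]$counts; sh <- imm[[k]]$shares
    for (i in seq_len(nrow(cs))) {
      w("  %s %s: n = %s (%.1f dominant / %.1f rare); AGS %s%%; influent %s%%",
        cs$scope[i], cs$group[i], pm_sd(cs$n_mean[i], cs$n_sd[i]),
        cs$n_dominant_mean[i], cs$n_rare_mean[i],
        pm_sd(sh$ags_mean_pct[i], sh$ags_sd_pct[i]),
        pm_sd(sh$influent_mean_pct[i], sh$influent_sd_pct[i]))
    }
    ir <- imm[[k]]$immigration_rate_pct
    w("  immigration rate: %s",
      paste(sprintf("%s %.2f%%", names(ir), ir), collapse = ", "))
  }
  # group relative activity: cumulative RNA share over cumulative DNA share
  shd <- imm$metagenomics$shares
  shr <- imm$metatranscriptomics$shares
  both <- merge(shd[shd$scope == "whole", c("group", "ags_mean_pct")],
                shr[shr$scope == "whole", c("group", "ags_mean_pct")],
                by = "group", suffixes = c("_dna", "_rna"))
  w("")
  for (i in seq_len(nrow(both))) {
    w("group relative activity (%s growth): %.2f (= %.1f / %.1f)",
      both$group[i],
      group_relative_activity(both$ags_mean_pct_rna[i],
                              both$ags_mean_pct_dna[i]),
      both$ags_mean_pct_rna[i], both$ags_mean_pct_dna[i])
  }
  w("")
  w("RNA/DNA activity cutoff (%s): %.4f", cutoff_method, cutoff)
  if (!is.null(act$relative_activity_class)) {
    w("relative activity: %d higher, %d lower",
      sum(act$relative_activity_class == "higher", na.rm = TRUE),
      sum(act$relative_activity_class == "lower", na.rm = TRUE))
  }
  if (!is.null(quad)) {
    w("")
    w("growth x activity quadrants (sign-only, %d MAGs):", quad$n_classified)
    tt <- quad$totals
    for (g in rownames(tt)) for (a in colnames(tt))
      w("  %s / %s: %d", g, a, tt[g, a])
  }
  if (!is.null(ano)) {
    w("")
    w("ANOSIM on Bray-Curtis (DNA): R = %.3f, p = %.4g", ano$R, ano$p_value)
  }
}
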