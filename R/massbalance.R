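#' Per-MAG solids retention time
#'
#' SRT of one MAG at steady state: the biomass of that MAG held in the
#' reactor divided by the biomass of that MAG leaving per day with excess
#' sludge and effluent,
#' \deqn{\theta_x = \frac{p_{x,AGS}\,M_{AGS}}{p_{x,ES}\,J_{ES} + p_{x,EF}\,J_{EF}}.}
#' When nothing of the MAG leaves the system the SRT is `Inf`.
#'
#' @param p_ags Relative abundance (fraction) of the MAG in the reactor; must
#'   be positive.
#' @param p_es,p_ef Relative abundance in the excess sludge and effluent.
#' @param plant A [plant_parameters] object.
#' @return SRT in days (vectorized over the profile arguments).
#' @export
compute_srt <- function(p_ags, p_es, p_ef, plant) {
  stopifnot(inherits(plant, "plant_parameters"))
  if (any(p_ags <= 0))
    stop("p_ags must be > 0: SRT is undefined for a MAG absent from the reactor",
         call. = FALSE)
  if (any(p_es < 0) || any(p_ef < 0))
    stop("p_es and p_ef must be >= 0", call. = FALSE)
  num <- p_ags * plant$M_AGS
  den <- p_es * plant$J_ES + p_ef * plant$J_EF
  ifelse(den == 0, Inf, num / den)
}

#' Per-MAG net growth rate
#'
#' Steady-state net growth rate of one MAG: biomass leaving minus biomass
#' immigrating, per unit of that MAG's reactor biomass,
#' \deqn{\mu_x = \frac{p_{x,ES}\,J_{ES} + p_{x,EF}\,J_{EF} - p_{x,WW}\,J_{WW}}
#'   {p_{x,AGS}\,M_{AGS}},}
#' equivalently \eqn{\mu_x = 1/\theta_x - p_{x,WW} J_{WW}/(p_{x,AGS} M_{AGS})}.
#' A negative rate means the MAG declines in the reactor and persists only
#' through continuous immigration with the influent.
#'
#' @inheritParams compute_srt
#' @param p_ww Relative abundance (fraction) of the MAG in the influent.
#' @return Net growth rate in 1/d (vectorized).
#' @export
compute_net_growth <- function(p_ags, p_es, p_ef, p_ww, plant) {
  stopifnot(inherits(plant, "plant_parameters"))
  if (any(p_ags <= 0))
    stop("p_ags must be > 0: growth rate is undefined for a MAG absent from the reactor",
         call. = FALSE)
  if (any(p_es < 0) || any(p_ef < 0) || any(p_ww < 0))
    stop("p_es, p_ef and p_ww must be >= 0", call. = FALSE)
  (p_es * plant$J_ES + p_ef * plant$J_EF - p_ww * plant$J_WW) /
    (p_ags * plant$M_AGS)
}

# Mean profile over the matching columns, for one replicate. For
# metatranscriptomics the aerobic and anaerobic phase columns are averaged.
compartment_profile <- function(profiles, compartment, replicate,
                                aggregate_class = NULL) {
  idx <- profile_columns(profiles, compartment = compartment,
                         replicate = replicate,
                         aggregate_class = aggregate_class)
  if (!length(idx)) return(NULL)
  rowMeans(profiles$values[, idx, drop = FALSE])
}

# Reconstruct the whole-reactor (mixed) AGS profile for one replicate:
# the mixed column when present, otherwise sum_a f_a * p_{x,a} over the
# per-class columns.
ags_profile <- function(profiles, plant, replicate) {
  p <- compartment_profile(profiles, "AGS", replicate, "mixed")
  if (!is.null(p)) return(p)
  f <- plant$mlss_fractions
  per_class <- lapply(AGG_CLASSES, function(a)
    compartment_profile(profiles, "AGS", replicate, a))
  if (any(vapply(per_class, is.null, logical(1)))) return(NULL)
  f[["FL"]] * per_class[[1]] + f[["SG"]] * per_class[[2]] +
    f[["LG"]] * per_class[[3]]
}

#' Whole-system mass balance over all MAGs and replicates
#'
#' Applies the SRT and net-growth equations MAG by MAG for each replicate.
#' The reactor profile is the `AGS.mixed` column when present, otherwise it
#' is reconstructed from the per-class columns weighted by the MLSS
#' aggregate fractions; for metatranscriptomics the aerobic and anaerobic
#' phase profiles are averaged first. MAGs absent from the reactor but
#' present in the influent are flagged `washed_out` and keep an undefined
#' growth class; MAGs absent from the influent are `resident_only` (they are
#' not immigrants and are excluded from immigration summaries).
#'
#' @param profiles A [profile_matrix] holding, per replicate, influent,
#'   effluent and excess-sludge columns plus a mixed or per-class AGS
#'   profile.
#' @param plant A [plant_parameters] object.
#' @param kind Profile kind; defaults to the profile's own kind.
#' @param dominance_threshold Mean mixed-reactor abundance at or above which
#'   a MAG is called dominant (fraction; 0.001 = 0.1%).
#' @return A data.frame of growth records with columns `mag_id`,
#'   `replicate`, `scope` (`"whole"`), `theta_days`, `mu_per_day`,
#'   `growth_class` (`positive`/`negative`/`zero`/`undefined`), `dominance`
#'   and `flags`.
#' @export
run_mass_balance <- function(profiles, plant, kind = profiles$kind,
                             dominance_threshold = 0.001) {
  stopifnot(inherits(profiles, "profile_matrix"),
            inherits(plant, "plant_parameters"))
  reps <- sort(unique(profiles$keys$replicate))
  dom <- classify_dominance(profiles, plant = plant,
                            threshold = dominance_threshold)
  out <- lapply(reps, function(r) {
    p_ww <- compartment_profile(profiles, "influent", r)
    p_es <- compartment_profile(profiles, "excess_sludge", r)
    p_ef <- compartment_profile(profiles, "effluent", r)
    p_ags <- ags_profile(profiles, plant, r)
    for (nm in c("p_ww", "p_es", "p_ef", "p_ags"))
      if (is.null(get(nm)))
        stop(sprintf("replicate %d: missing %s column(s)", r,
                     switch(nm, p_ww = "influent", p_es = "excess sludge",
                            p_ef = "effluent", p_ags = "AGS")),
             call. = FALSE)
    growth_records(mag_ids(profiles), r, "whole",
                   p_ags * plant$M_AGS,
                   p_es * plant$J_ES + p_ef * plant$J_EF,
                   p_ww * plant$J_WW, dom)
  })
  do.call(rbind, out)
}

# Shared record builder: biomass term (kg), wastage term (kg/d) and influent
# term (kg/d) already apportioned to the scope at hand.
growth_records <- function(ids, replicate, scope, biomass, wastage, inflow,
                           dominance) {
  theta <- ifelse(biomass > 0, ifelse(wastage == 0, Inf, biomass / wastage),
                  NA_real_)
  mu <- ifelse(biomass > 0, (wastage - inflow) / biomass, NA_real_)
  cls <- ifelse(is.na(mu), "undefined",
                ifelse(mu > 0, "positive", ifelse(mu < 0, "negative", "zero")))
  washed_out <- biomass == 0 & inflow > 0
  resident_only <- inflow == 0 & biomass > 0
  flags <- ifelse(washed_out, "washed_out",
                  ifelse(resident_only, "resident_only", ""))
  data.frame(mag_id = ids, replicate = replicate, scope = scope,
             theta_days = theta, mu_per_day = mu, growth_class = cls,
             dominance = unname(dominance[ids]), flags = flags,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-aggregate-class mass balance
#'
#' Runs the same steady-state balance separately for flocs, small granules
#' and large granules. For class *a* with MLSS fraction `f_a`, excess-sludge
#' fraction `g_a` and effluent fraction `h_a`, the biomass term is
#' `p_{x,a} f_a M_AGS`, the wastage term `p_{x,ES} g_a J_ES + p_{x,EF} h_a
#' J_EF`, and the influent term `p_{x,WW} s_a J_WW`, where the influent
#' apportionment weights `s_a` default to the MLSS fractions (immigrants
#' entering a well-mixed reactor meet biomass in proportion to its mass).
#'
#' @inheritParams run_mass_balance
#' @param influent_split How the influent flux is apportioned between
#'   classes: `"mlss"` (by MLSS mass fraction, default), `"all-to-FL"`
#'   (immigrants join the flocs), or `"uniform"` (each class receives the
#'   full influent flux).
#' @return A growth-record data.frame with scopes `FL`, `SG`, `LG`.
#' @export
run_mass_balance_by_class <- function(profiles, plant, kind = profiles$kind,
                                      influent_split = c("mlss", "all-to-FL",
                                                         "uniform"),
                                      dominance_threshold = 0.001) {
  stopifnot(inherits(profiles, "profile_matrix"),
            inherits(plant, "plant_parameters"))
  influent_split <- match.arg(influent_split)
  s <- switch(influent_split,
              "mlss" = plant$mlss_fractions,
              "all-to-FL" = c(FL = 1, SG = 0, LG = 0),
              "uniform" = c(FL = 1, SG = 1, LG = 1))
  reps <- sort(unique(profiles$keys$replicate))
  dom <- classify_dominance(profiles, plant = plant,
                            threshold = dominance_threshold)
  out <- list()
  for (r in reps) {
    p_ww <- compartment_profile(profiles, "influent", r)
    p_es <- compartment_profile(profiles, "excess_sludge", r)
    p_ef <- compartment_profile(profiles, "effluent", r)
    if (is.null(p_ww) || is.null(p_es) || is.null(p_ef))
      stop(sprintf("replicate %d: missing influent/excess-sludge/effluent column(s)", r),
           call. = FALSE)
    for (a in AGG_CLASSES) {
      q <- compartment_profile(profiles, "AGS", r, a)
      if (is.null(q))
        stop(sprintf("replicate %d: missing AGS class column for %s", r, a),
             call. = FALSE)
      out[[paste(r, a)]] <- growth_records(
        mag_ids(profiles), r, a,
        q * plant$mlss_fractions[[a]] * plant$M_AGS,
        p_es * plant$es_fractions[[a]] * plant$J_ES +
          p_ef * plant$ef_fractions[[a]] * plant$J_EF,
        p_ww * s[[a]] * plant$J_WW, dom)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify MAGs as dominant or rare
#'
#' A MAG is dominant when its mean whole-reactor relative abundance over
#' replicates is at or above the threshold (default 0.1%), rare otherwise.
#'
#' @inheritParams run_mass_balance
#' @param threshold Abundance threshold as a fraction, in (0, 1).
#' @param plant Needed only to reconstruct the mixed profile from per-class
#'   columns; defaults to [example_plant()] MLSS weights when absent.
#' @return Named character vector (`"dominant"`/`"rare"`) over MAG ids.
#' @export
classify_dominance <- function(profiles, threshold = 0.001, plant = NULL) {
  stopifnot(inherits(profiles, "profile_matrix"),
            threshold > 0, threshold < 1)
  if (is.null(plant)) plant <- example_plant()
  reps <- sort(unique(profiles$keys$replicate))
  per_rep <- lapply(reps, function(r) ags_profile(profiles, plant, r))
  per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
  if (!length(per_rep))
    stop("no AGS columns found for dominance classification", call. = FALSE)
  m <- rowMeans(do.call(cbind, per_rep))
  stats::setNames(ifelse(m >= threshold, "dominant", "rare"),
                  mag_ids(profiles))
}

#' Summarize the contribution of immigration
#'
#' Splits immigrant MAGs (those shared between influent and reactor) into the
#' positive- and negative-net-growth groups and reports, per group: the MAG
#' counts (with dominant/rare split) and the cumulative relative abundance in
#' the reactor and in the influent, as mean and sample standard deviation
#' (n-1) across replicates. The immigration rate is the negative group's
#' cumulative reactor share: the slice of the community that persists only
#' through continuous immigration. `resident_only` MAGs are excluded. When
#' per-class records are supplied the per-class immigration rates are
#' reported as well.
#'
#' @param records Growth records from [run_mass_balance()] (optionally
#'   rbind-ed with [run_mass_balance_by_class()] output).
#' @param profiles The [profile_matrix] the records were computed from.
#' @param plant A [plant_parameters] object (mixed-profile reconstruction).
#' @return A list of class `immigration_summary` with elements `counts`
#'   (per group and dominance, mean and sd over replicates), `shares`
#'   (cumulative percent shares per scope, group and compartment) and
#'   `immigration_rate_pct` (named vector of means per scope, with an
#'   `sd` attribute).
#' @export
summarize_immigration <- function(records, profiles, plant = NULL) {
  stopifnot(inherits(profiles, "profile_matrix"))
  if (is.null(plant)) plant <- example_plant()
  recs <- records[records$flags != "resident_only" &
                    records$growth_class %in% c("positive", "negative"), ,
                  drop = FALSE]
  reps <- sort(unique(recs$replicate))
  scopes <- unique(recs$scope)

  count_rows <- list(); share_rows <- list()
  for (sc in scopes) {
    cnt <- list(); shr <- list()
    for (r in reps) {
      sub <- recs[recs$scope == sc & recs$replicate == r, , drop = FALSE]
      p_ww <- compartment_profile(profiles, "influent", r)
      p_sys <- if (sc == "whole") ags_profile(profiles, plant, r)
               else compartment_profile(profiles, "AGS", r, sc)
      for (g in c("positive", "negative")) {
        ids <- sub$mag_id[sub$growth_class == g]
        ids_dom <- sub$mag_id[sub$growth_class == g &
                                sub$dominance == "dominant"]
        cnt[[paste(r, g)]] <- data.frame(
          replicate = r, group = g, n = length(ids),
          n_dominant = length(ids_dom),
          n_rare = length(ids) - length(ids_dom))
        shr[[paste(r, g)]] <- data.frame(
          replicate = r, group = g,
          ags_pct = 100 * sum(p_sys[ids]),
          influent_pct = 100 * sum(p_ww[ids]))
      }
    }
    cnt <- do.call(rbind, cnt); shr <- do.call(rbind, shr)
    for (g in c("positive", "negative")) {
      cg <- cnt[cnt$group == g, ]; sg <- shr[shr$group == g, ]
      count_rows[[paste(sc, g)]] <- data.frame(
        scope = sc, group = g,
        n_mean = mean(cg$n), n_sd = stats::sd(cg$n),
        n_dominant_mean = mean(cg$n_dominant),
        n_rare_mean = mean(cg$n_rare),
        stringsAsFactors = FALSE)
      share_rows[[paste(sc, g)]] <- data.frame(
        scope = sc, group = g,
        ags_mean_pct = mean(sg$ags_pct), ags_sd_pct = stats::sd(sg$ags_pct),
        influent_mean_pct = mean(sg$influent_pct),
        influent_sd_pct = stats::sd(sg$influent_pct),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, count_rows); rownames(counts) <- NULL
  shares <- do.call(rbind, share_rows); rownames(shares) <- NULL
  neg <- shares[shares$group == "negative", ]
  rate <- stats::setNames(neg$ags_mean_pct, neg$scope)
  attr(rate, "sd") <- stats::setNames(neg$ags_sd_pct, neg$scope)
  structure(list(kind = profiles$kind, counts = counts, shares = shares,
                 immigration_rate_pct = rate),
            class = "immigration_summary")
}

#' @export
print.immigration_summary <- function(x, ...) {
  cat(sprintf("Immigration summary (%s)\n", x$kind))
  for (i in seq_len(nrow(x$counts))) {
    cn <- x$counts[i, ]; sh <- x$shares[i, ]
    cat(sprintf("  [%s] %s: n = %.1f +/- %.1f (%.1f dominant, %.1f rare); AGS %.2f +/- %.2f%%, influent %.2f +/- %.2f%%\n",
                cn$scope, cn$group, cn$n_mean,
                ifelse(is.na(cn$n_sd), 0, cn$n_sd),
                cn$n_dominant_mean, cn$n_rare_mean,
                sh$ags_mean_pct, ifelse(is.na(sh$ags_sd_pct), 0, sh$ags_sd_pct),
                sh$influent_mean_pct,
                ifelse(is.na(sh$influent_sd_pct), 0, sh$influent_sd_pct)))
  }
  cat("  immigration rate (negative-group AGS share):",
      paste(sprintf("%s %.2f%%", names(x$immigration_rate_pct),
                    x$immigration_rate_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Write growth records to TSV
#'
#' @param records Growth-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
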