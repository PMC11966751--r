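#' Per-MAG relative activity (RNA/DNA ratio)
#'
#' For each MAG, the mean relative expression across the scope's replicate
#' columns divided by the mean relative abundance: relative expression
#' reflects a population's overall activity while relative abundance reflects
#' its size, so the ratio is a per-unit-biomass activity proxy ("relative
#' activity"). Mean profiles across replicates are used because per-replicate
#' ratios are noisy where abundance and expression are low. Ratios built on a
#' DNA mean below `dna_floor` are flagged low-confidence but kept.
#'
#' @param dna Metagenomic [profile_matrix].
#' @param rna Metatranscriptomic [profile_matrix] (phase columns, if present,
#'   enter the mean).
#' @param scope Compartment to evaluate in (default `"AGS"`).
#' @param aggregate_class Optional aggregate-class restriction (e.g.
#'   `"mixed"` for the whole-reactor profile); `NULL` uses every column of
#'   the compartment.
#' @param dna_floor DNA-mean fraction below which the ratio is flagged
#'   low-confidence.
#' @return A data.frame with columns `mag_id`, `dna_mean`, `rna_mean`,
#'   `rna_dna_ratio` (NA when the DNA mean is zero) and `low_confidence`.
#' @export
relative_activity <- function(dna, rna, scope = "AGS",
                              aggregate_class = NULL, dna_floor = 1e-5) {
  stopifnot(inherits(dna, "profile_matrix"), inherits(rna, "profile_matrix"))
  common <- intersect(mag_ids(dna), mag_ids(rna))
  if (!length(common))
    stop("DNA and RNA profiles share no MAG ids", call. = FALSE)
  di <- profile_columns(dna, compartment = scope,
                        aggregate_class = aggregate_class)
  ri <- profile_columns(rna, compartment = scope,
                        aggregate_class = aggregate_class)
  if (!length(di) || !length(ri))
    stop(sprintf("no '%s' columns in both profiles", scope), call. = FALSE)
  dm <- rowMeans(dna$values[common, di, drop = FALSE])
  rm_ <- rowMeans(rna$values[common, ri, drop = FALSE])
  ratio <- ifelse(dm > 0, rm_ / dm, NA_real_)
  data.frame(mag_id = common, dna_mean = unname(dm), rna_mean = unname(rm_),
             rna_dna_ratio = unname(ratio),
             low_confidence = unname(dm < dna_floor),
             stringsAsFactors = FALSE)
}

#' Estimate the RNA/DNA activity cutoff
#'
#' The threshold separating MAGs with higher and lower relative activity.
#' Because mapped metatranscriptomic read fractions are typically lower than
#' metagenomic ones, the community-wide RNA/DNA ratio sits below 1; the
#' cutoff recovers that community-average ratio. `"slope"` (default) fits a
#' least-squares line through the origin of mean RNA versus mean DNA
#' fractions across MAGs, which weights MAGs by abundance; `"mean_ratio"`
#' averages the per-MAG ratios with equal weight. A fixed cutoff of 1 can
#' always be passed downstream instead.
#'
#' @inheritParams relative_activity
#' @param method `"slope"` or `"mean_ratio"`.
#' @return The cutoff (dimensionless scalar).
#' @export
estimate_cutoff <- function(dna, rna, scope = "AGS",
                            aggregate_class = NULL,
                            method = c("slope", "mean_ratio")) {
  method <- match.arg(method)
  act <- relative_activity(dna, rna, scope = scope,
                           aggregate_class = aggregate_class)
  pos <- act$dna_mean > 0
  if (!any(pos))
    stop("cannot estimate a cutoff: all DNA means are zero", call. = FALSE)
  if (sum(pos) < 2L)
    warning("cutoff estimated from a single MAG")
  if (method == "slope") {
    sum(act$rna_mean[pos] * act$dna_mean[pos]) / sum(act$dna_mean[pos]^2)
  } else {
    mean(act$rna_mean[pos] / act$dna_mean[pos])
  }
}

#' Classify relative activity against a cutoff
#'
#' @param activity Output of [relative_activity()].
#' @param cutoff RNA/DNA threshold (e.g. from [estimate_cutoff()], or 1).
#' @return The input data.frame with a `relative_activity_class` column
#'   (`"higher"` iff ratio >= cutoff, `"lower"` otherwise, NA when the ratio
#'   is undefined).
#' @export
classify_relative_activity <- function(activity, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  activity$relative_activity_class <-
    ifelse(is.na(activity$rna_dna_ratio), NA_character_,
           ifelse(activity$rna_dna_ratio >= cutoff, "higher", "lower"))
  activity
}

#' Cumulative relative activity of a group of MAGs
#'
#' The ratio of a group's cumulative relative expression to its cumulative
#' relative abundance (both in percent or both as fractions). This equals the
#' abundance-weighted mean of the member RNA/DNA ratios. For the studied
#' plant the positive-net-growth group has 51.7% cumulative expression over
#' 66.4% cumulative abundance, a relative activity of 0.78.
#'
#' @param cum_expression Cumulative relative expression of the group.
#' @param cum_abundance Cumulative relative abundance of the group (same
#'   units; must be > 0).
#' @return Dimensionless group relative activity.
#' @export
group_relative_activity <- function(cum_expression, cum_abundance) {
  stopifnot(cum_abundance > 0, cum_expression >= 0)
  cum_expression / cum_abundance
}

#' Cross-classify growth against expression-based activity
#'
#' Joins growth records with differential-expression results and counts MAGs
#' in the four growth-by-activity quadrants: positive/negative net growth
#' crossed with active/inactive, where a MAG is active iff its expression is
#' higher in the reactor than in the influent (`log2fc > 0`). Counts are also
#' split by significance tier (see [de_tier()]); both the sign-only totals
#' and the tier-filtered counts are reported since an activity call may or
#' may not demand significance.
#'
#' @param growth Growth-record data.frame (one scope; replicate-level records
#'   are reduced to the per-MAG majority growth class, ties to the mean-mu
#'   sign).
#' @param de Differential-expression results from [de_test()] with influent
#'   as group A and reactor as group B.
#' @param mag_subset Optional MAG ids (e.g. from [filter_mags()]) to restrict
#'   the classification to.
#' @return A list with `quadrants` (data.frame `growth_class`,
#'   `activity_class`, `tier`, `n`), `totals` (2x2 sign-only table) and
#'   `n_classified`.
#' @export
classify_quadrants <- function(growth, de, mag_subset = NULL) {
  cons <- consensus_growth(growth)
  df <- merge(cons, de[, c("mag_id", "log2fc", "p_value", "tier")],
              by = "mag_id")
  if (!is.null(mag_subset)) df <- df[df$mag_id %in% mag_subset, , drop = FALSE]
  df <- df[df$growth_class %in% c("positive", "negative"), , drop = FALSE]
  df$activity_class <- ifelse(df$log2fc > 0, "active", "inactive")
  grid <- expand.grid(growth_class = c("positive", "negative"),
                      activity_class = c("active", "inactive"),
                      tier = c("NS", "fc_only", "p_only", "both"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(g, a, t)
    sum(df$growth_class == g & df$activity_class == a & df$tier == t),
    grid$growth_class, grid$activity_class, grid$tier)
  totals <- table(factor(df$growth_class, c("positive", "negative")),
                  factor(df$activity_class, c("active", "inactive")))
  list(quadrants = grid, totals = totals, n_classified = nrow(df))
}

# Per-MAG consensus over replicates: majority growth class, mean mu/theta.
consensus_growth <- function(growth) {
  sp <- split(growth, growth$mag_id)
  out <- lapply(sp, function(g) {
    cls <- g$growth_class[g$growth_class %in% c("positive", "negative", "zero")]
    mu <- mean(g$mu_per_day, na.rm = TRUE)
    cons <- if (!length(cls)) "undefined" else {
      tab <- sort(table(cls), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) {
        if (is.nan(mu) || mu == 0) "zero" else if (mu > 0) "positive" else "negative"
      } else names(tab)[1]
    }
    data.frame(mag_id = g$mag_id[1], growth_class = cons,
               mu_mean = mu, theta_mean = mean(g$theta_days, na.rm = TRUE),
               dominance = g$dominance[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write activity records to TSV
#'
#' @param activity Data.frame from [classify_relative_activity()], optionally
#'   merged with DE results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_records <- function(activity, path) {
  utils::write.table(activity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
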