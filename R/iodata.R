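#' Sample keys
#'
#' Samples are addressed by a dot-separated, case-insensitive key
#' `compartment[.class][.phase].repN`:
#' compartment is one of `influent`, `AGS`, `effluent`, `excess_sludge`;
#' the aggregate class (`FL`, `SG`, `LG`, or `mixed` for the reconstructed
#' whole-reactor profile) is only valid for AGS and excess-sludge samples;
#' the cycle phase (`aerobic`/`anaerobic`) only for AGS metatranscriptomic
#' samples; `repN` is the replicate index (weekly sampling, replicates are
#' paired across compartments by index).
#'
#' @param keys Character vector of sample-key strings.
#' @return A data.frame with columns `compartment`, `aggregate_class`,
#'   `phase`, `replicate` (one row per key).
#' @examples
#' parse_sample_keys(c("influent.rep1", "AGS.FL.anaerobic.rep2"))
#' @export
parse_sample_keys <- function(keys) {
  comps <- c("influent", "ags", "effluent", "excess_sludge")
  out <- lapply(keys, function(k) {
    toks <- strsplit(tolower(k), ".", fixed = TRUE)[[1]]
    if (length(toks) < 2L)
      stop(sprintf("malformed sample key '%s': expected compartment[.class][.phase].repN", k),
           call. = FALSE)
    comp <- toks[1]
    if (!comp %in% comps)
      stop(sprintf("malformed sample key '%s': unknown compartment '%s'", k, toks[1]),
           call. = FALSE)
    last <- toks[length(toks)]
    if (!grepl("^rep[0-9]+$", last))
      stop(sprintf("malformed sample key '%s': last token '%s' is not repN", k, last),
           call. = FALSE)
    rep <- as.integer(sub("^rep", "", last))
    if (rep < 1L)
      stop(sprintf("malformed sample key '%s': replicate must be >= 1", k),
           call. = FALSE)
    mid <- toks[-c(1, length(toks))]
    cls <- "none"; phase <- "none"
    for (tok in mid) {
      if (tok %in% c("fl", "sg", "lg", "mixed")) {
        cls <- toupper(tok)
        if (tok == "mixed") cls <- "mixed"
      } else if (tok %in% c("aerobic", "anaerobic")) {
        phase <- tok
      } else {
        stop(sprintf("malformed sample key '%s': unknown token '%s'", k, tok),
             call. = FALSE)
      }
    }
    comp <- switch(comp, ags = "AGS", comp)
    if (cls != "none" && !comp %in% c("AGS", "excess_sludge"))
      stop(sprintf("sample key '%s': aggregate class is only valid for AGS/excess_sludge samples", k),
           call. = FALSE)
    if (phase != "none" && comp != "AGS")
      stop(sprintf("sample key '%s': phase is only valid for AGS samples", k),
           call. = FALSE)
    data.frame(compartment = comp, aggregate_class = cls, phase = phase,
               replicate = rep, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname parse_sample_keys
#' @param keydf A data.frame as returned by `parse_sample_keys()`.
#' @export
format_sample_keys <- function(keydf) {
  vapply(seq_len(nrow(keydf)), function(i) {
    toks <- keydf$compartment[i]
    if (keydf$aggregate_class[i] != "none")
      toks <- c(toks, keydf$aggregate_class[i])
    if (keydf$phase[i] != "none")
      toks <- c(toks, keydf$phase[i])
    paste(c(toks, paste0("rep", keydf$replicate[i])), collapse = ".")
  }, character(1))
}

#' Construct a profile matrix
#'
#' A `profile_matrix` holds MAG-by-sample relative abundances (metagenomics)
#' or relative expressions (metatranscriptomics) as fractions of total reads
#' in `[0, 1]`. Column sums below 1 reflect unmapped reads; the per-column sum
#' is retained as `mapped_fraction`.
#'
#' @param values Numeric matrix, MAGs in rows, samples in columns; fractions
#'   of total reads.
#' @param keys Sample keys: a character vector of key strings or a data.frame
#'   from [parse_sample_keys()], one entry per column.
#' @param kind `"metagenomics"` or `"metatranscriptomics"`.
#' @param mapped_fraction Optional per-column mapped-read fraction; defaults
#'   to the column sums.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, keys,
                           kind = c("metagenomics", "metatranscriptomics"),
                           mapped_fraction = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("'values' must have MAG ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate MAG ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0))
    stop("profile values must be non-negative", call. = FALSE)
  cs <- colSums(values)
  if (any(cs > 1 + 1e-9))
    stop("column(s) sum to more than 100%: ",
         paste(which(cs > 1 + 1e-9), collapse = ", "), call. = FALSE)
  if (is.character(keys)) keys <- parse_sample_keys(keys)
  if (nrow(keys) != ncol(values))
    stop("number of sample keys must match number of columns", call. = FALSE)
  colnames(values) <- format_sample_keys(keys)
  if (is.null(mapped_fraction)) mapped_fraction <- cs
  structure(list(values = values, keys = keys, kind = kind,
                 mapped_fraction = unname(mapped_fraction)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix (%s): %d MAGs x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  mapped fraction: %.1f%% (mean)\n",
              100 * mean(x$mapped_fraction)))
  tab <- table(x$keys$compartment)
  cat("  samples:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' MAG ids of a profile matrix
#' @param x A `profile_matrix`.
#' @return Character vector of MAG identifiers.
#' @export
mag_ids <- function(x) rownames(x$values)

#' Read a MAG-by-sample profile table
#'
#' Reads a TSV whose first column holds MAG ids and whose remaining column
#' names encode sample keys (see [parse_sample_keys()]); values are percent
#' of total reads (0-100, CoverM-style output) and are converted to fractions
#' internally.
#'
#' @param path Path to the TSV file.
#' @param kind `"metagenomics"` or `"metatranscriptomics"`.
#' @return A [profile_matrix].
#' @export
read_profile_table <- function(path,
                               kind = c("metagenomics", "metatranscriptomics")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("profile table needs a MAG id column plus at least one sample column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("profile table contains non-numeric values", call. = FALSE)
  rownames(vals) <- ids
  if (any(vals < 0))
    stop("negative value(s) in profile table", call. = FALSE)
  cs <- colSums(vals)
  bad <- cs > 100 + 1e-7
  if (any(bad))
    stop("column(s) sum to more than 100%: ",
         paste(colnames(vals)[bad], collapse = ", "), call. = FALSE)
  profile_matrix(vals / 100, colnames(vals), kind = kind)
}

#' Write a profile table
#'
#' Inverse of [read_profile_table()]: fractions are written back as percent.
#'
#' @param x A [profile_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  stopifnot(inherits(x, "profile_matrix"))
  df <- data.frame(mag_id = rownames(x$values),
                   100 * x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize a profile to mapped reads
#'
#' Divides each column by its mapped-read fraction so that columns sum to 1.
#' Reported relative abundances are fractions of *total* reads by default
#' (unmapped included); this converts them to fractions of mapped reads.
#'
#' @param x A [profile_matrix].
#' @return A [profile_matrix] with unit column sums.
#' @export
renormalize_to_mapped <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  mf <- x$mapped_fraction
  if (any(mf <= 0))
    stop("cannot renormalize: column(s) with zero mapped fraction",
         call. = FALSE)
  profile_matrix(sweep(x$values, 2, mf, "/"), x$keys, kind = x$kind,
                 mapped_fraction = rep(1, length(mf)))
}

#' Select profile columns by sample-key fields
#'
#' @param x A [profile_matrix].
#' @param compartment,aggregate_class,phase,replicate Optional filters; `NULL`
#'   leaves the field unrestricted.
#' @return Integer vector of matching column indices.
#' @export
profile_columns <- function(x, compartment = NULL, aggregate_class = NULL,
                            phase = NULL, replicate = NULL) {
  keep <- rep(TRUE, nrow(x$keys))
  if (!is.null(compartment))
    keep <- keep & x$keys$compartment %in% compartment
  if (!is.null(aggregate_class))
    keep <- keep & x$keys$aggregate_class %in% aggregate_class
  if (!is.null(phase)) keep <- keep & x$keys$phase %in% phase
  if (!is.null(replicate)) keep <- keep & x$keys$replicate %in% replicate
  which(keep)
}

#' Read a MAG metadata table
#'
#' TSV with columns `mag_id`, `taxonomy`, `completeness`, `contamination`
#' and optionally `guild`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_mag_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mag_id", "completeness", "contamination")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MAG metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$completeness < 0 | df$completeness > 100))
    stop("completeness must be in [0, 100]", call. = FALSE)
  if (any(df$contamination < 0))
    stop("contamination must be >= 0", call. = FALSE)
  df
}

#' Filter MAGs on genome quality
#'
#' Keeps MAGs with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (both percent). The
#' defaults, >50% complete and <10% contaminated, are the MIMAG-style
#' thresholds applied before activity classification.
#'
#' @param meta MAG metadata data.frame (see [read_mag_metadata()]).
#' @param min_completeness,max_contamination Percent thresholds in `[0, 100]`.
#' @return Character vector of retained MAG ids.
#' @export
filter_mags <- function(meta, min_completeness = 50, max_contamination = 10) {
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_contamination >= 0, max_contamination <= 100)
  meta$mag_id[meta$completeness > min_completeness &
                meta$contamination < max_contamination]
}
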