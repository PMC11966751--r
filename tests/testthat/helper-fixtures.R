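# Shared fixtures: tiny hand-built profile matrices and plants.

paper_plant <- function() example_plant()

# Equal-aggregate plant for symmetry checks.
uniform_plant <- function() {
  f <- c(FL = 1, SG = 1, LG = 1) / 3
  plant_parameters(M_AGS = 55972, J_ES = 2177, J_EF = 1256, J_WW = 4122.5,
                   mlss_fractions = f, es_fractions = f, ef_fractions = f)
}

# Profile matrix from a named list of columns (fractions).
make_profile <- function(cols, mag_names, kind = "metagenomics") {
  m <- do.call(cbind, cols)
  rownames(m) <- mag_names
  profile_matrix(m, names(cols), kind = kind)
}

# One-replicate whole-system profile with explicit compartment fractions.
whole_profile <- function(p_ww, p_ags, p_es, p_ef, mag_names,
                          kind = "metagenomics", replicate = 1) {
  cols <- list(p_ww, p_ags, p_es, p_ef)
  names(cols) <- sprintf(c("influent.rep%d", "AGS.mixed.rep%d",
                           "excess_sludge.rep%d", "effluent.rep%d"),
                         replicate)
  make_profile(cols, mag_names, kind)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
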