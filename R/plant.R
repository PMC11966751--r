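#' Plant design and operational parameters
#'
#' Container for the total suspended solids (TSS) biomass inventory and daily
#' biomass fluxes of an aerobic granular sludge (AGS) plant, together with the
#' aggregate-size composition of the reactor biomass (MLSS), the excess sludge
#' and the effluent. All mass-balance calculations take a `plant_parameters`
#' object.
#'
#' @param M_AGS Total TSS biomass held in the AGS reactor, kg.
#' @param J_ES Daily TSS biomass discharged with the excess sludge, kg/d.
#' @param J_EF Daily TSS biomass escaping with the effluent, kg/d.
#' @param J_WW Daily TSS biomass load entering with the influent, kg/d.
#' @param mlss_fractions Named numeric vector `c(FL=, SG=, LG=)` giving the
#'   mass fraction of reactor biomass in flocs (FL, <0.2 mm), small granules
#'   (SG, 0.2-1 mm) and large granules (LG, >1 mm). Must sum to 1.
#' @param es_fractions Aggregate-class mass fractions of the excess sludge;
#'   same format, must sum to 1.
#' @param ef_fractions Aggregate-class mass fractions of the effluent biomass.
#'   Defaults to `c(FL=1, SG=0, LG=0)`: effluent losses are flocs, which wash
#'   out far more easily than granules.
#' @return An object of class `plant_parameters`.
#' @seealso [read_plant_config()], [example_plant()]
#' @export
plant_parameters <- function(M_AGS, J_ES, J_EF, J_WW,
                             mlss_fractions, es_fractions,
                             ef_fractions = c(FL = 1, SG = 0, LG = 0)) {
  for (nm in c("M_AGS", "J_ES", "J_EF", "J_WW")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  mlss_fractions <- check_fraction_map(mlss_fractions, "mlss_fractions")
  es_fractions <- check_fraction_map(es_fractions, "es_fractions")
  ef_fractions <- check_fraction_map(ef_fractions, "ef_fractions")
  structure(
    list(M_AGS = M_AGS, J_ES = J_ES, J_EF = J_EF, J_WW = J_WW,
         mlss_fractions = mlss_fractions,
         es_fractions = es_fractions,
         ef_fractions = ef_fractions),
    class = "plant_parameters")
}

AGG_CLASSES <- c("FL", "SG", "LG")

check_fraction_map <- function(x, what) {
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x) || is.null(names(x)))
    stop(sprintf("'%s' must be a named numeric vector", what), call. = FALSE)
  names(x) <- toupper(names(x))
  if (!setequal(names(x), AGG_CLASSES))
    stop(sprintf("'%s' must have exactly the names FL, SG, LG", what),
         call. = FALSE)
  x <- x[AGG_CLASSES]
  if (any(x < 0))
    stop(sprintf("'%s' has negative entries", what), call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9)
    stop(sprintf("'%s' must sum to 1 (got %.12g)", what, sum(x)),
         call. = FALSE)
  x
}

#' @export
print.plant_parameters <- function(x, ...) {
  cat("AGS plant parameters\n")
  cat(sprintf("  reactor biomass M_AGS : %12.1f kg TSS\n", x$M_AGS))
  cat(sprintf("  excess sludge  J_ES   : %12.1f kg TSS/d\n", x$J_ES))
  cat(sprintf("  effluent       J_EF   : %12.1f kg TSS/d\n", x$J_EF))
  cat(sprintf("  influent load  J_WW   : %12.1f kg TSS/d\n", x$J_WW))
  fm <- function(f) paste(sprintf("%s %.1f%%", names(f), 100 * f),
                          collapse = ", ")
  cat("  MLSS fractions  :", fm(x$mlss_fractions), "\n")
  cat("  ES fractions    :", fm(x$es_fractions), "\n")
  cat("  EF fractions    :", fm(x$ef_fractions), "\n")
  invisible(x)
}

#' Parameters of the studied full-scale AGS plant
#'
#' The design and operational figures of the full-scale municipal AGS plant
#' used throughout the examples: 55,972 kg TSS reactor inventory, 2177 kg/d
#' wasted as excess sludge, 1256 kg/d lost with the effluent and 4122.5 kg/d
#' entering with the influent; well-mixed MLSS composed of 25% flocs, 53%
#' small granules and 22% large granules, excess sludge of 50% FL / 45% SG /
#' 5% LG, and effluent biomass taken as flocs only.
#'
#' @return A [plant_parameters] object.
#' @export
example_plant <- function() {
  plant_parameters(
    M_AGS = 55972, J_ES = 2177, J_EF = 1256, J_WW = 4122.5,
    mlss_fractions = c(FL = 0.25, SG = 0.53, LG = 0.22),
    es_fractions = c(FL = 0.50, SG = 0.45, LG = 0.05))
}

#' Read a plant configuration file
#'
#' Reads a YAML plant description with keys `M_AGS`, `J_ES`, `J_EF`, `J_WW`,
#' `mlss_fractions`, `es_fractions` and optionally `ef_fractions` (defaulting
#' to flocs-only effluent) and validates it.
#'
#' @param path Path to the YAML file.
#' @return A [plant_parameters] object.
#' @export
read_plant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("M_AGS", "J_ES", "J_EF", "J_WW", "mlss_fractions", "es_fractions")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("plant config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ef <- cfg$ef_fractions
  if (is.null(ef)) ef <- c(FL = 1, SG = 0, LG = 0)
  plant_parameters(M_AGS = cfg$M_AGS, J_ES = cfg$J_ES, J_EF = cfg$J_EF,
                   J_WW = cfg$J_WW,
                   mlss_fractions = cfg$mlss_fractions,
                   es_fractions = cfg$es_fractions,
                   ef_fractions = ef)
}

#' Write a plant configuration file
#'
#' @param plant A [plant_parameters] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_plant_config <- function(plant, path) {
  stopifnot(inherits(plant, "plant_parameters"))
  yaml::write_yaml(list(
    M_AGS = plant$M_AGS, J_ES = plant$J_ES, J_EF = plant$J_EF,
    J_WW = plant$J_WW,
    mlss_fractions = as.list(plant$mlss_fractions),
    es_fractions = as.list(plant$es_fractions),
    ef_fractions = as.list(plant$ef_fractions)), path)
  invisible(path)
}

#' Daily influent biomass load relative to the reactor inventory
#'
#' The daily TSS biomass transported from the influent into the AGS system,
#' expressed as a percentage of the total reactor biomass:
#' `100 * J_WW / M_AGS`. For the studied plant this is about 7.5% per day
#' (to the nearest 0.5%), the gross upper bound on how much of the standing
#' biomass immigration could replace daily.
#'
#' @param plant A [plant_parameters] object.
#' @return Percent per day (numeric scalar).
#' @export
daily_load_ratio <- function(plant) {
  stopifnot(inherits(plant, "plant_parameters"))
  100 * plant$J_WW / plant$M_AGS
}

#' Round a percentage to the nearest half percent
#'
#' @param x Numeric.
#' @return `x` rounded to the nearest 0.5.
#' @export
round_half_percent <- function(x) round(x * 2) / 2
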