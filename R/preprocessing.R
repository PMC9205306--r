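#' Derive the ten functional traits from per-seedling organ measurements
#'
#' Computes, per seedling, the standard leaf/stem/root traits from raw organ
#' measurements and averages them to species means:
#' \itemize{
#'   \item `SLA` = leaf area / leaf dry weight (cm^2 g^-1)
#'   \item `MPU` = area of the minimum photosynthetic unit, given directly
#'         (leaf area if entire, leaflet area if compound) (cm^2)
#'   \item `LTh` = leaf thickness, given directly (mm)
#'   \item `LWC` = (leaf wet weight - dry weight) / dry weight (g g^-1)
#'   \item `WD`  = wood dry weight / wet volume (g cm^-3)
#'   \item `SWC` = (stem wet weight - dry weight) / dry weight (g g^-1)
#'   \item `SRL` = root length / root dry weight (m g^-1)
#'   \item `MRD` = maximum root depth, given directly (cm)
#'   \item `RTh` = average root diameter, given directly (cm)
#'   \item `RD`  = root dry weight / wet volume (g cm^-3)
#' }
#' Total biomass is the summed dry mass of leaves, stem and roots (or the
#' `biomass` column when supplied). Zero dry weights or volumes make the
#' corresponding trait undefined: the cell is recorded missing with a
#' warning. A dry weight exceeding its wet weight is tolerated but flagged
#' with a warning.
#'
#' @param raw data.frame of per-seedling measurements with columns
#'   `species_id` and any of `leaf_area`, `leaf_dry_weight`,
#'   `leaf_wet_weight`, `leaf_thickness`, `mpu_area`, `wood_dry_weight`,
#'   `wood_wet_volume`, `stem_dry_weight`, `stem_wet_weight`, `root_length`,
#'   `root_dry_weight`, `root_wet_volume`, `root_diameter`,
#'   `max_root_depth`, optionally `biomass`, `site`.
#' @param site optional site label.
#' @return A [trait_table()] of species means (traits present in `raw`
#'   only), with biomass when derivable.
#' @export
derive_traits <- function(raw, site = NULL) {
  if (!"species_id" %in% names(raw)) stop("raw data needs a 'species_id' column")
  num <- setdiff(names(raw), c("species_id", "site"))
  for (v in num) {
    if (any(raw[[v]] < 0, na.rm = TRUE))
      stop("negative measurement in column '", v, "'")
  }
  if (is.null(site)) site <- if ("site" %in% names(raw)) raw$site[1] else NA_character_

  safe_div <- function(a, b, what) {
    bad <- !is.na(b) & b == 0
    if (any(bad)) {
      warning("zero denominator for ", what, " in ", sum(bad),
              " seedling(s); recorded missing")
      b[bad] <- NA_real_
    }
    a / b
  }
  flag_wet_dry <- function(wet, dry, what) {
    bad <- !is.na(wet) & !is.na(dry) & dry > wet
    if (any(bad))
      warning("dry weight exceeds wet weight for ", what, " in ",
              sum(bad), " seedling(s)")
  }

  col <- function(v) if (v %in% names(raw)) raw[[v]] else NULL
  tr <- list()
  if (!is.null(col("leaf_area")) && !is.null(col("leaf_dry_weight")))
    tr$SLA <- safe_div(raw$leaf_area, raw$leaf_dry_weight, "SLA")
  if (!is.null(col("mpu_area"))) tr$MPU <- raw$mpu_area
  if (!is.null(col("leaf_thickness"))) tr$LTh <- raw$leaf_thickness
  if (!is.null(col("leaf_wet_weight")) && !is.null(col("leaf_dry_weight"))) {
    flag_wet_dry(raw$leaf_wet_weight, raw$leaf_dry_weight, "leaves")
    tr$LWC <- safe_div(raw$leaf_wet_weight - raw$leaf_dry_weight,
                       raw$leaf_dry_weight, "LWC")
  }
  if (!is.null(col("wood_dry_weight")) && !is.null(col("wood_wet_volume")))
    tr$WD <- safe_div(raw$wood_dry_weight, raw$wood_wet_volume, "WD")
  if (!is.null(col("stem_wet_weight")) && !is.null(col("stem_dry_weight"))) {
    flag_wet_dry(raw$stem_wet_weight, raw$stem_dry_weight, "stems")
    tr$SWC <- safe_div(raw$stem_wet_weight - raw$stem_dry_weight,
                       raw$stem_dry_weight, "SWC")
  }
  if (!is.null(col("root_length")) && !is.null(col("root_dry_weight")))
    tr$SRL <- safe_div(raw$root_length, raw$root_dry_weight, "SRL")
  if (!is.null(col("max_root_depth"))) tr$MRD <- raw$max_root_depth
  if (!is.null(col("root_diameter"))) tr$RTh <- raw$root_diameter
  if (!is.null(col("root_dry_weight")) && !is.null(col("root_wet_volume")))
    tr$RD <- safe_div(raw$root_dry_weight, raw$root_wet_volume, "RD")
  if (!length(tr)) stop("no derivable trait found in raw data")

  per_seedling <- as.data.frame(tr)
  biomass_seedling <- if (!is.null(col("biomass"))) raw$biomass else {
    parts <- c("leaf_dry_weight", "stem_dry_weight", "root_dry_weight")
    if (all(parts %in% names(raw)))
      raw$leaf_dry_weight + raw$stem_dry_weight + raw$root_dry_weight
    else NULL
  }

  sp <- sort(unique(as.character(raw$species_id)))
  agg <- function(v) {
    out <- tapply(v, raw$species_id, mean, na.rm = TRUE)[sp]
    out[is.nan(out)] <- NA_real_
    out
  }
  values <- vapply(per_seedling, agg, numeric(length(sp)))
  rownames(values) <- sp
  biomass <- if (is.null(biomass_seedling)) NULL else agg(biomass_seedling)
  trait_table(values, site = site, biomass = biomass)
}

#' Log10-transform a configured list of traits, with an advisory normality
#' report
#'
#' Replaces the listed trait columns by their `log10` values and reports a
#' Shapiro-Wilk statistic and p-value per trait before and after. The report
#' is advisory only: the transform list (configured per site, since the
#' hand-picked exceptions differ between forests) decides what is
#' transformed, not the test.
#'
#' @param table a [trait_table()] whose listed columns are still `"raw"`.
#' @param transform_list character vector of trait names to log10-transform
#'   (may be empty).
#' @return The transformed `trait_table`, with a `normality` attribute: a
#'   data.frame of Shapiro-Wilk `W` and `p` before/after per trait.
#' @export
log_transform <- function(table, transform_list = character()) {
  stopifnot(inherits(table, "trait_table"))
  unknown <- setdiff(transform_list, traits(table))
  if (length(unknown)) stop("unknown traits: ", paste(unknown, collapse = ", "))
  done <- transform_list[table$state[transform_list] != "raw"]
  if (length(done))
    stop("already processed, refusing to transform again: ",
         paste(done, collapse = ", "))
  sw <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || length(unique(v)) < 2) return(c(NA_real_, NA_real_))
    s <- stats::shapiro.test(v)
    c(unname(s$statistic), s$p.value)
  }
  before <- t(vapply(as.data.frame(table$values), sw, numeric(2)))
  for (tn in transform_list) {
    v <- table$values[, tn]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("non-positive value(s) in trait '", tn, "' for species: ",
           paste(table$species_id[bad], collapse = ", "))
    table$values[, tn] <- log10(v)
    table$state[tn] <- "log10"
  }
  after <- t(vapply(as.data.frame(table$values), sw, numeric(2)))
  attr(table, "normality") <- data.frame(
    trait = traits(table),
    W_before = before[, 1], p_before = before[, 2],
    W_after = after[, 1], p_after = after[, 2],
    transformed = traits(table) %in% transform_list,
    row.names = NULL)
  table
}

#' Remove plant-size effects by residualising traits on biomass
#'
#' Regresses each trait on `log10(total biomass)` (ordinary least squares;
#' set `regressor = "raw"` to use untransformed biomass) and, wherever the
#' slope is significant at `alpha`, replaces the column by the regression
#' residuals so that downstream correlations are not driven by plant size.
#' Species lacking biomass are excluded pairwise (their residual is `NA`).
#'
#' @param table a [trait_table()] with biomass present.
#' @param alpha significance level for the slope test (default 0.05).
#' @param regressor `"log10"` (default, allometric convention) or `"raw"`.
#' @return The corrected `trait_table`; its `size_correction` attribute is a
#'   data.frame with per-trait slope, intercept, p-value and decision
#'   (`"residualized"` or `"kept"`, `"skipped"` when fewer than 3 complete
#'   pairs exist).
#' @export
size_correct <- function(table, alpha = 0.05, regressor = c("log10", "raw")) {
  stopifnot(inherits(table, "trait_table"))
  regressor <- match.arg(regressor)
  if (is.null(table$biomass)) stop("table has no biomass column")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (any(table$state == "residual"))
    stop("already processed, refusing to residualize again: ",
         paste(traits(table)[table$state == "residual"], collapse = ", "))
  b <- if (regressor == "log10") log10(table$biomass) else table$biomass
  rep_rows <- lapply(traits(table), function(tn) {
    y <- table$values[, tn]
    ok <- !is.na(y) & !is.na(b)
    if (sum(ok) < 3) {
      warning("fewer than 3 complete pairs for trait '", tn, "'; skipped")
      return(data.frame(trait = tn, n = sum(ok), slope = NA_real_,
                        intercept = NA_real_, p = NA_real_,
                        decision = "skipped"))
    }
    fit <- stats::lm(y[ok] ~ b[ok])
    co <- summary(fit)$coefficients
    p <- co[2, "Pr(>|t|)"]
    data.frame(trait = tn, n = sum(ok), slope = co[2, 1],
               intercept = co[1, 1], p = p,
               decision = if (p < alpha) "residualized" else "kept")
  })
  report <- do.call(rbind, rep_rows)
  for (i in seq_len(nrow(report))) {
    if (report$decision[i] != "residualized") next
    tn <- report$trait[i]
    y <- table$values[, tn]
    ok <- !is.na(y) & !is.na(b)
    res <- rep(NA_real_, length(y))
    res[ok] <- stats::residuals(stats::lm(y[ok] ~ b[ok]))
    table$values[, tn] <- res
    table$state[tn] <- "residual"
  }
  attr(table, "size_correction") <- report
  table
}
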