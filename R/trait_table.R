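#' Species-by-trait table of species means
#'
#' The central data container of the pipeline: a numeric matrix of
#' species-mean trait values (rows = species, columns = traits), an optional
#' per-species total dry biomass (g), a site label, and a per-column state
#' flag recording whether a column currently holds raw values, log10 values,
#' or residuals from the size correction. The state flag is what lets
#' [log_transform()] and [size_correct()] refuse to run twice on the same
#' column.
#'
#' @param values numeric matrix, species x traits; `NA` marks missing cells.
#'   Must have column names (trait names); row names are taken as species
#'   ids when `species_id` is not given.
#' @param species_id character vector of unique species identifiers.
#' @param site single character site label.
#' @param biomass optional numeric vector of per-species total dry mass (g),
#'   same length/order as `species_id`.
#' @param state optional character vector per trait, each one of
#'   `"raw"`, `"log10"`, `"residual"`; defaults to `"raw"`.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values, species_id = rownames(values),
                        site = NA_character_, biomass = NULL,
                        state = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("trait columns must be named")
  if (is.null(species_id)) stop("species identifiers are required")
  species_id <- as.character(species_id)
  if (anyDuplicated(species_id)) stop("species identifiers must be unique")
  if (length(species_id) != nrow(values))
    stop("species_id length does not match number of rows")
  rownames(values) <- species_id
  if (!is.null(biomass)) {
    biomass <- stats::setNames(as.numeric(biomass), species_id)
    if (length(biomass) != nrow(values))
      stop("biomass length does not match number of species")
    if (any(biomass[!is.na(biomass)] <= 0))
      stop("biomass must be positive")
  }
  if (is.null(state)) state <- rep("raw", ncol(values))
  if (length(state) != ncol(values) ||
      !all(state %in% c("raw", "log10", "residual")))
    stop("state must be one of 'raw', 'log10', 'residual' per trait")
  names(state) <- colnames(values)
  structure(
    list(values = values, species_id = species_id,
         site = as.character(site), biomass = biomass, state = state),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species x %d traits (site: %s)\n",
              nrow(x$values), ncol(x$values), x$site))
  cat("traits:", paste(sprintf("%s[%s]", colnames(x$values),
                               substr(x$state, 1, 3)), collapse = " "), "\n")
  cat(sprintf("biomass: %s; missing cells: %d\n",
              if (is.null(x$biomass)) "absent" else "present",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' @rdname trait_table
#' @param x a `trait_table`.
#' @export
traits <- function(x) colnames(x$values)

#' Read / write trait tables as CSV
#'
#' The on-disk format is one row per species with columns `species_id`,
#' `site`, `biomass` (blank when absent) and one column per trait; empty
#' cells denote missing values.
#'
#' @param path file path.
#' @param site optional site label overriding the file's `site` column.
#' @param biomass_col name of the biomass column, default `"biomass"`.
#' @return `read_trait_table()` returns a `trait_table`;
#'   `write_trait_table()` returns `path` invisibly.
#' @export
read_trait_table <- function(path, site = NULL, biomass_col = "biomass") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species_id" %in% names(df)) stop("missing 'species_id' column in ", path)
  if (is.null(site)) site <- if ("site" %in% names(df)) df$site[1] else NA_character_
  meta <- intersect(c("species_id", "site", biomass_col), names(df))
  trait_cols <- setdiff(names(df), meta)
  values <- as.matrix(df[, trait_cols, drop = FALSE])
  storage.mode(values) <- "double"
  biomass <- if (biomass_col %in% names(df)) as.numeric(df[[biomass_col]]) else NULL
  trait_table(values, species_id = df$species_id, site = site, biomass = biomass)
}

#' @rdname read_trait_table
#' @param table a `trait_table`.
#' @export
write_trait_table <- function(table, path) {
  df <- data.frame(species_id = table$species_id,
                   site = table$site,
                   biomass = if (is.null(table$biomass)) NA_real_ else table$biomass,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
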