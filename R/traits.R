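# Trait-table ingestion, region assignment, response handling and
# predictor standardisation.

# canonical column names; a column_map may rename user columns onto these
.trait_columns <- c("taxon_id", "species", "genus", "region", "decline",
                    "range_km2", "rainfall_mm", "female_mass_g",
                    "habitat_openness", "litter_size", "centroid_latitude")
.required_predictors <- c("range_km2", "rainfall_mm", "female_mass_g",
                          "habitat_openness", "litter_size")

#' Latitude of the Tropic of Capricorn (degrees)
#'
#' Default boundary between the northern (tropical) and southern (temperate
#' and arid) regions when regions are assigned from range-centroid latitude.
#' @export
TROPIC_OF_CAPRICORN <- -23.43665

#' Read a trait table
#'
#' Reads a delimited (or, when \pkg{readxl} is installed, an xlsx) table of
#' one row per analysis taxon: a species-by-region population with its
#' proportional range decline in [0, 1] and the ecological/life-history
#' predictors. Rows missing any required predictor are dropped and their
#' taxon ids reported via \code{message()}.
#'
#' Required columns (after \code{column_map} renaming): \code{species},
#' \code{decline}, the five predictors \code{range_km2}, \code{rainfall_mm},
#' \code{female_mass_g}, \code{habitat_openness}, \code{litter_size}, and
#' either \code{region} (\code{"north"}/\code{"south"}) or
#' \code{centroid_latitude} (decimal degrees, negative south). Optional:
#' \code{taxon_id} (defaults to species, suffixed with the region for
#' species present in both), \code{genus} (defaults to the first word of
#' \code{species}), and any extra trait columns, which are kept.
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"csv"} or \code{"xlsx"}.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. \code{c(decline = "prop.decline")}.
#' @return a data.frame of class \code{"trait_table"} with attribute
#'   \code{provenance} (the source path).
#' @export
read_trait_table <- function(path, format = c("auto", "csv", "xlsx"),
                             column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  df <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  as_trait_table(df, provenance = path)
}

#' Coerce a data.frame to a trait table
#'
#' Performs the validation and defaulting described in
#' [read_trait_table()].
#'
#' @param df a data.frame.
#' @param provenance source label stored as an attribute.
#' @return a \code{"trait_table"}.
#' @export
as_trait_table <- function(df, provenance = "in-memory") {
  need <- c("species", "decline", .required_predictors)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!("region" %in% names(df)) && !("centroid_latitude" %in% names(df)))
    stop("need either a 'region' or a 'centroid_latitude' column")
  if (!("region" %in% names(df)))
    df$region <- assign_region(df$centroid_latitude)
  df$region <- tolower(as.character(df$region))
  if (!all(df$region %in% c("north", "south")))
    stop("region must be 'north' or 'south'")
  if (!("genus" %in% names(df)))
    df$genus <- vapply(strsplit(df$species, "[ _]"), `[`, "", 1L)
  if (!("taxon_id" %in% names(df))) {
    dup <- df$species %in% df$species[duplicated(df$species)]
    df$taxon_id <- ifelse(dup, paste(df$species, df$region, sep = "_"),
                          df$species)
  }
  bad <- which(!is.na(df$decline) & (df$decline < 0 | df$decline > 1))
  if (length(bad))
    stop("decline outside [0, 1] in row(s): ", paste(bad, collapse = ", "),
         " (", paste(df$taxon_id[bad], collapse = ", "), ")")
  if (any(!df$habitat_openness %in% c(0:4, NA)))
    stop("habitat_openness must be a rank in 0..4")
  incomplete <- !stats::complete.cases(
    df[, c("decline", .required_predictors)])
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " row(s) with missing required values: ",
            paste(df$taxon_id[incomplete], collapse = ", "))
    df <- df[!incomplete, , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete rows")
  if (anyDuplicated(df$taxon_id))
    stop("taxon_id not unique: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("trait_table", "data.frame"))
}

#' Assign region from range-centroid latitude
#'
#' North of the Tropic of Capricorn is \code{"north"}; a centroid exactly on
#' the line is \code{"south"} ("north of the Tropic" read strictly).
#'
#' @param latitude numeric vector of decimal degrees (southern hemisphere
#'   negative).
#' @param tropic_latitude the boundary, default [TROPIC_OF_CAPRICORN].
#' @return character vector of \code{"north"}/\code{"south"}.
#' @export
assign_region <- function(latitude, tropic_latitude = TROPIC_OF_CAPRICORN) {
  if (any(is.na(latitude))) stop("latitude missing and no region given")
  ifelse(latitude > tropic_latitude, "north", "south")
}

#' Categorise proportional declines
#'
#' Partitions [0, 1] as: \code{None} (y = 0), \code{Low} (0 < y <= 0.25),
#' \code{Moderate} (0.25 < y <= 0.50), \code{High} (y > 0.50).
#'
#' @param y proportional declines in [0, 1].
#' @return a factor with levels \code{None, Low, Moderate, High}.
#' @export
categorize_decline <- function(y) {
  if (any(is.na(y) | y < 0 | y > 1)) stop("decline must lie in [0, 1]")
  cut(y, breaks = c(-Inf, 0, 0.25, 0.50, 1),
      labels = c("None", "Low", "Moderate", "High"), right = TRUE)
}

#' Compress proportions into the open unit interval
#'
#' The beta likelihood has support (0, 1), but observed proportional declines
#' include exact zeros (stable species) and can include ones (extirpation).
#' The standard compression \code{y' = (y * (n - 1) + 0.5) / n} (Smithson &
#' Verkuilen) maps [0, 1] strictly inside (0, 1), preserving order; its
#' inverse is [unsqueeze_response()].
#'
#' @param y proportions in [0, 1].
#' @param n number of analysis taxa (default \code{length(y)}); must be >= 2.
#' @return compressed proportions strictly inside (0, 1).
#' @export
squeeze_response <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  if (n < 2) stop("n must be >= 2")
  (y * (n - 1) + 0.5) / n
}

#' @rdname squeeze_response
#' @param y_squeezed previously compressed values.
#' @export
unsqueeze_response <- function(y_squeezed, n) {
  (y_squeezed * n - 0.5) / (n - 1)
}

# Standardise the model predictors of a trait table (no response handling).
# Natural logs of range, mass, rainfall and litter size are centred and
# scaled by their sample (n-1) standard deviation; habitat openness enters
# as its raw 0-4 rank; region is coded NS = 1 for north, 0 for south.
.standardize_predictors <- function(table) {
  logged <- c(range_km2 = "log Range", female_mass_g = "log Female mass",
              rainfall_mm = "log Rainfall", litter_size = "log Litter")
  for (col in names(logged)) {
    bad <- which(table[[col]] <= 0)
    if (length(bad))
      stop("non-positive ", col, " for: ",
           paste(table$taxon_id[bad], collapse = ", "))
  }
  P <- data.frame(NS = as.numeric(table$region == "north"))
  center <- scale_ <- setNames(numeric(length(logged)), unname(logged))
  for (col in names(logged)) {
    lv <- log(table[[col]])
    mu <- mean(lv)
    sdv <- sd(lv)
    if (sdv == 0) stop("zero variance in log ", col)
    P[[logged[[col]]]] <- (lv - mu) / sdv
    center[logged[[col]]] <- mu
    scale_[logged[[col]]] <- sdv
  }
  P[["Habitat openness"]] <- as.numeric(table$habitat_openness)
  P <- P[, c("NS", "log Range", "log Female mass", "log Rainfall",
             "Habitat openness", "log Litter")]
  list(predictors = P, center = center, scale = scale_)
}

#' Prepare response and predictors for model fitting
#'
#' Applies the response compression and the predictor transformations used
#' throughout: natural-log transform of range, female mass, rainfall and
#' litter size, each centred and scaled to unit sample variance; habitat
#' openness kept as its raw ordinal rank; region coded \code{NS} = 1 (north)
#' / 0 (south). Standardisation constants are stored so log-scale values can
#' be recovered.
#'
#' @param table a \code{"trait_table"}.
#' @param squeeze \code{"smithson"} (default; see [squeeze_response()]),
#'   \code{"epsilon"} (clamp to \code{[epsilon, 1 - epsilon]}) or
#'   \code{"none"} (response must already be strictly inside (0, 1)).
#' @param epsilon clamp width for \code{squeeze = "epsilon"}.
#' @return an object of class \code{"prepared_data"}: list with \code{taxa},
#'   \code{y} (compressed response), \code{y_raw}, \code{predictors}
#'   (data.frame), \code{center}, \code{scale}, \code{squeeze},
#'   \code{table} (the input rows retained).
#' @export
prepare_predictors <- function(table, squeeze = c("smithson", "epsilon",
                                                  "none"), epsilon = 1e-4) {
  stopifnot(inherits(table, "trait_table"))
  squeeze <- match.arg(squeeze)
  y_raw <- table$decline
  y <- switch(squeeze,
              smithson = squeeze_response(y_raw),
              epsilon = pmin(pmax(y_raw, epsilon), 1 - epsilon),
              none = y_raw)
  if (any(y <= 0 | y >= 1))
    stop("response not strictly inside (0, 1); choose a squeeze rule")
  std <- .standardize_predictors(table)
  structure(list(taxa = table$taxon_id, y = y, y_raw = y_raw,
                 predictors = std$predictors, center = std$center,
                 scale = std$scale, squeeze = squeeze, table = table),
            class = "prepared_data")
}

#' @export
print.prepared_data <- function(x, ...) {
  cat(sprintf("Prepared data: %d taxa, %d predictor columns (squeeze: %s)\n",
              length(x$taxa), ncol(x$predictors), x$squeeze))
  invisible(x)
}
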