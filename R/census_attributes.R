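#' Neighborhood demand data: housing condition index and dengue incidence
#'
#' A neighborhood is the demand unit for service delivery: a census-block
#' centroid with population, household count, a housing condition index
#' (HCI) and reported dengue case count. The HCI is a normalized composite
#' of roof, wall and floor condition grades, where 0 is excellent and 1 is
#' very poor housing; poor housing is an established social-ecological risk
#' factor for arboviral transmission.
#'
#' @name census_attributes
NULL

#' Housing condition index from component grades
#'
#' Each ordinal grade (0 = best condition) is min-max normalized by its
#' stated maximum and the normalized grades are combined as a weighted mean
#' (equal weights by default). Vectorized over neighborhoods.
#'
#' @param roof_grade,wall_grade,floor_grade ordinal condition scores, 0 = best
#' @param grade_maxima numeric length-3 vector of the maximum grade on each
#'   scale (roof, wall, floor). Grade scales vary between census instruments,
#'   so the maxima are a required input.
#' @param weights nonnegative length-3 weights, normalized internally.
#' @return HCI values in \[0, 1\]; 0 = excellent, 1 = very poor.
#' @examples
#' compute_hci(1, 1, 1, grade_maxima = c(2, 2, 2))  # 0.5
#' @export
compute_hci <- function(roof_grade, wall_grade, floor_grade, grade_maxima,
                        weights = c(1, 1, 1)) {
  if (length(grade_maxima) != 3L || any(!is.finite(grade_maxima)) ||
      any(grade_maxima <= 0))
    stop_vectorops("grade_maxima must be three positive numbers",
                   class = "vectorops_validation_error")
  if (length(weights) != 3L || any(weights < 0) || sum(weights) == 0)
    stop_vectorops("weights must be three nonnegative numbers, not all zero",
                   class = "vectorops_validation_error")
  g <- cbind(roof_grade, wall_grade, floor_grade)
  if (any(g < 0) || any(t(g) > grade_maxima))
    stop_vectorops("grades must lie in [0, grade_maxima]",
                   class = "vectorops_validation_error")
  norm <- sweep(g, 2L, grade_maxima, "/")
  as.numeric(norm %*% (weights / sum(weights)))
}

#' Dengue incidence per 10,000 population
#'
#' @param cases reported case count (>= 0)
#' @param population population count (> 0)
#' @return cases / population x 10,000; vectorized.
#' @export
incidence_per_10k <- function(cases, population) {
  if (any(cases < 0))
    stop_vectorops("cases must be nonnegative",
                   class = "vectorops_validation_error")
  if (any(population <= 0))
    stop_vectorops("incidence undefined for population <= 0",
                   class = "vectorops_validation_error")
  cases / population * 10000
}

# Validate and normalize a neighborhood table to the canonical columns:
# id, x, y, population, households, hci, dengue_cases.
as_neighborhoods <- function(df, grade_maxima = NULL,
                             mean_household_size = 3.8) {
  req <- c("id", "x", "y", "population", "dengue_cases")
  if (!all(req %in% names(df)))
    stop_vectorops("neighborhood table missing column(s): ",
                   paste(setdiff(req, names(df)), collapse = ", "),
                   class = "vectorops_structural_error")
  out <- data.frame(id = as.character(df$id),
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    population = as.numeric(df$population),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id))
    stop_vectorops("duplicate neighborhood ids",
                   class = "vectorops_structural_error")
  if (any(out$population < 0) || any(df$dengue_cases < 0))
    stop_vectorops("population and dengue_cases must be nonnegative",
                   class = "vectorops_validation_error")

  if ("households" %in% names(df) && !anyNA(df$households)) {
    out$households <- as.numeric(df$households)
    if (any(out$households < 0))
      stop_vectorops("households must be nonnegative",
                     class = "vectorops_validation_error")
  } else {
    out$households <- round(out$population / mean_household_size)
    attr(out, "households_imputed") <- TRUE
    message("households imputed from population / ", mean_household_size)
  }

  if ("hci" %in% names(df) && !anyNA(df$hci)) {
    out$hci <- as.numeric(df$hci)
    if (any(out$hci < 0 | out$hci > 1))
      stop_vectorops("hci must lie in [0, 1]",
                     class = "vectorops_validation_error")
  } else if (all(c("roof", "wall", "floor") %in% names(df))) {
    if (is.null(grade_maxima))
      stop_vectorops("grade_maxima required to compute HCI from grades",
                     class = "vectorops_validation_error")
    out$hci <- compute_hci(df$roof, df$wall, df$floor, grade_maxima)
  } else {
    stop_vectorops("need either an hci column or roof/wall/floor grades",
                   class = "vectorops_structural_error")
  }
  out$dengue_cases <- as.numeric(df$dengue_cases)
  out
}

#' Read a neighborhood table from CSV or GeoJSON
#'
#' CSV columns: `id,x,y,population,households,roof,wall,floor[,hci],
#' dengue_cases` (households and the grade triple optional; HCI is computed
#' from grades when no `hci` column is present). GeoJSON: Point features
#' with the same keys as properties.
#'
#' @param path file path (`.csv`, `.geojson` or `.json`)
#' @param grade_maxima passed to [compute_hci()] when HCI must be derived
#' @param mean_household_size used to impute households when absent
#'   (default 3.8 persons/household, a typical coastal-Ecuador figure)
#' @return data.frame of validated neighborhoods
#' @export
read_neighborhoods <- function(path, grade_maxima = NULL,
                               mean_household_size = 3.8) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(fc$type, "FeatureCollection"))
      stop_vectorops("expected a GeoJSON FeatureCollection",
                     class = "vectorops_structural_error")
    rows <- lapply(fc$features, function(f) {
      if (!identical(f$geometry$type, "Point"))
        stop_vectorops("neighborhood features must be Points",
                       class = "vectorops_structural_error")
      p <- f$properties
      c(list(x = f$geometry$coordinates[[1]],
             y = f$geometry$coordinates[[2]]), p)
    })
    cols <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(lapply(setNames(cols, cols), function(cl)
      unlist(lapply(rows, function(r) r[[cl]] %||% NA))),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_neighborhoods(df, grade_maxima = grade_maxima,
                   mean_household_size = mean_household_size)
}

#' Read facility points from CSV or GeoJSON
#'
#' Facilities are service deployment points: `role` is either `"active"`
#' (a current spray hub) or `"candidate"` (a subcenter available for
#' relocation). CSV columns / GeoJSON Point properties: `id, x, y, role`.
#'
#' @param path file path
#' @return data.frame with columns id, x, y, role
#' @export
read_facilities <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(fc$features, function(f) {
      data.frame(id = as.character(f$properties$id),
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 role = as.character(f$properties$role %||% "candidate"),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$id <- as.character(df$id)
  }
  if (!all(c("id", "x", "y", "role") %in% names(df)))
    stop_vectorops("facility table must have id, x, y, role",
                   class = "vectorops_structural_error")
  if (!all(df$role %in% c("active", "candidate")))
    stop_vectorops("facility role must be 'active' or 'candidate'",
                   class = "vectorops_validation_error")
  df
}
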