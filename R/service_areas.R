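#' Service-area ranges by network driving distance
#'
#' Neighborhoods are binned by the driving distance (km) from their nearest
#' active spray hub, then each distance band is summarized by neighborhood
#' count, total population, mean HCI and pooled dengue incidence. Because
#' each demand point is characterized by its *nearest* hub, the bands
#' partition the reachable neighborhoods even when per-facility catchments
#' overlap.
#'
#' @name service_areas
NULL

#' Service-area bin scheme
#'
#' @param cutoffs_km strictly increasing positive upper cutoffs; the default
#'   `c(0.5, 1, 3, 5)` yields bands 0-0.5, 0.5-1, 1-3, 3-5 and an open
#'   final band > 5 km. Intervals are closed on the upper edge.
#' @return a `service_bins` object with `$cutoffs_km` and display `$labels`.
#' @export
service_bins <- function(cutoffs_km = c(0.5, 1, 3, 5)) {
  if (length(cutoffs_km) < 1L || any(!is.finite(cutoffs_km)) ||
      any(cutoffs_km <= 0) || is.unsorted(cutoffs_km, strictly = TRUE))
    stop_vectorops("cutoffs must be strictly increasing and positive",
                   class = "vectorops_validation_error")
  lo <- c(0, cutoffs_km[-length(cutoffs_km)] + 0.1)
  labels <- c(sprintf("%.1f-%.1f", lo, cutoffs_km),
              sprintf("> %g", cutoffs_km[length(cutoffs_km)]))
  structure(list(cutoffs_km = cutoffs_km, labels = labels),
            class = "service_bins")
}

#' Assign distances to service-area bins
#'
#' Upper-closed intervals: with default cutoffs, bin 1 is \[0, 0.5\], bin 2
#' is (0.5, 1\], ..., final bin (5, Inf).
#'
#' @param distance_km nonnegative distances (vectorized); `Inf` (unreachable)
#'   maps to `NA`.
#' @param scheme a [service_bins()] scheme
#' @return factor of bin labels, levels in band order.
#' @export
assign_bin <- function(distance_km, scheme = service_bins()) {
  if (any(distance_km < 0, na.rm = TRUE))
    stop_vectorops("distances must be nonnegative",
                   class = "vectorops_validation_error")
  idx <- rowSums(outer(distance_km, scheme$cutoffs_km, ">")) + 1L
  idx[!is.finite(distance_km)] <- NA_integer_
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Distance from each neighborhood to its nearest facility
#'
#' @param network a snapped `road_network`
#' @param facility_nodes character vector of facility node ids
#' @param neighborhood_nodes character vector of neighborhood node ids
#' @return named numeric vector (km); `Inf` where no facility is reachable.
#' @export
min_facility_distance <- function(network, facility_nodes, neighborhood_nodes) {
  if (!length(facility_nodes))
    stop_vectorops("need at least one facility",
                   class = "vectorops_validation_error")
  dm <- distance_matrix(network, facility_nodes, neighborhood_nodes)
  d <- apply(dm, 2L, min)
  names(d) <- neighborhood_nodes
  d
}

# Shared band/class summarizer. `group` is a factor over neighborhoods;
# incidence is pooled (sum cases / sum population), not a mean of rates,
# and mean HCI is the unweighted mean across neighborhoods (both
# configurable at the caller level).
summarize_groups <- function(neighborhoods, group,
                             hci_weighting = c("unweighted", "population"),
                             label_col = "bin_label") {
  hci_weighting <- match.arg(hci_weighting)
  lv <- levels(group)
  out <- data.frame(label = lv, n_neighborhoods = 0L, population = 0,
                    mean_hci = NA_real_, incidence_per_10k = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(lv)) {
    sel <- which(!is.na(group) & group == lv[k])
    out$n_neighborhoods[k] <- length(sel)
    if (!length(sel)) next
    nb <- neighborhoods[sel, ]
    out$population[k] <- sum(nb$population)
    out$mean_hci[k] <- if (hci_weighting == "population") {
      if (sum(nb$population) > 0)
        sum(nb$hci * nb$population) / sum(nb$population) else NA_real_
    } else mean(nb$hci)
    out$incidence_per_10k[k] <- if (sum(nb$population) > 0)
      sum(nb$dengue_cases) / sum(nb$population) * 10000 else NA_real_
  }
  names(out)[1L] <- label_col
  out
}

#' Summarize neighborhoods by service-area band
#'
#' @param neighborhoods validated neighborhood data.frame
#' @param distances_km per-neighborhood distance to the nearest active hub,
#'   aligned with `neighborhoods` rows; `Inf` = unreachable (excluded).
#' @param scheme a [service_bins()] scheme
#' @param hci_weighting `"unweighted"` (default: plain mean across
#'   neighborhoods) or `"population"`
#' @return data.frame: bin_label, n_neighborhoods, population, mean_hci,
#'   incidence_per_10k. Bands with zero population report `NA` incidence.
#' @export
summarize_bins <- function(neighborhoods, distances_km,
                           scheme = service_bins(),
                           hci_weighting = "unweighted") {
  if (length(distances_km) != nrow(neighborhoods))
    stop_vectorops("one distance per neighborhood required",
                   class = "vectorops_structural_error")
  grp <- assign_bin(distances_km, scheme)
  summarize_groups(neighborhoods, grp, hci_weighting, "bin_label")
}
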