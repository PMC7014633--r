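#' Weighted p-median location-allocation of spray hubs
#'
#' Given a candidate pool of facility sites (the active hubs plus available
#' subcenters) choose the k sites minimizing the sum over neighborhoods of
#' demand weight times network distance to the nearest chosen site. Four
#' weighting scenarios mirror distinct management priorities: distance only,
#' population (high-demand areas), reported dengue cases (reactive control)
#' and HCI (proactive, risk-factor-driven control).
#'
#' @name location_allocation
NULL

#' Demand weights for a location-allocation scenario
#'
#' @param neighborhoods validated neighborhood data.frame
#' @param mode one of `"distance_only"` (unit weights), `"population"`,
#'   `"dengue_cases"` (raw case counts, not incidence), `"hci"`
#' @return named nonnegative numeric vector, one weight per neighborhood.
#' @export
scenario_weights <- function(neighborhoods,
                             mode = c("distance_only", "population",
                                      "dengue_cases", "hci")) {
  mode <- match.arg(mode)
  w <- switch(mode,
              distance_only = rep(1, nrow(neighborhoods)),
              population = neighborhoods$population,
              dengue_cases = neighborhoods$dengue_cases,
              hci = neighborhoods$hci)
  if (is.null(w) || anyNA(w))
    stop_vectorops("attribute required by mode '", mode, "' is missing",
                   class = "vectorops_validation_error")
  names(w) <- neighborhoods$id
  w
}

#' p-median objective for a facility subset
#'
#' @param dm distance matrix (km), rows = candidate facility ids,
#'   columns = neighborhoods
#' @param selected nonempty subset of rownames(dm)
#' @param weights nonnegative demand weights aligned with columns of `dm`
#' @return sum over neighborhoods of w_i x distance to nearest selected site.
#' @export
pmedian_objective <- function(dm, selected, weights) {
  if (!length(selected))
    stop_vectorops("selection must be nonempty",
                   class = "vectorops_validation_error")
  if (!all(selected %in% rownames(dm)))
    stop_vectorops("selected ids not all in distance matrix",
                   class = "vectorops_structural_error")
  d <- apply(dm[selected, , drop = FALSE], 2L, min)
  sum(weights * d)
}

# Nearest selected facility per neighborhood, ties to smallest facility id.
assign_nearest <- function(dm, selected) {
  sel <- sort(selected)
  sub <- dm[sel, , drop = FALSE]
  best <- apply(sub, 2L, which.min)
  stats::setNames(sel[best], colnames(dm))
}

new_allocation_result <- function(selected, objective, dm, weights, solver) {
  structure(list(selected = sort(selected),
                 objective = objective,
                 assignments = assign_nearest(dm, selected),
                 solver = solver),
            class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> {%s}, objective %.6g (%s)\n",
              paste(x$selected, collapse = ", "), x$objective, x$solver))
  invisible(x)
}

#' Exact p-median by exhaustive enumeration
#'
#' Evaluates every k-subset of the candidates; the paper-scale instance
#' (10 candidates, k = 2) has only 45 subsets, so enumeration is the
#' default solver. Ties are broken by the lexicographically smallest
#' sorted id set.
#'
#' @param dm distance matrix, rows = candidate ids, cols = neighborhoods
#' @param candidates candidate facility ids (default: all rows of `dm`)
#' @param k number of sites to select
#' @param weights demand weights aligned with columns of `dm`
#' @param enumeration_limit refuse instances with more than this many
#'   k-subsets (default 10000); use [solve_teitz_bart()] beyond it.
#' @return an `allocation_result` (`solver = "exact"`).
#' @export
solve_enumerate <- function(dm, candidates = rownames(dm), k, weights,
                            enumeration_limit = 10000) {
  if (k < 1 || k > length(candidates))
    stop_vectorops("need 1 <= k <= number of candidates",
                   class = "vectorops_validation_error")
  if (choose(length(candidates), k) > enumeration_limit)
    stop_vectorops("instance exceeds enumeration limit; ",
                   "use solve_teitz_bart()",
                   class = "vectorops_limit_error")
  candidates <- sort(candidates)
  subsets <- utils::combn(candidates, k, simplify = FALSE)
  best <- NULL
  best_obj <- Inf
  for (s in subsets) {
    obj <- pmedian_objective(dm, s, weights)
    if (obj < best_obj ||
        (obj == best_obj && !is.null(best) && lex_less(match(s, candidates),
                                                       match(best, candidates)))) {
      best <- s
      best_obj <- obj
    }
  }
  new_allocation_result(best, best_obj, dm, weights, "exact")
}

#' p-median by Teitz-Bart vertex substitution
#'
#' Local search: starting from a random k-subset, repeatedly apply the best
#' improving swap of a selected site for an unselected candidate until no
#' swap improves the objective; the best local optimum over `restarts`
#' seeded starts is returned. Provided for candidate pools too large to
#' enumerate; it carries no global-optimality guarantee.
#'
#' @inheritParams solve_enumerate
#' @param restarts number of random restarts (default 5)
#' @param seed integer seed for reproducible restarts (NULL: ambient RNG)
#' @return an `allocation_result` (`solver = "heuristic"`).
#' @export
solve_teitz_bart <- function(dm, candidates = rownames(dm), k, weights,
                             restarts = 5, seed = NULL) {
  if (k < 1 || k > length(candidates))
    stop_vectorops("need 1 <= k <= number of candidates",
                   class = "vectorops_validation_error")
  candidates <- sort(candidates)
  obj_of <- function(s) pmedian_objective(dm, s, weights)
  run_one <- function() {
    sel <- sort(sample(candidates, k))
    cur <- obj_of(sel)
    repeat {
      best_swap <- NULL
      best_obj <- cur
      for (out in sel) for (inn in setdiff(candidates, sel)) {
        cand <- sort(c(setdiff(sel, out), inn))
        obj <- obj_of(cand)
        if (obj < best_obj - 1e-12 ||
            (!is.null(best_swap) && obj <= best_obj &&
             obj < cur - 1e-12 && lex_less(match(cand, candidates),
                                           match(best_swap, candidates)))) {
          best_swap <- cand
          best_obj <- obj
        }
      }
      if (is.null(best_swap)) break
      sel <- best_swap
      cur <- best_obj
    }
    list(sel = sel, obj = cur)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      res <- run_one()
      if (is.null(best) || res$obj < best$obj - 1e-12 ||
          (abs(res$obj - best$obj) <= 1e-12 &&
           lex_less(match(res$sel, candidates), match(best$sel, candidates))))
        best <- res
    }
    new_allocation_result(best$sel, best$obj, dm, weights, "heuristic")
  })
}

#' Compare an alternative hub scenario against the baseline
#'
#' Reports the percent reduction in mean access cost and the percent change
#' in population served by the cheapest cost class. Class membership uses
#' class edges fixed from the baseline scenario for both scenarios, so the
#' "least expensive routes" refer to the same dollar band.
#'
#' @param baseline_costs,alternative_costs data.frames from
#'   [access_costs()] over the same neighborhood set
#' @param neighborhoods neighborhood data.frame (matched on `id`)
#' @param class_edges increasing class upper bounds; default: quintiles of
#'   the baseline total-cost distribution
#' @return list: `mean_cost_reduction_pct`,
#'   `cheapest_class_population_change_pct` (NA with a warning when the
#'   baseline mean or cheapest-class population is zero).
#' @export
compare_scenarios <- function(baseline_costs, alternative_costs,
                              neighborhoods, class_edges = NULL) {
  if (!setequal(baseline_costs$id, alternative_costs$id))
    stop_vectorops("scenarios must cover the same neighborhoods",
                   class = "vectorops_structural_error")
  ok <- is.finite(baseline_costs$total_cost_usd) &
    is.finite(alternative_costs$total_cost_usd[
      match(baseline_costs$id, alternative_costs$id)])
  base <- baseline_costs[ok, ]
  alt <- alternative_costs[match(base$id, alternative_costs$id), ]
  if (is.null(class_edges)) class_edges <- cost_class_edges(base$total_cost_usd)

  mean_base <- mean(base$total_cost_usd)
  red <- if (mean_base > 0) {
    (mean_base - mean(alt$total_cost_usd)) / mean_base * 100
  } else {
    warning("baseline mean cost is zero; reduction undefined")
    NA_real_
  }

  pop_in_cheapest <- function(costs) {
    sum1 <- cost_bin_summary(costs, neighborhoods, edges = class_edges)
    sum1$population[1L]
  }
  pb <- pop_in_cheapest(base)
  pa <- pop_in_cheapest(alt)
  chg <- if (pb > 0) (pa - pb) / pb * 100 else {
    warning("baseline cheapest-class population is zero; change undefined")
    NA_real_
  }
  list(mean_cost_reduction_pct = red,
       cheapest_class_population_change_pct = chg)
}
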