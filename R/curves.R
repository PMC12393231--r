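# Both curves are computed on a single sweep of the domain grid: the target
# score and the complexity of every grid policy are evaluated once, after
# which each epsilon (or delta) is a threshold query.

new_telic_curve <- function(df, metadata) {
  attr(df, "metadata") <- metadata
  class(df) <- c("telic_curve", class(df))
  df
}

#' Curve metadata
#'
#' @param curve A `telic_curve`.
#' @return The provenance list recorded when the curve was computed.
#' @export
curve_metadata <- function(curve) attr(curve, "metadata")

#' Complexity-granularity tradeoff curve
#'
#' For each sensitivity `epsilon`, builds the target telic state at that
#' sensitivity and records the complexity of the information projection of
#' the default policy onto it (the capacity an agent needs to reach the
#' state).  The granularity axis is `-log(epsilon)` (natural log by
#' default).  States are nested decreasing in `epsilon`, so the required
#' complexity is non-decreasing in `epsilon` -- equivalently non-increasing
#' along the granularity axis: as `epsilon` tends to zero the state grows
#' toward the whole positive-score set, which contains policies arbitrarily
#' close to the default, and the required capacity falls toward zero.
#'
#' Sensitivities at which the state is empty on the grid yield an infinite
#' complexity and are flagged in the metadata.
#'
#' @param goal A [goal_spec()].
#' @param target Target region label (e.g. `"R"`); defaults to the goal's
#'   target.
#' @param cfg A [complexity_config()].
#' @param env An [environment_spec()].
#' @param domain A [policy_domain()].
#' @param epsilons Sensitivities in `(0, 1)`; any order, deduplicated and
#'   evaluated at increasing granularity.
#' @param log_base Base of the granularity logarithm (default `exp(1)`).
#' @param est An [estimator_spec()].
#' @return A tibble of class `telic_curve` with columns `epsilon`,
#'   `granularity` (strictly increasing) and `complexity`, plus a provenance
#'   metadata attribute (see [curve_metadata()]).
#' @export
complexity_granularity_curve <- function(goal, target = NULL, cfg, env,
                                         domain, epsilons,
                                         log_base = exp(1),
                                         est = estimator_spec()) {
  stopifnot(inherits(goal, "goal_spec"), inherits(cfg, "complexity_config"),
            inherits(env, "environment_spec"),
            inherits(domain, "policy_domain"))
  target <- target %||% goal$target
  epsilons <- sort(unique(as.numeric(epsilons)), decreasing = TRUE)
  if (any(epsilons <= 0 | epsilons >= 1)) {
    stop_invalid("`epsilons` must lie strictly inside (0, 1).")
  }
  grid <- domain_grid(domain)
  probs <- region_prob_matrix(grid, goal, env, est)
  score <- score_from_probs(probs, goal, target)
  tbl <- goal$regions_tbl
  if (tbl$waypoint[match(target, tbl$label)]) {
    goal_labels <- tbl$label[!tbl$waypoint]
    max_goal <- if (length(goal_labels)) {
      apply(vapply(goal_labels,
                   function(l) score_from_probs(probs, goal, l),
                   numeric(nrow(grid))), 1L, max)
    } else {
      rep(-Inf, nrow(grid))
    }
  }
  comp <- complexity_values(grid, cfg, env)
  y <- vapply(epsilons, function(eps) {
    member <- score >= eps
    if (tbl$waypoint[match(target, tbl$label)]) {
      member <- member & (max_goal < eps)
    }
    if (!any(member)) Inf else min(comp[member])
  }, 0.0)
  meta <- list(
    type = "complexity_granularity", target = target,
    level = cfg$level, direction = cfg$direction, base = cfg$base,
    default_policy = as.list(cfg$default_policy),
    log_base = log_base,
    env = list(horizon = env$horizon, start = env$start,
               param_convention = env$param_convention),
    domain = unclass(domain),
    empty_epsilons = epsilons[!is.finite(y)]
  )
  new_telic_curve(
    tibble(epsilon = epsilons,
           granularity = -log(epsilons) / log(log_base),
           complexity = y),
    meta)
}

#' Goal-complexity tradeoff curve
#'
#' For each capacity `delta`, the best attainable probability of reaching the
#' target region over all grid policies whose complexity does not exceed
#' `delta` (the default policy is always a candidate, so `delta = 0` yields
#' its own reach probability).  The feasible set grows with `delta`, so the
#' curve is non-decreasing, plateauing once the capacity covers the grid's
#' best policy.
#'
#' @inheritParams complexity_granularity_curve
#' @param deltas Non-negative capacities; any order, deduplicated ascending.
#' @return A tibble of class `telic_curve` with columns `delta` (strictly
#'   increasing) and `p_reach`, plus a provenance metadata attribute.
#' @export
goal_complexity_curve <- function(goal, target = NULL, cfg, env, domain,
                                  deltas, est = estimator_spec()) {
  stopifnot(inherits(goal, "goal_spec"), inherits(cfg, "complexity_config"),
            inherits(env, "environment_spec"),
            inherits(domain, "policy_domain"))
  target <- target %||% goal$target
  deltas <- sort(unique(as.numeric(deltas)))
  if (any(deltas < 0)) stop_invalid("`deltas` must be non-negative.")
  tbl <- goal$regions_tbl
  reg <- list(lower = tbl$lower[match(target, tbl$label)],
              upper = tbl$upper[match(target, tbl$label)])
  cand <- dplyr::distinct(bind_rows(domain_grid(domain),
                                    cfg$default_policy))
  p <- region_prob(cand, reg, env, goal$reach_mode, est)
  comp <- complexity_values(cand, cfg, env)
  # sort by complexity; running max of p answers every threshold query
  ord <- order(comp)
  comp_s <- comp[ord]
  best_p <- cummax(p[ord])
  y <- vapply(deltas, function(d) {
    i <- findInterval(d, comp_s)
    if (i == 0L) NA_real_ else best_p[i]
  }, 0.0)
  meta <- list(
    type = "goal_complexity", target = target,
    level = cfg$level, direction = cfg$direction, base = cfg$base,
    default_policy = as.list(cfg$default_policy),
    env = list(horizon = env$horizon, start = env$start,
               param_convention = env$param_convention),
    domain = unclass(domain)
  )
  new_telic_curve(tibble(delta = deltas, p_reach = y), meta)
}

#' Plot a tradeoff curve
#'
#' @param object A `telic_curve`.
#' @param ref_x,ref_y Optional dashed reference lines (e.g. the scenario's
#'   `epsilon`/`delta` and capacity).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.telic_curve <- function(object, ref_x = NULL, ref_y = NULL, ...) {
  meta <- curve_metadata(object)
  if (meta$type == "complexity_granularity") {
    xvar <- "granularity"; yvar <- "complexity"
    xlab <- expression(-log(epsilon))
    ylab <- sprintf("projection complexity (%s)", meta$base)
  } else {
    xvar <- "delta"; yvar <- "p_reach"
    xlab <- sprintf("policy complexity capacity (%s)", meta$base)
    ylab <- sprintf("P(reach %s)", meta$target)
  }
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(ref_x)) {
    p <- p + ggplot2::geom_vline(xintercept = ref_x, linetype = "dashed",
                                 colour = "grey50")
  }
  if (!is.null(ref_y)) {
    p <- p + ggplot2::geom_hline(yintercept = ref_y, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Write a curve as CSV with a JSON metadata sidecar
#'
#' @param curve A `telic_curve`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "telic_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(curve_metadata(curve), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
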