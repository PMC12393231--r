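#' Goal regions on the line
#'
#' A region is the closed interval `[center - width/2, center + width/2]`.
#' Membership at exactly a boundary counts as inside.
#'
#' @param center Region center, in position units.
#' @param width Region width, positive (default 1, the unit-length regions of
#'   the worked navigation scenarios).
#' @return A list of class `telic_region` with fields `center`, `width`,
#'   `lower`, `upper`.
#' @export
region <- function(center, width = 1) {
  center <- check_number(center, "center")
  width <- check_number(width, "width")
  if (width <= 0) stop_invalid("`width` must be > 0.")
  structure(
    list(center = center, width = width,
         lower = center - width / 2, upper = center + width / 2),
    class = "telic_region"
  )
}

#' @export
print.telic_region <- function(x, ...) {
  cat(sprintf("<region> [%g, %g] (center %g, width %g)\n",
              x$lower, x$upper, x$center, x$width))
  invisible(x)
}

#' Goals as scored preferences over experience distributions
#'
#' A goal names a set of disjoint regions, designates one as the target, and
#' fixes the reach semantics.  It induces a scalar preference score over
#' policies -- the probability of reaching the target region minus the largest
#' probability of reaching any competing region (see [preference_score()]) --
#' and therefore a total preorder: policies with equal scores are
#' goal-equivalent.
#'
#' Regions flagged in `waypoints` are intermediate waypoint regions (inserted
#' by [split_state()] during refinement).  They never compete in the scores of
#' the original goal regions; their own score is measured against all original
#' goal regions.  This keeps the original goal-equivalence classes intact when
#' a representation is repaired.
#'
#' @param regions Named list of [region()]s, e.g.
#'   `list(R = region(2), L = region(-2))`.  Pairwise disjoint.
#' @param target Name of the target region (must be in `regions`).
#' @param reach_mode `"terminal"` (default; position at the final step) or
#'   `"first_passage"` (any step `1..T`; Monte-Carlo only).
#' @param waypoints Character vector of region names that are waypoints
#'   (default none).
#' @return An object of class `goal_spec` carrying the region table
#'   (`regions_tbl`), the target and the reach mode.
#' @export
goal_spec <- function(regions, target,
                      reach_mode = c("terminal", "first_passage"),
                      waypoints = character()) {
  reach_mode <- match.arg(reach_mode)
  if (!is.list(regions) || length(regions) == 0L ||
      is.null(names(regions)) || any(names(regions) == "")) {
    stop_invalid("`regions` must be a non-empty named list of region().")
  }
  if (anyDuplicated(names(regions))) {
    stop_invalid("`regions` names must be unique.")
  }
  regions <- lapply(regions, function(r) {
    if (inherits(r, "telic_region")) r
    else if (is.list(r) && all(c("center", "width") %in% names(r))) {
      region(r$center, r$width)
    } else stop_invalid("each element of `regions` must be a region().")
  })
  if (!is.character(target) || length(target) != 1L ||
      !target %in% names(regions)) {
    stop_invalid("`target` must name one of `regions`.")
  }
  if (!all(waypoints %in% names(regions))) {
    stop_invalid("`waypoints` must be a subset of region names.")
  }
  tbl <- tibble(
    label = names(regions),
    center = unname(vapply(regions, `[[`, 0, "center")),
    width = unname(vapply(regions, `[[`, 0, "width")),
    lower = unname(vapply(regions, `[[`, 0, "lower")),
    upper = unname(vapply(regions, `[[`, 0, "upper")),
    waypoint = names(regions) %in% waypoints
  )
  # pairwise disjointness (closed intervals: shared endpoints also overlap)
  if (nrow(tbl) > 1L) {
    ord <- order(tbl$lower)
    if (any(tbl$lower[ord][-1L] <= tbl$upper[ord][-nrow(tbl)])) {
      stop_invalid("regions must be pairwise disjoint.")
    }
  }
  structure(
    list(regions = regions, regions_tbl = tbl, target = target,
         reach_mode = reach_mode),
    class = "goal_spec"
  )
}

#' @export
print.goal_spec <- function(x, ...) {
  cat(sprintf("<goal_spec> target = %s, reach_mode = %s\n",
              x$target, x$reach_mode))
  print(x$regions_tbl)
  invisible(x)
}

#' Estimator settings for reach probabilities
#'
#' @param method `"analytic"` (Gaussian CDF; terminal mode only) or
#'   `"monte_carlo"`.
#' @param n_mc Number of Monte-Carlo trajectories (default `1e5`).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(method = c("analytic", "monte_carlo"),
                           n_mc = 1e5, seed = 1L) {
  method <- match.arg(method)
  n_mc <- check_count(n_mc, "n_mc", lower = 1L)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(list(method = method, n_mc = n_mc, seed = seed),
            class = "estimator_spec")
}

# Probability that each policy's experience reaches `reg`, as a bare numeric
# vector.  Analytic: exact Gaussian CDF of the terminal law.  Monte-Carlo:
# simulate trajectories per policy (common seed across policies and regions,
# so comparisons use common random numbers).
region_prob <- function(policies, reg, env, mode, est) {
  if (est$method == "analytic") {
    if (mode != "terminal") {
      abort(
        "analytic estimation is only available for reach_mode = 'terminal'.",
        class = c("telic_unsupported_estimator", "telic_error"))
    }
    ep <- endpoint_params(policies$mu, policies$sigma, env)
    pnorm((reg$upper - ep$mean) / ep$sd) - pnorm((reg$lower - ep$mean) / ep$sd)
  } else {
    vapply(seq_len(nrow(policies)), function(i) {
      batch <- sample_trajectories(policies[i, ], env,
                                   n = est$n_mc, seed = est$seed)
      mat <- as.matrix(as.data.frame(batch))[, -1L, drop = FALSE]  # t1..tT
      if (mode == "terminal") {
        term <- mat[, ncol(mat)]
        mean(term >= reg$lower & term <= reg$upper)
      } else {
        mean(apply(mat >= reg$lower & mat <= reg$upper, 1L, any))
      }
    }, 0.0)
  }
}

# n_policies x n_regions matrix of reach probabilities for every region of a
# goal (columns in region-table order).
region_prob_matrix <- function(policies, goal, env, est) {
  tbl <- goal$regions_tbl
  out <- matrix(NA_real_, nrow(policies), nrow(tbl),
                dimnames = list(NULL, tbl$label))
  for (j in seq_len(nrow(tbl))) {
    out[, j] <- region_prob(policies,
                            list(lower = tbl$lower[j], upper = tbl$upper[j]),
                            env, goal$reach_mode, est)
  }
  out
}

# Preference scores toward `target` for each row of a probability matrix.
# Original goal regions compete with the other goal regions; waypoint regions
# are scored against all original goal regions.  With a single region the
# score is the region's own reach probability.
score_from_probs <- function(probs, goal, target) {
  tbl <- goal$regions_tbl
  if (!target %in% tbl$label) {
    stop_invalid(sprintf("unknown target region `%s`.", target))
  }
  is_wp <- tbl$waypoint[match(target, tbl$label)]
  if (is_wp) {
    competitors <- tbl$label[!tbl$waypoint]
  } else {
    competitors <- setdiff(tbl$label[!tbl$waypoint], target)
  }
  p_t <- unname(probs[, target])
  if (length(competitors) == 0L) return(p_t)
  p_c <- probs[, competitors, drop = FALSE]
  unname(p_t - apply(p_c, 1L, max))
}

#' Probability of reaching a region
#'
#' Terminal mode gives `P(terminal position in region)`; first-passage mode
#' gives `P(position enters the region at some step 1..T)` (the start is
#' excluded).  Terminal probabilities are available in closed form via the
#' Gaussian CDF; first passage requires Monte Carlo.
#'
#' @param policies A data frame of policies (columns `mu`, `sigma`).
#' @param reg A [region()].
#' @param env An [environment_spec()].
#' @param mode `"terminal"` or `"first_passage"`.
#' @param est An [estimator_spec()].
#' @return The input tibble with a `p_reach` column appended.
#' @examples
#' reach_probability(policy(1, 1), region(2), environment_spec())
#' # p_reach = pnorm(1.5) - pnorm(0.5) ~ 0.2417
#' @export
reach_probability <- function(policies, reg, env,
                              mode = c("terminal", "first_passage"),
                              est = estimator_spec()) {
  validate_policies(policies)
  stopifnot(inherits(reg, "telic_region"), inherits(env, "environment_spec"))
  mode <- match.arg(mode)
  p <- region_prob(policies, reg, env, mode, est)
  mutate(as_tibble(policies), p_reach = p)
}

#' Preference score of policies under a goal
#'
#' The score of a policy is the probability that its experience reaches the
#' target region minus the largest reach probability among the competing goal
#' regions (for two regions this is the familiar difference
#' `P(target) - P(other)`).  With a single region the score is the target
#' probability itself.  Scores order policies: equal scores mean
#' goal-equivalence.
#'
#' @param policies A data frame of policies.
#' @param goal A [goal_spec()].
#' @param env An [environment_spec()].
#' @param est An [estimator_spec()].
#' @param target Target region label; defaults to the goal's designated
#'   target.
#' @return The input tibble with a `score` column appended (in `[-1, 1]`).
#' @export
preference_score <- function(policies, goal, env, est = estimator_spec(),
                             target = NULL) {
  validate_policies(policies)
  stopifnot(inherits(goal, "goal_spec"), inherits(env, "environment_spec"))
  target <- target %||% goal$target
  probs <- region_prob_matrix(policies, goal, env, est)
  mutate(as_tibble(policies),
         score = score_from_probs(probs, goal, target))
}

#' Rank policies by preference score
#'
#' Sorts policies by descending preference score and assigns competition
#' ranks.  Exact score ties (within `tie_tol`, default `1e-12`, to absorb
#' floating-point noise) receive the same rank: tied policies are
#' goal-equivalent.
#'
#' @inheritParams preference_score
#' @param tie_tol Absolute tolerance below which adjacent sorted scores are
#'   treated as tied.
#' @return A tibble sorted by descending `score` with a `rank` column
#'   (ties share the smallest rank in their group).
#' @export
rank_policies <- function(policies, goal, env, est = estimator_spec(),
                          tie_tol = 1e-12) {
  scored <- preference_score(policies, goal, env, est)
  scored <- arrange(scored, dplyr::desc(.data$score))
  s <- scored$score
  rank <- integer(length(s))
  if (length(s) > 0L) {
    rank[1L] <- 1L
    for (i in seq_along(s)[-1L]) {
      rank[i] <- if (s[i - 1L] - s[i] <= tie_tol) rank[i - 1L] else i
    }
  }
  mutate(scored, rank = rank)
}
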