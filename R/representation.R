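#' Sensitivity rule for telic-state formation
#'
#' The sensitivity \eqn{\epsilon} is the smallest preference-score margin at
#' which two experience distributions count as different with respect to the
#' goal.  A policy belongs to the telic state of region `g` when its
#' preference score toward `g` is at least \eqn{\epsilon} (inclusive
#' comparison); policies clearing the threshold for no region form the
#' residual state `S0`.  Smaller \eqn{\epsilon} means finer granularity.
#'
#' @param epsilon Sensitivity threshold, in `(0, 1)`.
#' @return An object of class `telic_rule`.
#' @export
telic_rule <- function(epsilon = 0.1) {
  epsilon <- check_number(epsilon, "epsilon")
  if (epsilon <= 0 || epsilon >= 1) {
    stop_invalid("`epsilon` must lie strictly inside (0, 1).")
  }
  structure(list(epsilon = epsilon), class = "telic_rule")
}

#' Rectangular search grid over the policy domain
#'
#' Telic states are represented extensionally on a finite \eqn{(\mu, \sigma)}
#' grid (besides the intensional score predicate).  The default grid, 301
#' \eqn{\times} 151 points over \eqn{\mu \in [-3, 3]}, \eqn{\sigma \in
#' [0.5, 2]}, covers the policy tiles of the worked navigation scenarios at
#' steps of 0.02 in \eqn{\mu} and 0.01 in \eqn{\sigma} while keeping every
#' grid sweep interactive.
#'
#' @param mu_min,mu_max Bounds of the drift axis.
#' @param sigma_min,sigma_max Bounds of the dispersion axis (positive).
#' @param n_mu,n_sigma Number of grid points per axis (at least 1).
#' @return An object of class `policy_domain`.
#' @export
policy_domain <- function(mu_min = -3, mu_max = 3,
                          sigma_min = 0.5, sigma_max = 2,
                          n_mu = 301, n_sigma = 151) {
  mu_min <- check_number(mu_min, "mu_min")
  mu_max <- check_number(mu_max, "mu_max")
  sigma_min <- check_number(sigma_min, "sigma_min")
  sigma_max <- check_number(sigma_max, "sigma_max")
  n_mu <- check_count(n_mu, "n_mu", lower = 1L)
  n_sigma <- check_count(n_sigma, "n_sigma", lower = 1L)
  if (mu_max < mu_min || sigma_max < sigma_min) {
    stop_invalid("domain bounds must satisfy min <= max.")
  }
  if (sigma_min <= 0) stop_invalid("`sigma_min` must be > 0.")
  structure(
    list(mu_min = mu_min, mu_max = mu_max,
         sigma_min = sigma_min, sigma_max = sigma_max,
         n_mu = n_mu, n_sigma = n_sigma),
    class = "policy_domain"
  )
}

#' @export
print.policy_domain <- function(x, ...) {
  cat(sprintf(
    "<policy_domain> mu in [%g, %g] x %d, sigma in [%g, %g] x %d (%d policies)\n",
    x$mu_min, x$mu_max, x$n_mu, x$sigma_min, x$sigma_max, x$n_sigma,
    x$n_mu * x$n_sigma))
  invisible(x)
}

#' Enumerate the policies of a domain grid
#'
#' @param domain A [policy_domain()].
#' @return A tibble of policies (`mu`, `sigma`), `n_mu * n_sigma` rows,
#'   `mu` varying fastest.
#' @export
domain_grid <- function(domain) {
  stopifnot(inherits(domain, "policy_domain"))
  mu <- seq(domain$mu_min, domain$mu_max, length.out = domain$n_mu)
  sigma <- seq(domain$sigma_min, domain$sigma_max,
               length.out = domain$n_sigma)
  tidyr::expand_grid(sigma = sigma, mu = mu)[, c("mu", "sigma")]
}

state_label <- function(region_label) paste0("S", region_label)

# Two-tier classification from a probability matrix: original goal regions
# first (argmax score >= eps wins, ties broken by region order), then waypoint
# regions, then the residual S0.
labels_from_probs <- function(probs, goal, rule) {
  tbl <- goal$regions_tbl
  eps <- rule$epsilon
  n <- nrow(probs)
  out <- rep("S0", n)
  assign_tier <- function(labels_in_tier, unassigned) {
    if (length(labels_in_tier) == 0L || !any(unassigned)) return(invisible())
    sc <- vapply(labels_in_tier,
                 function(l) score_from_probs(probs, goal, l),
                 numeric(n))
    sc <- matrix(sc, nrow = n)
    best <- max.col(sc, ties.method = "first")
    best_score <- sc[cbind(seq_len(n), best)]
    hit <- unassigned & best_score >= eps
    out[hit] <<- state_label(labels_in_tier[best[hit]])
  }
  goal_labels <- tbl$label[!tbl$waypoint]
  wp_labels <- tbl$label[tbl$waypoint]
  assign_tier(goal_labels, rep(TRUE, n))
  assign_tier(wp_labels, out == "S0")
  out
}

#' Assign policies to telic states
#'
#' Classifies each policy into the telic state of the goal region whose
#' preference score it maximizes, provided that score reaches the sensitivity
#' threshold \eqn{\epsilon}; otherwise into the residual state `S0`.
#' Waypoint regions (inserted during refinement) are considered only for
#' policies that belong to no original goal state.  Ties in the argmax are
#' broken by the fixed region order of the goal.
#'
#' @param policies A data frame of policies.
#' @param goal A [goal_spec()].
#' @param rule A [telic_rule()].
#' @param env An [environment_spec()].
#' @param est An [estimator_spec()].
#' @return The input tibble with a `state` column appended (labels `S<region>`
#'   or `S0`).
#' @examples
#' goal <- goal_spec(list(R = region(2), L = region(-2)), target = "R")
#' classify_policies(policy(c(1, 0, -1), 1), goal, telic_rule(0.1),
#'                   environment_spec())
#' @export
classify_policies <- function(policies, goal, rule, env,
                              est = estimator_spec()) {
  validate_policies(policies)
  stopifnot(inherits(goal, "goal_spec"), inherits(rule, "telic_rule"),
            inherits(env, "environment_spec"))
  probs <- region_prob_matrix(policies, goal, env, est)
  mutate(as_tibble(policies),
         state = labels_from_probs(probs, goal, rule))
}

#' Build a telic state representation over a policy domain
#'
#' Classifies every policy of the domain grid, yielding the partition of the
#' grid into telic states (goal-equivalence classes) plus the residual state
#' `S0`.  States with no members on the grid are reported with a zero count,
#' not dropped.
#'
#' @param goal A [goal_spec()].
#' @param rule A [telic_rule()].
#' @param env An [environment_spec()].
#' @param domain A [policy_domain()].
#' @param est An [estimator_spec()].
#' @return An object of class `telic_representation`: a list with the
#'   classified grid (`assignments`, also carrying per-region reach
#'   probabilities `p_<label>` and scores `score_<label>`), the state count
#'   table (`counts`), and the `goal`, `rule`, `env`, `domain`, `est` used.
#' @export
build_representation <- function(goal, rule, env, domain,
                                 est = estimator_spec()) {
  stopifnot(inherits(goal, "goal_spec"), inherits(rule, "telic_rule"),
            inherits(env, "environment_spec"),
            inherits(domain, "policy_domain"))
  grid <- domain_grid(domain)
  if (nrow(grid) == 0L) stop_invalid("policy domain grid is empty.")
  probs <- region_prob_matrix(grid, goal, env, est)
  assignments <- grid
  for (l in goal$regions_tbl$label) {
    assignments[[paste0("p_", l)]] <- probs[, l]
    assignments[[paste0("score_", l)]] <- score_from_probs(probs, goal, l)
  }
  assignments$state <- labels_from_probs(probs, goal, rule)
  all_states <- c("S0", state_label(goal$regions_tbl$label))
  counts <- tibble(
    state = all_states,
    n = unname(vapply(all_states,
                      function(s) sum(assignments$state == s), 0L))
  )
  structure(
    list(assignments = assignments, counts = counts, goal = goal,
         rule = rule, env = env, domain = domain, est = est),
    class = "telic_representation"
  )
}

#' @export
print.telic_representation <- function(x, ...) {
  cat(sprintf(
    "<telic_representation> epsilon = %g, %d grid policies, states:\n",
    x$rule$epsilon, nrow(x$assignments)))
  print(x$counts)
  invisible(x)
}

#' @describeIn build_representation `tidy()` returns the classified grid, one
#'   row per policy, with reach probabilities, scores and state label.
#' @param x A `telic_representation`.
#' @param ... Unused.
#' @export
tidy.telic_representation <- function(x, ...) x$assignments

#' @describeIn build_representation `glance()` returns a one-row summary.
#' @export
glance.telic_representation <- function(x, ...) {
  tibble(
    epsilon = x$rule$epsilon,
    n_grid = nrow(x$assignments),
    n_states = nrow(x$counts),
    n_nonempty = sum(x$counts$n > 0L),
    n_residual = x$counts$n[x$counts$state == "S0"]
  )
}

# Grid members of one telic state (rows of the classified grid).
state_members <- function(rep, label) {
  stopifnot(inherits(rep, "telic_representation"))
  if (!label %in% rep$counts$state) {
    stop_invalid(sprintf("unknown state `%s`.", label))
  }
  rep$assignments[rep$assignments$state == label, , drop = FALSE]
}

# Region label ("R") behind a state label ("SR"); NULL for "S0".
region_of_state <- function(rep, label) {
  if (label == "S0") return(NULL)
  l <- sub("^S", "", label)
  if (!l %in% rep$goal$regions_tbl$label) {
    stop_invalid(sprintf("unknown state `%s`.", label))
  }
  l
}

#' Are two policies goal-equivalent under a representation?
#'
#' Two policies are goal-equivalent when the representation assigns them to
#' the same telic state.  This is an equivalence relation by construction
#' (labels are a partition).
#'
#' @param p1,p2 Policies (one-row data frames or `c(mu, sigma)`).
#' @param rep A [build_representation()] result.
#' @return `TRUE` or `FALSE`.
#' @export
goal_equivalent <- function(p1, p2, rep) {
  stopifnot(inherits(rep, "telic_representation"))
  both <- bind_rows(as_policy(p1, "p1"), as_policy(p2, "p2"))
  lab <- classify_policies(both, rep$goal, rep$rule, rep$env, rep$est)$state
  lab[1L] == lab[2L]
}

#' Plot a telic state representation
#'
#' Raster of the policy grid coloured by the preference score toward the
#' goal's target region, with telic-state membership drawn as contour
#' outlines and the default policy marked when a complexity configuration is
#' supplied.
#'
#' @param object A `telic_representation`.
#' @param cfg Optional [complexity_config()]; when given, the default policy
#'   is marked and iso-complexity contours at `delta` are drawn.
#' @param delta Optional capacity (bits) for a highlighted complexity contour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.telic_representation <- function(object, cfg = NULL, delta = NULL,
                                          ...) {
  a <- object$assignments
  target <- object$goal$target
  a$target_score <- a[[paste0("score_", target)]]
  p <- ggplot2::ggplot(a, ggplot2::aes(x = .data$mu, y = .data$sigma)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$target_score)) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "grey95",
                                  high = "forestgreen", midpoint = 0) +
    ggplot2::labs(x = expression(mu), y = expression(sigma),
                  fill = "score") +
    ggplot2::theme_minimal()
  for (l in object$goal$regions_tbl$label) {
    a_l <- a
    a_l$member <- as.numeric(a$state == state_label(l))
    if (sum(a_l$member) > 0 && length(unique(a_l$member)) > 1L) {
      p <- p + ggplot2::geom_contour(
        data = a_l,
        ggplot2::aes(z = .data$member),
        breaks = 0.5, colour = "black", linewidth = 0.3,
        linetype = "dashed")
    }
  }
  if (!is.null(cfg)) {
    comp <- policy_complexity(a[, c("mu", "sigma")], cfg, object$env)
    a$complexity <- comp$complexity
    p <- p + ggplot2::geom_point(
      data = cfg$default_policy,
      ggplot2::aes(x = .data$mu, y = .data$sigma),
      inherit.aes = FALSE, size = 2)
    if (!is.null(delta)) {
      p <- p + ggplot2::geom_contour(
        data = a, ggplot2::aes(z = .data$complexity),
        breaks = delta, colour = "grey30", linewidth = 0.4)
    }
  }
  p
}
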