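#' Kullback-Leibler divergence between univariate Gaussians
#'
#' `KL(N(mean1, sd1^2) || N(mean0, sd0^2))`, vectorized over all arguments.
#'
#' @param mean1,sd1 Parameters of the left (data-generating) distribution.
#' @param mean0,sd0 Parameters of the right (reference) distribution.
#' @param base `"nats"` (natural log) or `"bits"` (log base 2).
#' @return Non-negative numeric vector; zero iff the parameters coincide.
#' @examples
#' kl_gaussian(0, 2, 0, 1)            # log(1/2) + 4/2 - 1/2 = 0.80685 nats
#' kl_gaussian(1, 1, 0, 1, "bits")    # 0.5 nats = 0.72135 bits
#' @export
kl_gaussian <- function(mean1, sd1, mean0, sd0, base = c("nats", "bits")) {
  base <- match.arg(base)
  if (any(sd1 <= 0) || any(sd0 <= 0)) stop_invalid("sd must be > 0.")
  nats <- log(sd0 / sd1) + (sd1^2 + (mean1 - mean0)^2) / (2 * sd0^2) - 0.5
  if (base == "bits") nats / log(2) else nats
}

#' Policy-complexity convention
#'
#' Policy complexity is the KL divergence between a policy's induced
#' experience distribution and the default policy's.  Three axes fix the
#' convention:
#' \describe{
#'   \item{`level`}{`"endpoint"` (default) compares terminal-position laws;
#'     `"trajectory"` compares full trajectory laws, which for open-loop
#'     Gaussian policies equals `horizon` times the single-step KL (steps are
#'     i.i.d., so the joint KL factorizes exactly).}
#'   \item{`direction`}{`"forward"` (default) is `KL(policy || default)` --
#'     the convention under which the information projection of the default
#'     onto a set is the set member closest in this divergence;
#'     `"reverse"` is `KL(default || policy)`.}
#'   \item{`base`}{`"bits"` (default; capacity bounds are quoted in bits) or
#'     `"nats"`.}
#' }
#'
#' @param default_policy The default policy \eqn{\pi_0} (one-row data frame
#'   or `c(mu, sigma)`); default `policy(0, 1)`.
#' @param level `"endpoint"` or `"trajectory"`.
#' @param direction `"forward"` or `"reverse"`.
#' @param base `"bits"` or `"nats"`.
#' @return An object of class `complexity_config`.
#' @export
complexity_config <- function(default_policy = policy(0, 1),
                              level = c("endpoint", "trajectory"),
                              direction = c("forward", "reverse"),
                              base = c("bits", "nats")) {
  structure(
    list(default_policy = as_policy(default_policy, "default_policy"),
         level = match.arg(level),
         direction = match.arg(direction),
         base = match.arg(base)),
    class = "complexity_config"
  )
}

#' @export
print.complexity_config <- function(x, ...) {
  cat(sprintf(
    "<complexity_config> default (%g, %g), level = %s, direction = %s, base = %s\n",
    x$default_policy$mu, x$default_policy$sigma, x$level, x$direction, x$base))
  invisible(x)
}

#' Capacity bound on policy complexity
#'
#' @param delta Maximum complexity the agent can spend on a single
#'   re-anchoring leg, in the units of the complexity configuration
#'   (conventionally bits).  Non-negative.
#' @return An object of class `capacity_bound`.
#' @export
capacity_bound <- function(delta = 1) {
  delta <- check_number(delta, "delta", lower = 0)
  structure(list(delta = delta), class = "capacity_bound")
}

# Complexity of each policy row relative to `anchor` (defaults to the config's
# default policy), as a bare numeric vector.
complexity_values <- function(policies, cfg, env, anchor = NULL) {
  anchor <- anchor %||% cfg$default_policy
  if (cfg$level == "endpoint") {
    p1 <- endpoint_params(policies$mu, policies$sigma, env)
    p0 <- endpoint_params(anchor$mu, anchor$sigma, env)
    scale <- 1
  } else {
    p1 <- step_params(policies$mu, policies$sigma, env)
    p0 <- step_params(anchor$mu, anchor$sigma, env)
    scale <- env$horizon
  }
  kl <- if (cfg$direction == "forward") {
    kl_gaussian(p1$mean, p1$sd, p0$mean, p0$sd, base = cfg$base)
  } else {
    kl_gaussian(p0$mean, p0$sd, p1$mean, p1$sd, base = cfg$base)
  }
  scale * kl
}

#' Policy complexity relative to the default policy
#'
#' Closed-form Gaussian KL divergence between each policy's induced
#' distribution and the default policy's, at the level, direction and base of
#' the configuration.  Zero iff the parameters equal the default's.
#'
#' @param policies A data frame of policies.
#' @param cfg A [complexity_config()].
#' @param env An [environment_spec()].
#' @param anchor Optional policy overriding the configured default (used when
#'   measuring legs from a re-anchored default).
#' @return The input tibble with a `complexity` column appended.
#' @examples
#' policy_complexity(policy(1, 1), complexity_config(), environment_spec())
#' # 0.72135 bits
#' @export
policy_complexity <- function(policies, cfg, env, anchor = NULL) {
  validate_policies(policies)
  stopifnot(inherits(cfg, "complexity_config"),
            inherits(env, "environment_spec"))
  if (!is.null(anchor)) anchor <- as_policy(anchor, "anchor")
  mutate(as_tibble(policies),
         complexity = complexity_values(policies, cfg, env, anchor))
}

# Continuous membership margin of a policy toward state `label`:
# non-negative iff the policy belongs to the state.  For a goal-region state
# the binding constraint is score >= eps (a score >= eps > 0 already implies
# the region is the argmax); for a waypoint state the policy must also clear
# no original goal region.
membership_margin <- function(mu, sigma, rep, label) {
  reg_label <- region_of_state(rep, label)
  p <- tibble(mu = mu, sigma = sigma)
  probs <- region_prob_matrix(p, rep$goal, rep$env, rep$est)
  eps <- rep$rule$epsilon
  m <- score_from_probs(probs, rep$goal, reg_label) - eps
  tbl <- rep$goal$regions_tbl
  if (tbl$waypoint[match(reg_label, tbl$label)]) {
    goal_labels <- tbl$label[!tbl$waypoint]
    if (length(goal_labels) > 0L) {
      gs <- vapply(goal_labels,
                   function(l) score_from_probs(probs, rep$goal, l), 0.0)
      m <- min(m, eps - max(gs))
    }
  }
  m
}

# Deterministic Nelder-Mead polish of a grid minimizer: minimize complexity
# subject to staying inside the state, via a smooth penalty; the refined
# point is pulled back to the feasible set by bisection toward the (feasible)
# grid start and accepted only if it is a member with strictly smaller
# complexity.
refine_projection <- function(start, rep, cfg, anchor, label,
                              tol = 1e-6, maxit = 200L) {
  dom <- rep$domain
  obj <- function(par) {
    mu <- par[1L]; sigma <- par[2L]
    if (sigma < dom$sigma_min || sigma > dom$sigma_max ||
        mu < dom$mu_min || mu > dom$mu_max) {
      return(Inf)
    }
    comp <- complexity_values(tibble(mu = mu, sigma = sigma), cfg,
                              rep$env, anchor)
    margin <- membership_margin(mu, sigma, rep, label)
    comp + 1e3 * max(0, -margin)
  }
  fit <- optim(c(start$mu, start$sigma), obj, method = "Nelder-Mead",
               control = list(reltol = tol, maxit = maxit))
  cand <- tibble(mu = fit$par[1L], sigma = fit$par[2L])
  if (membership_margin(cand$mu, cand$sigma, rep, label) < 0) {
    # bisect along the segment back to the feasible grid start
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      mu <- cand$mu + mid * (start$mu - cand$mu)
      sigma <- cand$sigma + mid * (start$sigma - cand$sigma)
      if (membership_margin(mu, sigma, rep, label) >= 0) hi <- mid else lo <- mid
    }
    cand <- tibble(mu = cand$mu + hi * (start$mu - cand$mu),
                   sigma = cand$sigma + hi * (start$sigma - cand$sigma))
  }
  comp <- complexity_values(cand, cfg, rep$env, anchor)
  if (is.finite(comp) && comp < start$complexity &&
      membership_margin(cand$mu, cand$sigma, rep, label) >= 0) {
    tibble(mu = cand$mu, sigma = cand$sigma, complexity = comp)
  } else {
    start
  }
}

#' Information projection of the default policy onto a telic state
#'
#' Returns the member of the state minimizing policy complexity -- the state
#' member closest to the default policy in the configured divergence.  The
#' minimizer is found by exhaustive search over the state's grid members,
#' optionally followed by a deterministic derivative-free local polish
#' (parameter tolerance `1e-6`, bounded iterations) constrained to stay
#' inside the state; the polished point is kept only when it strictly
#' improves on the grid optimum.  Grid ties are broken by smaller
#' `|mu - mu0|`, then smaller `sigma`, then smaller `mu`.
#'
#' @param rep A [build_representation()] result.
#' @param state State label (e.g. `"SR"`).
#' @param cfg A [complexity_config()].
#' @param anchor Optional policy overriding the configured default.
#' @param refine Run the continuous polish after the grid search
#'   (default `TRUE`).
#' @return A one-row tibble: `state`, `mu`, `sigma`, `complexity`, `refined`.
#' @export
information_projection <- function(rep, state, cfg, anchor = NULL,
                                   refine = TRUE) {
  stopifnot(inherits(rep, "telic_representation"),
            inherits(cfg, "complexity_config"))
  anchor <- if (is.null(anchor)) cfg$default_policy else as_policy(anchor)
  members <- state_members(rep, state)
  if (nrow(members) == 0L) {
    abort(sprintf("telic state `%s` has no members on the grid.", state),
          class = c("telic_empty_state", "telic_error"))
  }
  comp <- complexity_values(members, cfg, rep$env, anchor)
  ord <- order(comp, abs(members$mu - anchor$mu), members$sigma, members$mu)
  best <- ord[1L]
  out <- tibble(mu = members$mu[best], sigma = members$sigma[best],
                complexity = comp[best])
  refined <- FALSE
  if (refine) {
    polished <- refine_projection(out, rep, cfg, anchor, state)
    refined <- polished$complexity < out$complexity
    out <- polished
  }
  tibble(state = state, mu = out$mu, sigma = out$sigma,
         complexity = out$complexity, refined = refined)
}

#' Is a telic state reachable under a capacity bound?
#'
#' A state is reachable when the complexity of the information projection of
#' the default policy onto it does not exceed the capacity `delta`; the
#' projection is then a witness policy the agent can actually adopt.
#'
#' @inheritParams information_projection
#' @param bound A [capacity_bound()].
#' @return A one-row tibble: `state`, `reachable`, and the projection's
#'   `mu`, `sigma`, `complexity` (the witness when reachable).
#' @export
is_reachable <- function(rep, state, cfg, bound, anchor = NULL,
                         refine = TRUE) {
  stopifnot(inherits(bound, "capacity_bound"))
  proj <- information_projection(rep, state, cfg, anchor = anchor,
                                 refine = refine)
  tibble(state = state, reachable = proj$complexity <= bound$delta,
         mu = proj$mu, sigma = proj$sigma, complexity = proj$complexity)
}

# Distance from a candidate anchor position to a state: min over state
# members m of KL(m || candidate), at the configured level/base (forward
# member-to-candidate divergence regardless of cfg$direction, matching the
# projection objective).  `members_*` are precomputed law parameters.
dist_to_state <- function(cand_mean, cand_sd, members_mean, members_sd,
                          base, scale) {
  scale * min(kl_gaussian(members_mean, members_sd, cand_mean, cand_sd,
                          base = base))
}

# Law parameters (mean, sd, KL scale factor) at the configured level.
level_params <- function(policies, cfg, env) {
  if (cfg$level == "endpoint") {
    c(endpoint_params(policies$mu, policies$sigma, env), list(scale = 1))
  } else {
    c(step_params(policies$mu, policies$sigma, env),
      list(scale = env$horizon))
  }
}

#' Capacity-bounded policy nearest to a telic state
#'
#' Over the feasible set of grid policies whose complexity (relative to the
#' anchor) is at most `delta`, returns the one minimizing the distance to the
#' target state -- by default the smallest KL divergence from any state
#' member to the candidate, at the configured level and base.  When the state
#' is already reachable the information projection itself is returned with
#' distance zero.  Ties are broken by smaller complexity, then smaller
#' `|mu - mu0|`, then smaller `sigma`.  The anchor is always a feasible
#' candidate, so the feasible set is never empty (at `delta = 0` the distance
#' is evaluated at the anchor exactly).
#'
#' @inheritParams is_reachable
#' @param distance `"kl"` (default) or `"score_shortfall"` (the gap
#'   `epsilon - score` toward the target region, clamped at zero).
#' @return A one-row tibble: `state`, `mu`, `sigma`, `complexity` (relative
#'   to the anchor, `<= delta`), `distance`.
#' @export
nearest_feasible_policy <- function(rep, state, cfg, bound, anchor = NULL,
                                    distance = c("kl", "score_shortfall"),
                                    refine = TRUE) {
  stopifnot(inherits(rep, "telic_representation"),
            inherits(cfg, "complexity_config"),
            inherits(bound, "capacity_bound"))
  distance <- match.arg(distance)
  anchor <- if (is.null(anchor)) cfg$default_policy else as_policy(anchor)
  members <- state_members(rep, state)
  if (nrow(members) == 0L) {
    abort(sprintf("telic state `%s` has no members on the grid.", state),
          class = c("telic_empty_state", "telic_error"))
  }
  proj <- information_projection(rep, state, cfg, anchor = anchor,
                                 refine = refine)
  if (proj$complexity <= bound$delta) {
    return(tibble(state = state, mu = proj$mu, sigma = proj$sigma,
                  complexity = proj$complexity, distance = 0))
  }
  grid <- rep$assignments[, c("mu", "sigma")]
  # the anchor itself is always feasible, even off-grid
  cand <- dplyr::distinct(bind_rows(grid, anchor))
  comp <- complexity_values(cand, cfg, rep$env, anchor)
  feasible <- comp <= bound$delta
  cand <- cand[feasible, , drop = FALSE]
  comp <- comp[feasible]
  if (distance == "kl") {
    mp <- level_params(members, cfg, rep$env)
    cp <- level_params(cand, cfg, rep$env)
    d <- vapply(seq_len(nrow(cand)), function(i) {
      dist_to_state(cp$mean[i], cp$sd[i], mp$mean, mp$sd,
                    cfg$base, cp$scale)
    }, 0.0)
  } else {
    reg_label <- region_of_state(rep, state)
    probs <- region_prob_matrix(cand, rep$goal, rep$env, rep$est)
    d <- pmax(0, rep$rule$epsilon - score_from_probs(probs, rep$goal,
                                                     reg_label))
  }
  ord <- order(d, comp, abs(cand$mu - anchor$mu), cand$sigma, cand$mu)
  best <- ord[1L]
  tibble(state = state, mu = cand$mu[best], sigma = cand$sigma[best],
         complexity = comp[best], distance = d[best])
}
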