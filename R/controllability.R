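#' Hop budget for controllability chains
#'
#' @param n_hops Maximum number of intermediate re-anchorings `N` allowed on
#'   the way to a telic state (non-negative integer).  `N = 0` demands direct
#'   reachability; `N = 1` allows one intermediate waypoint (e.g. the chain
#'   default -> S_M -> S_R).
#' @return An object of class `hop_budget`.
#' @export
hop_budget <- function(n_hops = 1) {
  n_hops <- check_count(n_hops, "n_hops", lower = 0L)
  structure(list(n_hops = n_hops), class = "hop_budget")
}

# Recursive chain search: can `label` be reached from `anchor` within `depth`
# intermediate hops, every leg costing at most delta?  A direct leg lands on
# the information projection of the anchor onto the state.  An intermediate
# hop lands on the member of a *non-residual* telic state that, among grid
# policies within capacity of the anchor, is nearest the target; residual
# policies are not valid anchors (chains transition between telic states).
# Each hop must strictly reduce the distance to the target, which guarantees
# termination and keeps the search deterministic.
reach_chain <- function(rep, label, cfg, bound, anchor, depth,
                        refine = TRUE) {
  proj <- tryCatch(
    information_projection(rep, label, cfg, anchor = anchor, refine = refine),
    telic_empty_state = function(e) NULL
  )
  if (is.null(proj)) {
    return(list(reachable = FALSE, gap = Inf, chain = NULL))
  }
  if (proj$complexity <= bound$delta) {
    chain <- tibble(leg = 1L, mu = proj$mu, sigma = proj$sigma,
                    complexity = proj$complexity, landing = label)
    return(list(reachable = TRUE, gap = 0, chain = chain))
  }
  fail <- list(reachable = FALSE, gap = proj$complexity, chain = NULL)
  if (depth <= 0L) return(fail)
  # candidate waypoints: within-capacity grid members of non-residual states
  cand <- rep$assignments[rep$assignments$state != "S0", , drop = FALSE]
  if (nrow(cand) == 0L) return(fail)
  comp <- complexity_values(cand, cfg, rep$env, anchor)
  feasible <- comp <= bound$delta
  if (!any(feasible)) return(fail)
  cand <- cand[feasible, , drop = FALSE]
  comp <- comp[feasible]
  members <- state_members(rep, label)
  mp <- level_params(members, cfg, rep$env)
  cp <- level_params(cand, cfg, rep$env)
  d <- vapply(seq_len(nrow(cand)), function(i) {
    dist_to_state(cp$mean[i], cp$sd[i], mp$mean, mp$sd, cfg$base, cp$scale)
  }, 0.0)
  ord <- order(d, comp, abs(cand$mu - anchor$mu), cand$sigma, cand$mu)
  best <- ord[1L]
  # progress check: the hop must bring the agent strictly closer
  ap <- level_params(anchor, cfg, rep$env)
  d_anchor <- dist_to_state(ap$mean, ap$sd, mp$mean, mp$sd, cfg$base,
                            ap$scale)
  if (d[best] >= d_anchor - 1e-12) return(fail)
  w_policy <- policy(cand$mu[best], cand$sigma[best])
  sub <- reach_chain(rep, label, cfg, bound, w_policy, depth - 1L,
                     refine = refine)
  if (!sub$reachable) return(fail)
  leg <- tibble(leg = 1L, mu = w_policy$mu, sigma = w_policy$sigma,
                complexity = comp[best], landing = cand$state[best])
  chain <- bind_rows(leg, sub$chain)
  chain$leg <- seq_len(nrow(chain))
  list(reachable = TRUE, gap = 0, chain = chain)
}

#' Test telic controllability of a representation
#'
#' A representation is telic controllable, with respect to a default policy,
#' a capacity `delta` and a hop budget `N`, when every non-residual telic
#' state can be reached from the default policy by a chain of at most `N + 1`
#' policy changes, each leg landing inside a telic state of the
#' representation and costing at most `delta` of complexity relative to the
#' previous anchor.  A direct leg lands on the information projection of the
#' anchor onto the target state; an intermediate hop re-anchors on the member
#' of a non-residual telic state that, among within-capacity grid policies,
#' is nearest the target (after a repair, this is a member of the inserted
#' waypoint state).  Residual policies are not valid intermediate anchors:
#' chains transition between telic states.  Empty goal states are reported
#' unreachable.
#'
#' @param rep A [build_representation()] result.
#' @param cfg A [complexity_config()]; its default policy is the chain start
#'   unless `anchor` overrides it.
#' @param bound A [capacity_bound()].
#' @param hops A [hop_budget()].
#' @param anchor Optional starting policy overriding the configured default.
#' @param refine Passed to [information_projection()].
#' @return An object of class `telic_controllability`: a list with
#'   `controllable` (logical), `per_state` (tibble: `state`, `reachable`,
#'   `n_legs`, `gap` -- the projection complexity left unmet when
#'   unreachable), and `chains` (named list of per-leg tibbles).
#' @export
is_telic_controllable <- function(rep, cfg, bound, hops = hop_budget(0),
                                  anchor = NULL, refine = TRUE) {
  stopifnot(inherits(rep, "telic_representation"),
            inherits(cfg, "complexity_config"),
            inherits(bound, "capacity_bound"),
            inherits(hops, "hop_budget"))
  anchor <- if (is.null(anchor)) cfg$default_policy else as_policy(anchor)
  labels <- setdiff(rep$counts$state, "S0")
  res <- lapply(labels, function(l) {
    reach_chain(rep, l, cfg, bound, anchor, hops$n_hops, refine = refine)
  })
  names(res) <- labels
  per_state <- tibble(
    state = labels,
    reachable = unname(vapply(res, `[[`, TRUE, "reachable")),
    n_legs = unname(vapply(res, function(r) {
      if (is.null(r$chain)) NA_integer_ else nrow(r$chain)
    }, 0L)),
    gap = unname(vapply(res, `[[`, 0.0, "gap"))
  )
  structure(
    list(controllable = all(per_state$reachable),
         per_state = per_state,
         chains = lapply(res, `[[`, "chain"),
         delta = bound$delta, n_hops = hops$n_hops,
         anchor = anchor),
    class = "telic_controllability"
  )
}

#' @export
print.telic_controllability <- function(x, ...) {
  cat(sprintf(
    "<telic_controllability> %s (delta = %g, N = %d, anchor (%g, %g))\n",
    if (x$controllable) "controllable" else "NOT controllable",
    x$delta, x$n_hops, x$anchor$mu, x$anchor$sigma))
  print(x$per_state)
  invisible(x)
}

#' @describeIn is_telic_controllable `tidy()` returns the per-state table.
#' @param x A `telic_controllability`.
#' @param ... Unused.
#' @export
tidy.telic_controllability <- function(x, ...) x$per_state

#' @describeIn is_telic_controllable `glance()` returns a one-row summary.
#' @export
glance.telic_controllability <- function(x, ...) {
  tibble(controllable = x$controllable,
         n_states = nrow(x$per_state),
         n_unreachable = sum(!x$per_state$reachable),
         delta = x$delta, n_hops = x$n_hops)
}

# First region label in M, M2, M3, ... not already used by the goal.
next_waypoint_label <- function(goal) {
  used <- goal$regions_tbl$label
  cand <- c("M", paste0("M", 2:99))
  cand[!cand %in% used][1L]
}

#' Split an unreachable telic state by inserting a waypoint state
#'
#' Computes the capacity-bounded policy nearest the target state
#' ([nearest_feasible_policy()]), then inserts a new waypoint region of the
#' target's width centred at that policy's terminal-position mean and
#' rebuilds the representation.  The inserted waypoint state contains the
#' waypoint policy itself (whose complexity is within the capacity), so the
#' projection of the current default onto the new state is always within
#' `delta` -- this is asserted.  Existing goal states are untouched: waypoint
#' regions do not compete in their preference scores, so the split only
#' carves the new state out of the residual `S0`.
#'
#' @inheritParams is_reachable
#' @param anchor Optional current default policy overriding the configured
#'   one.
#' @return A new `telic_representation` with one more state, carrying
#'   attributes `inserted` (the new state label) and `waypoint` (the policy
#'   the new region is centred on).
#' @export
split_state <- function(rep, state, cfg, bound, anchor = NULL,
                        refine = TRUE) {
  stopifnot(inherits(rep, "telic_representation"),
            inherits(bound, "capacity_bound"))
  anchor <- if (is.null(anchor)) cfg$default_policy else as_policy(anchor)
  proj <- information_projection(rep, state, cfg, anchor = anchor,
                                 refine = refine)
  if (proj$complexity <= bound$delta) {
    abort(sprintf(
      "state `%s` is already reachable (complexity %.4f <= delta %.4f); no split needed.",
      state, proj$complexity, bound$delta),
      class = c("telic_split_not_needed", "telic_error"))
  }
  w <- nearest_feasible_policy(rep, state, cfg, bound, anchor = anchor,
                               refine = refine)
  reg_label <- region_of_state(rep, state)
  tbl <- rep$goal$regions_tbl
  width <- tbl$width[match(reg_label, tbl$label)]
  ep <- endpoint_params(w$mu, w$sigma, rep$env)
  new_label <- next_waypoint_label(rep$goal)
  regions <- rep$goal$regions
  regions[[new_label]] <- region(ep$mean, width)
  goal2 <- goal_spec(regions, target = rep$goal$target,
                     reach_mode = rep$goal$reach_mode,
                     waypoints = c(tbl$label[tbl$waypoint], new_label))
  rep2 <- build_representation(goal2, rep$rule, rep$env, rep$domain, rep$est)
  new_state <- state_label(new_label)
  if (sum(rep2$assignments$state == new_state) == 0L) {
    abort(sprintf("inserted state `%s` has no members on the grid.",
                  new_state),
          class = c("telic_degenerate_split", "telic_error"))
  }
  proj_new <- information_projection(rep2, new_state, cfg, anchor = anchor,
                                     refine = FALSE)
  if (proj_new$complexity > bound$delta) {
    abort(sprintf(
      "split postcondition failed: projection onto `%s` costs %.4f > delta %.4f.",
      new_state, proj_new$complexity, bound$delta),
      class = c("telic_degenerate_split", "telic_error"))
  }
  attr(rep2, "inserted") <- new_state
  attr(rep2, "waypoint") <- policy(w$mu, w$sigma)
  rep2
}

#' Refine a representation until it is telic controllable
#'
#' Repeatedly: test controllability; if it fails, take the unreachable state
#' whose information-projection complexity (from the current default) is
#' smallest, split it by inserting a waypoint state ([split_state()]), and
#' re-anchor the default policy.  The default re-anchoring adopts the
#' capacity-bounded waypoint policy itself as the new default (the policy the
#' inserted region is centred on); `reanchor = "projection"` instead adopts
#' the information projection of the current default onto the inserted
#' state.  Controllability is always judged from the original default policy
#' with the given hop budget.  Each split must strictly reduce the distance
#' from the current default chain to the state being repaired, otherwise a
#' non-convergence error (class `telic_no_convergence`, carrying the partial
#' result in its `result` field) is raised; the same error is raised when
#' `max_iter` splits do not suffice.
#'
#' @inheritParams is_telic_controllable
#' @param max_iter Maximum number of splits (default 10).
#' @param reanchor `"waypoint"` (default) or `"projection"`.
#' @return An object of class `telic_refinement`: list with `representations`
#'   (initial ... final), `anchors` (tibble of the default-policy chain with
#'   per-leg complexities), `inserted_states`, `iterations`, and the final
#'   controllability `report`.
#' @export
refine_until_controllable <- function(rep, cfg, bound, hops = hop_budget(1),
                                      max_iter = 10,
                                      reanchor = c("waypoint", "projection"),
                                      refine = TRUE) {
  reanchor <- match.arg(reanchor)
  max_iter <- check_count(max_iter, "max_iter", lower = 1L)
  pi0 <- cfg$default_policy
  anchors <- mutate(pi0, step = 0L, leg_complexity = 0)
  reps <- list(rep)
  inserted <- character()
  cur_anchor <- pi0
  prev_gap <- Inf
  for (iter in 0:max_iter) {
    report <- is_telic_controllable(rep, cfg, bound, hops, anchor = pi0,
                                    refine = refine)
    if (report$controllable) {
      return(structure(
        list(representations = reps, anchors = anchors,
             inserted_states = inserted, iterations = iter,
             report = report),
        class = "telic_refinement"))
    }
    if (iter == max_iter) break
    # repair the unreachable state with the smallest projection complexity
    # from the current (possibly re-anchored) default
    unreach <- report$per_state$state[!report$per_state$reachable]
    gaps <- vapply(unreach, function(l) {
      p <- tryCatch(
        information_projection(rep, l, cfg, anchor = cur_anchor,
                               refine = refine),
        telic_empty_state = function(e) NULL)
      if (is.null(p)) Inf else p$complexity
    }, 0.0)
    target <- unreach[which.min(gaps)]
    if (!is.finite(min(gaps)) || min(gaps) >= prev_gap - 1e-12) {
      abort("refinement is not making progress; aborting.",
            class = c("telic_no_convergence", "telic_error"),
            result = list(representations = reps, anchors = anchors,
                          inserted_states = inserted, iterations = iter))
    }
    prev_gap <- min(gaps)
    partial <- list(representations = reps, anchors = anchors,
                    inserted_states = inserted, iterations = iter)
    rep <- tryCatch(
      split_state(rep, target, cfg, bound, anchor = cur_anchor,
                  refine = refine),
      telic_split_not_needed = function(e) {
        # the target is within capacity of the re-anchored default already;
        # only the hop budget stands in the way, so splitting cannot help
        abort(paste0("`", target, "` is reachable from the re-anchored ",
                     "default but not within the hop budget; ",
                     "splitting cannot make progress."),
              class = c("telic_no_convergence", "telic_error"),
              result = partial)
      })
    new_state <- attr(rep, "inserted")
    new_anchor <- if (reanchor == "waypoint") {
      attr(rep, "waypoint")
    } else {
      p <- information_projection(rep, new_state, cfg, anchor = cur_anchor,
                                  refine = refine)
      policy(p$mu, p$sigma)
    }
    leg <- complexity_values(new_anchor, cfg, rep$env, cur_anchor)
    anchors <- bind_rows(anchors,
                         mutate(new_anchor, step = nrow(anchors),
                                leg_complexity = leg))
    reps <- c(reps, list(rep))
    inserted <- c(inserted, new_state)
    cur_anchor <- new_anchor
  }
  abort(sprintf("not telic controllable after %d splits.", max_iter),
        class = c("telic_no_convergence", "telic_error"),
        result = list(representations = reps, anchors = anchors,
                      inserted_states = inserted, iterations = max_iter))
}

#' @export
print.telic_refinement <- function(x, ...) {
  cat(sprintf(
    "<telic_refinement> %d split(s); inserted: %s; final %s\n",
    x$iterations,
    if (length(x$inserted_states)) paste(x$inserted_states, collapse = ", ")
    else "none",
    if (x$report$controllable) "controllable" else "NOT controllable"))
  print(x$anchors)
  invisible(x)
}

#' @describeIn refine_until_controllable `tidy()` returns the anchor chain
#'   with per-leg complexities.
#' @param x A `telic_refinement`.
#' @param ... Unused.
#' @export
tidy.telic_refinement <- function(x, ...) x$anchors

#' @describeIn refine_until_controllable `glance()` returns a one-row
#'   summary.
#' @export
glance.telic_refinement <- function(x, ...) {
  final <- x$representations[[length(x$representations)]]
  tibble(iterations = x$iterations,
         controllable = x$report$controllable,
         n_states_final = nrow(final$counts),
         inserted = paste(x$inserted_states, collapse = ","))
}
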