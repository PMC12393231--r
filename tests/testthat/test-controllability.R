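# The shifted scenario (target region recentred at 2.5, capacity 0.25 bits)
# is the canonical repair exercise: SR is out of reach directly, and one
# inserted waypoint state restores controllability at N = 1.

test_that("a representation whose goal states contain the default is controllable at N = 0", {
  env <- environment_spec()
  cfg <- complexity_config()
  goal <- goal_spec(list(C = region(0, 2)), target = "C")
  rep <- build_representation(goal, telic_rule(0.1), env, coarse_domain())
  report <- is_telic_controllable(rep, cfg, capacity_bound(0),
                                  hop_budget(0))
  expect_true(report$controllable)
  expect_equal(report$per_state$n_legs, 1L)
  expect_equal(report$chains$SC$complexity, 0)
})

test_that("the dual-goal scenario is controllable at one bit with no hops", {
  env <- environment_spec()
  cfg <- complexity_config()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  report <- is_telic_controllable(rep, cfg, capacity_bound(1),
                                  hop_budget(0), refine = FALSE)
  expect_true(report$controllable)
  # the closed-form witness (1, 1) already certifies feasibility at 1 bit
  expect_lte(report$chains$SR$complexity, 0.5 / log(2))
  expect_true(all(tidy(report)$reachable))
  g <- glance(report)
  expect_equal(g$n_unreachable, 0L)
})

test_that("the shifted scenario is not controllable at 0.25 bits without hops", {
  env <- environment_spec()
  cfg <- complexity_config()
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              coarse_domain())
  report <- is_telic_controllable(rep, cfg, capacity_bound(0.25),
                                  hop_budget(0), refine = FALSE)
  expect_false(report$controllable)
  per <- tidy(report)
  expect_false(per$reachable[per$state == "SR"])
  expect_true(per$reachable[per$state == "SL"])
  expect_gt(per$gap[per$state == "SR"], 0.25)
})

test_that("splitting a reachable state is refused", {
  env <- environment_spec()
  cfg <- complexity_config()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  expect_error(
    split_state(rep, "SR", cfg, capacity_bound(1), refine = FALSE),
    class = "telic_split_not_needed")
})

test_that("splitting inserts a waypoint state without disturbing existing ones", {
  env <- environment_spec()
  cfg <- complexity_config()
  bound <- capacity_bound(0.25)
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              coarse_domain())
  rep2 <- split_state(rep, "SR", cfg, bound, refine = FALSE)
  expect_equal(attr(rep2, "inserted"), "SM")
  expect_setequal(rep2$counts$state, c("S0", "SR", "SL", "SM"))
  expect_gt(rep2$counts$n[rep2$counts$state == "SM"], 0L)
  # monotone repair: one more state, and the original goal states unchanged
  expect_equal(nrow(rep2$counts), nrow(rep$counts) + 1L)
  for (s in c("SR", "SL")) {
    expect_equal(rep2$assignments$state == s, rep$assignments$state == s)
  }
  # the inserted region is centred between start and the shifted target
  w <- attr(rep2, "waypoint")
  m_center <- rep2$goal$regions_tbl$center[rep2$goal$regions_tbl$label == "M"]
  expect_gt(m_center, 0)
  expect_lt(m_center, 2.5)
  expect_equal(m_center, env$start + w$mu)
  # the waypoint policy is itself a member within capacity
  expect_lte(policy_complexity(w, cfg, env)$complexity, bound$delta)
  proj_m <- information_projection(rep2, "SM", cfg, refine = FALSE)
  expect_lte(proj_m$complexity, bound$delta)
})

test_that("refinement repairs the shifted scenario with exactly one split", {
  env <- environment_spec()
  cfg <- complexity_config()
  bound <- capacity_bound(0.25)
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              coarse_domain())
  res <- refine_until_controllable(rep, cfg, bound, hop_budget(1),
                                   refine = FALSE)
  expect_s3_class(res, "telic_refinement")
  expect_equal(res$iterations, 1L)
  expect_equal(res$inserted_states, "SM")
  expect_true(res$report$controllable)
  # every re-anchoring leg respects the capacity
  expect_true(all(tidy(res)$leg_complexity <= bound$delta + 1e-12))
  # refinement soundness: an independent controllability check passes
  final <- res$representations[[length(res$representations)]]
  verify <- is_telic_controllable(final, cfg, bound, hop_budget(1),
                                  refine = FALSE)
  expect_true(verify$controllable)
  # chain validity from the report alone
  for (ch in verify$chains) {
    expect_lte(nrow(ch), 2L)            # N + 1 legs
    expect_true(all(ch$complexity <= bound$delta + 1e-12))
    expect_true(all(ch$landing != "S0"))
  }
  expect_equal(glance(res)$n_states_final, 4L)
})

test_that("an already-controllable representation refines in zero iterations", {
  env <- environment_spec()
  cfg <- complexity_config()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  res <- refine_until_controllable(rep, cfg, capacity_bound(1),
                                   hop_budget(1), refine = FALSE)
  expect_equal(res$iterations, 0L)
  expect_equal(length(res$representations), 1L)
  expect_identical(res$representations[[1]]$counts, rep$counts)
})

test_that("a generous capacity covers the whole grid without splits", {
  env <- environment_spec()
  cfg <- complexity_config()
  dom <- coarse_domain()
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              dom)
  # 10 bits exceed the grid's KL diameter from the default policy
  comp <- policy_complexity(domain_grid(dom), cfg, env)$complexity
  expect_lt(max(comp), 10)
  res <- refine_until_controllable(rep, cfg, capacity_bound(10),
                                   hop_budget(0), refine = FALSE)
  expect_equal(res$iterations, 0L)
  expect_true(res$report$controllable)
})

test_that("controllability is monotone in capacity and hop budget", {
  env <- environment_spec()
  cfg <- complexity_config()
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              coarse_domain())
  ctl <- function(delta, n) {
    is_telic_controllable(rep, cfg, capacity_bound(delta), hop_budget(n),
                          refine = FALSE)$controllable
  }
  for (n in 0:1) {
    res <- vapply(c(0.1, 0.3, 0.6, 1.5), ctl, TRUE, n = n)
    expect_true(all(diff(as.integer(res)) >= 0))
  }
  for (d in c(0.3, 0.6)) {
    expect_gte(as.integer(ctl(d, 1)), as.integer(ctl(d, 0)))
  }
})

test_that("refinement that cannot progress raises a non-convergence error", {
  env <- environment_spec()
  cfg <- complexity_config()
  # with no hop budget the repaired representation can never pass: the
  # target needs two legs, so the split brings no controllability gain
  rep <- build_representation(shifted_goal_spec(), telic_rule(0.1), env,
                              coarse_domain())
  err <- tryCatch(
    refine_until_controllable(rep, cfg, capacity_bound(0.25), hop_budget(0),
                              max_iter = 3, refine = FALSE),
    telic_no_convergence = function(e) e)
  expect_s3_class(err, "telic_no_convergence")
  expect_true(is.list(err$result))
  expect_gte(err$result$iterations, 1L)
})
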