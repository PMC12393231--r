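test_that("single policies are classified by the thresholded score rule", {
  env <- environment_spec()
  goal <- dual_goal()
  rule <- telic_rule(0.1)
  lab <- classify_policies(policy(c(1, 0, -1), 1), goal, rule, env)$state
  expect_equal(lab, c("SR", "S0", "SL"))

  # agreement with an independent reimplementation of the rule on a sweep
  sweep <- tidyr::expand_grid(mu = seq(-2.5, 2.5, by = 0.5),
                              sigma = c(0.6, 1, 1.7))
  got <- classify_policies(sweep, goal, rule, env)$state
  want <- vapply(seq_len(nrow(sweep)), function(i) {
    oracle_classify(sweep$mu[i], sweep$sigma[i], goal, 0.1, env)
  }, "")
  expect_equal(got, want)
})

test_that("the representation partitions the grid", {
  env <- environment_spec()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  expect_s3_class(rep, "telic_representation")
  expect_equal(sum(rep$counts$n), nrow(rep$assignments))
  expect_equal(nrow(rep$assignments), 61L * 31L)
  # every grid policy carries exactly one label
  expect_true(all(rep$assignments$state %in% rep$counts$state))
  expect_setequal(rep$counts$state, c("S0", "SR", "SL"))
  expect_true(all(rep$counts$n > 0L))
  # dual-goal symmetry: the two goal states have equal size
  expect_equal(rep$counts$n[rep$counts$state == "SR"],
               rep$counts$n[rep$counts$state == "SL"])

  g <- glance(rep)
  expect_equal(g$n_grid, 61L * 31L)
  expect_equal(g$epsilon, 0.1)
  expect_equal(nrow(tidy(rep)), 61L * 31L)
})

test_that("SL is the exact mu-mirror of SR on the symmetric grid", {
  env <- environment_spec()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  a <- rep$assignments
  # reverse mu within each sigma row maps (mu, sigma) -> (-mu, sigma)
  mirrored <- a |>
    dplyr::arrange(.data$sigma, dplyr::desc(.data$mu)) |>
    dplyr::pull(.data$state)
  orig <- a |>
    dplyr::arrange(.data$sigma, .data$mu) |>
    dplyr::pull(.data$state)
  swap <- c(S0 = "S0", SR = "SL", SL = "SR")
  expect_equal(unname(swap[mirrored]), orig)
})

test_that("an extreme sensitivity empties every goal state", {
  env <- environment_spec()
  rep <- build_representation(dual_goal(), telic_rule(0.999), env,
                              coarse_domain())
  expect_equal(rep$counts$n[rep$counts$state == "S0"],
               nrow(rep$assignments))
  expect_equal(rep$counts$n[rep$counts$state != "S0"], c(0L, 0L))
  # empty states are reported, not dropped, and projecting onto one errors
  expect_error(information_projection(rep, "SR", complexity_config()),
               class = "telic_empty_state")
})

test_that("goal states are nested decreasing in epsilon", {
  env <- environment_spec()
  dom <- coarse_domain()
  eps <- c(0.05, 0.1, 0.2)
  reps <- lapply(eps, function(e) {
    build_representation(dual_goal(), telic_rule(e), env, dom)
  })
  for (s in c("SR", "SL")) {
    for (i in 2:3) {
      finer <- reps[[i - 1]]$assignments$state == s
      coarser <- reps[[i]]$assignments$state == s
      expect_true(all(!coarser | finer))  # coarser (larger eps) is a subset
      expect_lte(sum(coarser), sum(finer))
    }
  }
})

test_that("goal equivalence is an equivalence relation induced by the labels", {
  env <- environment_spec()
  rep <- build_representation(dual_goal(), telic_rule(0.1), env,
                              coarse_domain())
  expect_true(goal_equivalent(c(1, 1), c(1.2, 1.1), rep))
  expect_false(goal_equivalent(c(1, 1), c(-1, 1), rep))

  probes <- list(c(0, 1), c(1, 1), c(-1, 1), c(2, 0.6), c(0.2, 1.9),
                 c(-2, 0.6))
  for (p in probes) expect_true(goal_equivalent(p, p, rep))  # reflexive
  for (p in probes) {
    for (q in probes) {
      expect_equal(goal_equivalent(p, q, rep), goal_equivalent(q, p, rep))
      for (r in probes) {  # transitivity
        if (goal_equivalent(p, q, rep) && goal_equivalent(q, r, rep)) {
          expect_true(goal_equivalent(p, r, rep))
        }
      }
    }
  }
})

test_that("degenerate rules and domains are rejected", {
  expect_error(telic_rule(0), class = "telic_validation_error")
  expect_error(telic_rule(1), class = "telic_validation_error")
  expect_error(policy_domain(sigma_min = 0), class = "telic_validation_error")
  expect_error(policy_domain(mu_min = 2, mu_max = -2),
               class = "telic_validation_error")
})
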