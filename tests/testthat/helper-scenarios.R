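# Shared scenario objects and independent closed-form oracles.  The oracles
# are deliberately written from the raw formulas (pnorm, Gaussian KL), not
# through the package's code paths.

dual_goal <- function(reach_mode = "terminal") {
  goal_spec(list(R = region(2), L = region(-2)), target = "R",
            reach_mode = reach_mode)
}

shifted_goal_spec <- function() {
  goal_spec(list(R = region(2.5), L = region(-2)), target = "R")
}

default_env <- function(...) environment_spec(...)

# a coarse grid for fast sweeps in unit tests
coarse_domain <- function() policy_domain(n_mu = 61, n_sigma = 31)

tiny_domain <- function() policy_domain(n_mu = 5, n_sigma = 5)

# --- oracles ---------------------------------------------------------------

# terminal law of (mu, sigma) under a convention
oracle_endpoint <- function(mu, sigma, env) {
  if (env$param_convention == "endpoint") {
    c(mean = env$start + mu, sd = sigma)
  } else {
    c(mean = env$start + env$horizon * mu, sd = sigma * sqrt(env$horizon))
  }
}

# P(terminal in [lower, upper]) from the normal CDF
oracle_reach <- function(mu, sigma, lower, upper, env) {
  ep <- oracle_endpoint(mu, sigma, env)
  pnorm((upper - ep["mean"]) / ep["sd"]) -
    pnorm((lower - ep["mean"]) / ep["sd"])
}

# KL(N(m1,s1^2) || N(m0,s0^2)) in nats, straight from the formula
oracle_kl_nats <- function(m1, s1, m0, s0) {
  log(s0 / s1) + (s1^2 + (m1 - m0)^2) / (2 * s0^2) - 0.5
}

# policy complexity under any of the eight convention combinations
oracle_complexity <- function(mu, sigma, mu0, sigma0, env, level, direction,
                              base) {
  if (level == "endpoint") {
    a <- oracle_endpoint(mu, sigma, env)
    b <- oracle_endpoint(mu0, sigma0, env)
    scale <- 1
  } else {
    if (env$param_convention == "endpoint") {
      a <- c(mean = mu / env$horizon, sd = sigma / sqrt(env$horizon))
      b <- c(mean = mu0 / env$horizon, sd = sigma0 / sqrt(env$horizon))
    } else {
      a <- c(mean = mu, sd = sigma)
      b <- c(mean = mu0, sd = sigma0)
    }
    scale <- env$horizon
  }
  kl <- if (direction == "forward") {
    oracle_kl_nats(a["mean"], a["sd"], b["mean"], b["sd"])
  } else {
    oracle_kl_nats(b["mean"], b["sd"], a["mean"], a["sd"])
  }
  unname(scale * if (base == "bits") kl / log(2) else kl)
}

# classify one policy of a two-region goal by the score rule (single tier)
oracle_classify <- function(mu, sigma, goal, eps, env) {
  tbl <- goal$regions_tbl
  p <- vapply(seq_len(nrow(tbl)), function(j) {
    unname(oracle_reach(mu, sigma, tbl$lower[j], tbl$upper[j], env))
  }, 0.0)
  names(p) <- tbl$label
  sc <- vapply(tbl$label, function(l) {
    others <- setdiff(tbl$label, l)
    if (length(others) == 0L) p[l] else p[l] - max(p[others])
  }, 0.0)
  best <- which.max(sc)
  if (sc[best] >= eps) paste0("S", tbl$label[best]) else "S0"
}
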