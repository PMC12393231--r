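#' Gaussian random-walk policies
#'
#' A policy is a point \eqn{(\mu, \sigma)} in the two-parameter family of
#' open-loop Gaussian random walks.  How the pair maps onto the per-step law
#' depends on the environment's parameter convention (see
#' [environment_spec()]): under the `"endpoint"` convention the terminal
#' position after `horizon` steps is exactly \eqn{N(start + \mu, \sigma^2)};
#' under `"per_step"` each step is \eqn{N(\mu, \sigma^2)}.
#'
#' @param mu Drift parameter(s), in position units.
#' @param sigma Dispersion parameter(s), positive, in position units.
#' @return A tibble with columns `mu` and `sigma`, one row per policy.
#' @examples
#' policy(0, 1)                      # the canonical default policy
#' policy(c(-1, 0, 1), 1)            # three policies sharing sigma
#' @export
policy <- function(mu, sigma) {
  p <- tibble(mu = as.numeric(mu), sigma = as.numeric(sigma))
  validate_policies(p)
  p
}

#' Reflect a policy about the start position
#'
#' Returns the policy with the sign of `mu` flipped.  Under either parameter
#' convention the terminal-position law of the mirrored policy is the
#' reflection, about the start position, of the original law; the mirror is an
#' involution.
#'
#' @param policies A data frame of policies (columns `mu`, `sigma`).
#' @return A tibble of the same shape with `mu` negated.
#' @export
mirror_policy <- function(policies) {
  validate_policies(policies)
  mutate(as_tibble(policies), mu = -.data$mu)
}

#' Environment for the 1-D random-walk navigation task
#'
#' Time is discrete with unit steps; positions are unbounded reals (no walls
#' or absorption).  `param_convention` fixes how a policy's \eqn{(\mu,
#' \sigma)} parameterize the step law:
#' \describe{
#'   \item{`"endpoint"`}{each step is \eqn{N(\mu/T, \sigma^2/T)}, so the
#'     terminal position is exactly \eqn{N(start + \mu, \sigma^2)}.  This is
#'     the default: the worked scenarios place goal regions at terminal
#'     displacements of about 2 units, which is geometrically coherent only
#'     when \eqn{\mu} lives on the terminal scale.}
#'   \item{`"per_step"`}{each step is \eqn{N(\mu, \sigma^2)}, so the terminal
#'     position is \eqn{N(start + T\mu, T\sigma^2)}.}
#' }
#'
#' @param horizon Number of steps `T` (positive integer).
#' @param start Initial position (default 0).
#' @param param_convention `"endpoint"` (default) or `"per_step"`.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(horizon = 30,
                             start = 0,
                             param_convention = c("endpoint", "per_step")) {
  horizon <- check_count(horizon, "horizon", lower = 1L)
  start <- check_number(start, "start")
  param_convention <- match.arg(param_convention)
  structure(
    list(horizon = horizon, start = start,
         param_convention = param_convention),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf("<environment_spec> horizon = %d, start = %g, convention = %s\n",
              x$horizon, x$start, x$param_convention))
  invisible(x)
}

# Mean/sd of the terminal-position law for each policy row.
endpoint_params <- function(mu, sigma, env) {
  if (env$param_convention == "endpoint") {
    list(mean = env$start + mu, sd = sigma)
  } else {
    list(mean = env$start + env$horizon * mu,
         sd = sigma * sqrt(env$horizon))
  }
}

# Mean/sd of the single-step law for each policy row.
step_params <- function(mu, sigma, env) {
  if (env$param_convention == "endpoint") {
    list(mean = mu / env$horizon, sd = sigma / sqrt(env$horizon))
  } else {
    list(mean = mu, sd = sigma)
  }
}

#' Exact terminal-position distribution of a policy
#'
#' Returns the closed-form Gaussian law of the position after `horizon` steps
#' (the sum of `horizon` i.i.d. Gaussian steps, plus the start position).
#'
#' @param policies A data frame of policies (columns `mu`, `sigma`).
#' @param env An [environment_spec()].
#' @return The input tibble with columns `mean` and `sd` appended, one row per
#'   policy: the terminal position is `N(mean, sd^2)`.
#' @examples
#' endpoint_distribution(policy(0, 1), environment_spec(30, 0, "per_step"))
#' # mean 0, sd sqrt(30)
#' @export
endpoint_distribution <- function(policies, env) {
  validate_policies(policies)
  stopifnot(inherits(env, "environment_spec"))
  ep <- endpoint_params(policies$mu, policies$sigma, env)
  mutate(as_tibble(policies), mean = ep$mean, sd = ep$sd)
}

#' Simulate a batch of random-walk trajectories
#'
#' Draws `n` independent trajectories of length `horizon` from a single
#' policy's step law.  Each row starts at `env$start`; column `t0` is the
#' start, `tT` the terminal position.  The draw is fully determined by `seed`
#' (the global RNG state is left untouched).
#'
#' @param policies A single policy (one-row data frame, or `c(mu, sigma)`).
#' @param env An [environment_spec()].
#' @param n Number of trajectories (positive integer).
#' @param seed Integer RNG seed.
#' @return A tibble with `n` rows and columns `t0 ... t<horizon>`, carrying
#'   attributes `policy`, `env` and `seed`; class `trajectory_batch`.
#' @export
sample_trajectories <- function(policies, env, n = 500, seed = 1L) {
  p <- as_policy(policies)
  stopifnot(inherits(env, "environment_spec"))
  n <- check_count(n, "n", lower = 1L)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  sp <- step_params(p$mu, p$sigma, env)
  steps <- withr::with_seed(seed, {
    matrix(rnorm(n * env$horizon, mean = sp$mean, sd = sp$sd),
           nrow = n, ncol = env$horizon)
  })
  pos <- cbind(env$start, env$start + t(apply(steps, 1L, cumsum)))
  if (env$horizon == 1L) pos <- cbind(env$start, env$start + steps)
  colnames(pos) <- paste0("t", 0:env$horizon)
  out <- as_tibble(as.data.frame(pos))
  attr(out, "policy") <- p
  attr(out, "env") <- env
  attr(out, "seed") <- seed
  class(out) <- c("trajectory_batch", class(out))
  out
}

#' Terminal positions of a trajectory batch
#'
#' @param batch A [sample_trajectories()] result.
#' @return Numeric vector of final positions, one per trajectory.
#' @export
terminal_positions <- function(batch) {
  stopifnot(inherits(batch, "trajectory_batch"))
  batch[[ncol(batch)]]
}

#' Write a trajectory batch to CSV with a JSON metadata sidecar
#'
#' The CSV has one row per trajectory and columns `t0 ... tT`; the sidecar
#' (`<path>.json`) records the generating policy, environment and seed so the
#' batch can be regenerated bit-for-bit.
#'
#' @param batch A [sample_trajectories()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(batch, path) {
  stopifnot(inherits(batch, "trajectory_batch"))
  write.csv(as.data.frame(batch), path, row.names = FALSE)
  env <- attr(batch, "env")
  meta <- list(
    policy = as.list(attr(batch, "policy")),
    env = list(horizon = env$horizon, start = env$start,
               param_convention = env$param_convention),
    seed = attr(batch, "seed"),
    n = nrow(batch)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a trajectory batch
#'
#' Draws every trajectory as a line over time, optionally colouring the ones
#' whose terminal position lands inside each goal region.
#'
#' @param batch A [sample_trajectories()] result.
#' @param goal Optional [goal_spec()]; trajectories ending inside a region are
#'   coloured by region label.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(batch, goal = NULL, alpha = 0.2) {
  stopifnot(inherits(batch, "trajectory_batch"))
  df <- as_tibble(as.data.frame(batch))
  df$.trajectory <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -".trajectory",
                              names_to = "t", values_to = "position")
  long$t <- as.integer(sub("^t", "", long$t))
  long$outcome <- "none"
  if (!is.null(goal)) {
    term <- terminal_positions(batch)
    regions <- goal$regions_tbl
    lab <- rep("none", length(term))
    for (i in seq_len(nrow(regions))) {
      inside <- term >= regions$lower[i] & term <= regions$upper[i]
      lab[inside] <- regions$label[i]
    }
    long$outcome <- lab[long$.trajectory]
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$t,
                                     group = .data$.trajectory,
                                     colour = .data$outcome)) +
    ggplot2::geom_path(alpha = alpha) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position", y = "time step", colour = "reached") +
    ggplot2::theme_minimal()
}
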