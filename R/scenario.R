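# Scenario files: YAML (or JSON) for authoring, JSON for machine output.
# Unknown keys are rejected; every default is explicit after loading, so a
# load -> save -> load round trip is the identity.

scenario_defaults <- function() {
  list(
    name = "scenario",
    env = list(horizon = 30, start = 0, param_convention = "endpoint"),
    goal = list(
      regions = list(R = list(center = 2, width = 1),
                     L = list(center = -2, width = 1)),
      target = "R", reach_mode = "terminal", waypoints = list()
    ),
    rule = list(epsilon = 0.1),
    complexity = list(default_policy = list(mu = 0, sigma = 1),
                      level = "endpoint", direction = "forward",
                      base = "bits"),
    bound = list(delta = 1),
    hops = list(n_hops = 1),
    domain = list(mu_min = -3, mu_max = 3, sigma_min = 0.5, sigma_max = 2,
                  n_mu = 301, n_sigma = 151),
    estimator = list(method = "analytic", n_mc = 1e5),
    seeds = list(trajectories = 1, estimator = 1),
    n_trajectories = 500,
    epsilons = signif(exp(seq(log(1e-4), log(0.5), length.out = 25)), 6),
    deltas = seq(0, 8, by = 0.25)
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop_invalid(sprintf("unknown key(s) in %s: %s",
                         where, paste(extra, collapse = ", ")),
                 class = "telic_schema_error")
  }
}

# Fill defaults (recursively for the fixed sub-sections) and reject unknown
# keys with field-level messages.
normalize_scenario <- function(raw) {
  if (!is.list(raw) || length(raw) == 0L) {
    stop_invalid("scenario file is empty or not a mapping.",
                 class = "telic_schema_error")
  }
  d <- scenario_defaults()
  check_keys(raw, names(d), "scenario")
  sections <- c("env", "goal", "rule", "complexity", "bound", "hops",
                "domain", "estimator", "seeds")
  for (s in sections) {
    if (!is.null(raw[[s]])) {
      if (!is.list(raw[[s]])) {
        stop_invalid(sprintf("`%s` must be a mapping.", s),
                     class = "telic_schema_error")
      }
      check_keys(raw[[s]], names(d[[s]]), s)
      if (s == "goal") {
        # regions replace wholesale; other goal keys fill individually
        if (!is.null(raw$goal$regions)) d$goal$regions <- raw$goal$regions
        for (k in setdiff(names(d$goal), "regions")) {
          if (!is.null(raw$goal[[k]])) d$goal[[k]] <- raw$goal[[k]]
        }
      } else if (s == "complexity") {
        if (!is.null(raw$complexity$default_policy)) {
          check_keys(raw$complexity$default_policy, c("mu", "sigma"),
                     "complexity.default_policy")
          d$complexity$default_policy <- raw$complexity$default_policy
        }
        for (k in setdiff(names(d$complexity), "default_policy")) {
          if (!is.null(raw$complexity[[k]])) {
            d$complexity[[k]] <- raw$complexity[[k]]
          }
        }
      } else {
        d[[s]] <- modifyList(d[[s]], raw[[s]])
      }
    }
  }
  for (k in c("name", "n_trajectories", "epsilons", "deltas")) {
    if (!is.null(raw[[k]])) d[[k]] <- raw[[k]]
  }
  d$epsilons <- as.numeric(unlist(d$epsilons))
  d$deltas <- as.numeric(unlist(d$deltas))
  for (rl in names(d$goal$regions)) {
    check_keys(d$goal$regions[[rl]], c("center", "width"),
               sprintf("goal.regions.%s", rl))
  }
  d
}

# Instantiate validated package objects from a normalized scenario list.
build_scenario <- function(d) {
  regions <- lapply(d$goal$regions, function(r) {
    region(r$center, r$width %||% 1)
  })
  structure(
    list(
      name = as.character(d$name),
      env = environment_spec(d$env$horizon, d$env$start,
                             d$env$param_convention),
      goal = goal_spec(regions, target = d$goal$target,
                       reach_mode = d$goal$reach_mode,
                       waypoints = unlist(d$goal$waypoints) %||% character()),
      rule = telic_rule(d$rule$epsilon),
      cfg = complexity_config(
        policy(d$complexity$default_policy$mu,
               d$complexity$default_policy$sigma),
        level = d$complexity$level,
        direction = d$complexity$direction,
        base = d$complexity$base),
      bound = capacity_bound(d$bound$delta),
      hops = hop_budget(d$hops$n_hops),
      domain = policy_domain(d$domain$mu_min, d$domain$mu_max,
                             d$domain$sigma_min, d$domain$sigma_max,
                             d$domain$n_mu, d$domain$n_sigma),
      est = estimator_spec(d$estimator$method, d$estimator$n_mc,
                           d$seeds$estimator),
      seeds = lapply(d$seeds, as.integer),
      n_trajectories = check_count(d$n_trajectories, "n_trajectories"),
      epsilons = as.numeric(unlist(d$epsilons)),
      deltas = as.numeric(unlist(d$deltas)),
      config = d
    ),
    class = "telic_scenario"
  )
}

#' Load a scenario configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) scenario file, fills every
#' default explicitly, rejects unknown keys with field-level messages, and
#' instantiates the validated component objects.  Loading, saving with
#' [write_scenario()] and loading again yields an identical scenario.
#'
#' @param path Path to the scenario file.
#' @return An object of class `telic_scenario`: named components `env`,
#'   `goal`, `rule`, `cfg`, `bound`, `hops`, `domain`, `est`, `seeds`,
#'   `n_trajectories`, `epsilons`, `deltas`, plus the normalized raw `config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("scenario file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  build_scenario(normalize_scenario(raw))
}

#' Write a scenario configuration to YAML
#'
#' @param scenario A `telic_scenario` (from [load_scenario()] or
#'   [generate_fixture()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "telic_scenario"))
  yaml::write_yaml(scenario$config, path, precision = 15)
  invisible(path)
}

#' @export
print.telic_scenario <- function(x, ...) {
  cat(sprintf(
    "<telic_scenario> %s: T = %d, epsilon = %g, delta = %g, N = %d\n",
    x$name, x$env$horizon, x$rule$epsilon, x$bound$delta, x$hops$n_hops))
  print(x$goal$regions_tbl)
  invisible(x)
}

fixture_config <- function(name) {
  base <- scenario_defaults()
  switch(
    name,
    dual_goal = modifyList(base, list(name = "dual_goal")),
    shifted_goal = modifyList(base, list(
      name = "shifted_goal",
      goal = modifyList(base$goal, list(
        regions = list(R = list(center = 2.5, width = 1),
                       L = list(center = -2, width = 1)))),
      bound = list(delta = 0.25))),
    tiny_grid = modifyList(base, list(
      name = "tiny_grid",
      domain = list(mu_min = -3, mu_max = 3, sigma_min = 0.5,
                    sigma_max = 2, n_mu = 5, n_sigma = 5))),
    stop_invalid(sprintf("unknown fixture `%s`.", name))
  )
}

#' Canonical packaged scenarios
#'
#' Three canned scenarios cover the worked navigation examples:
#' \describe{
#'   \item{`dual_goal`}{unit-width goal regions centred at 2 and -2, horizon
#'     30, sensitivity 0.1, capacity 1 bit.}
#'   \item{`shifted_goal`}{identical except the target region is recentred at
#'     2.5 and the capacity tightened to 0.25 bits, which makes the target
#'     state unreachable and exercises the split-and-re-anchor repair.}
#'   \item{`tiny_grid`}{the dual-goal task on a 5 x 5 policy grid, small
#'     enough for exhaustive brute-force checking.}
#' }
#'
#' @param name One of `"dual_goal"`, `"shifted_goal"`, `"tiny_grid"`.
#' @param path Optional path; when given, the scenario YAML is also written
#'   there.
#' @return The `telic_scenario`, invisibly when `path` is given.
#' @export
generate_fixture <- function(name = c("dual_goal", "shifted_goal",
                                      "tiny_grid"),
                             path = NULL) {
  name <- match.arg(name)
  sc <- build_scenario(normalize_scenario(fixture_config(name)))
  if (!is.null(path)) {
    write_scenario(sc, path)
    return(invisible(sc))
  }
  sc
}

# Canonical JSON of the normalized config; its md5 stamps every output file.
config_hash <- function(scenario) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(scenario$config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

provenance <- function(scenario) {
  list(
    package = "telic",
    version = as.character(utils::packageVersion("telic")),
    scenario = scenario$name,
    config_hash = config_hash(scenario),
    seeds = scenario$seeds
  )
}

write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run a scenario command
#'
#' Executes one analysis step of a scenario and writes its results (JSON, and
#' CSV for matrices/curves) under `output_dir`.  Outputs are deterministic
#' given the scenario's seeds: rerunning the same command on the same
#' configuration reproduces every file byte for byte.  Every JSON result
#' carries the package version, the scenario's config hash and its seeds.
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{sample `n_trajectories` from the default policy;
#'     writes `trajectories.csv` (+ sidecar).}
#'   \item{`build-states`}{build the telic representation; writes
#'     `states.json` and the grid `labels.csv`.}
#'   \item{`project`}{information projection of the default onto every
#'     non-empty goal state; writes `projections.json`.}
#'   \item{`controllability`}{controllability report; writes
#'     `controllability.json`.}
#'   \item{`refine`}{run [refine_until_controllable()]; writes
#'     `refinement.json`.}
#'   \item{`curves`}{both tradeoff curves; writes `granularity_curve.csv`
#'     and `goal_complexity_curve.csv` (+ sidecars).}
#' }
#'
#' @param scenario A `telic_scenario`.
#' @param command One of the commands above.
#' @param output_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
run_scenario <- function(scenario,
                         command = c("simulate", "build-states", "project",
                                     "controllability", "refine", "curves"),
                         output_dir = ".") {
  stopifnot(inherits(scenario, "telic_scenario"))
  command <- match.arg(command)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance(scenario)
  out <- function(f) file.path(output_dir, f)
  files <- character()

  if (command == "simulate") {
    batch <- sample_trajectories(scenario$cfg$default_policy, scenario$env,
                                 n = scenario$n_trajectories,
                                 seed = scenario$seeds$trajectories)
    write_trajectories(batch, out("trajectories.csv"))
    files <- c(trajectories = out("trajectories.csv"),
               meta = out("trajectories.csv.json"))
  } else if (command == "curves") {
    gc1 <- complexity_granularity_curve(
      scenario$goal, scenario$goal$target, scenario$cfg, scenario$env,
      scenario$domain, scenario$epsilons, est = scenario$est)
    gc2 <- goal_complexity_curve(
      scenario$goal, scenario$goal$target, scenario$cfg, scenario$env,
      scenario$domain, scenario$deltas, est = scenario$est)
    write_curve(gc1, out("granularity_curve.csv"))
    write_curve(gc2, out("goal_complexity_curve.csv"))
    write_result_json(prov, out("curves.json"))
    files <- c(granularity = out("granularity_curve.csv"),
               goal_complexity = out("goal_complexity_curve.csv"),
               meta = out("curves.json"))
  } else {
    rep <- build_representation(scenario$goal, scenario$rule, scenario$env,
                                scenario$domain, scenario$est)
    if (command == "build-states") {
      write.csv(as.data.frame(rep$assignments[, c("mu", "sigma", "state")]),
                out("labels.csv"), row.names = FALSE)
      write_result_json(
        c(prov, list(epsilon = scenario$rule$epsilon,
                     counts = setNames(as.list(rep$counts$n),
                                       rep$counts$state))),
        out("states.json"))
      files <- c(labels = out("labels.csv"), states = out("states.json"))
    } else if (command == "project") {
      labels <- setdiff(rep$counts$state[rep$counts$n > 0L], "S0")
      projs <- lapply(labels, function(l) {
        p <- information_projection(rep, l, scenario$cfg)
        as.list(p)
      })
      names(projs) <- labels
      write_result_json(c(prov, list(projections = projs)),
                        out("projections.json"))
      files <- c(projections = out("projections.json"))
    } else if (command == "controllability") {
      report <- is_telic_controllable(rep, scenario$cfg, scenario$bound,
                                      scenario$hops)
      write_result_json(
        c(prov, list(
          controllable = report$controllable,
          delta = scenario$bound$delta, n_hops = scenario$hops$n_hops,
          per_state = lapply(split(report$per_state,
                                   seq_len(nrow(report$per_state))),
                             as.list),
          chains = lapply(report$chains, function(ch) {
            if (is.null(ch)) NULL else lapply(split(ch, seq_len(nrow(ch))),
                                              as.list)
          }))),
        out("controllability.json"))
      files <- c(controllability = out("controllability.json"))
    } else if (command == "refine") {
      res <- refine_until_controllable(rep, scenario$cfg, scenario$bound,
                                       scenario$hops)
      final <- res$representations[[length(res$representations)]]
      write_result_json(
        c(prov, list(
          iterations = res$iterations,
          inserted_states = as.list(res$inserted_states),
          anchors = lapply(split(res$anchors, seq_len(nrow(res$anchors))),
                           as.list),
          controllable = res$report$controllable,
          final_counts = setNames(as.list(final$counts$n),
                                  final$counts$state))),
        out("refinement.json"))
      files <- c(refinement = out("refinement.json"))
    }
  }
  invisible(files)
}
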