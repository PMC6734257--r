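config_keys_required <- c("beta", "delta", "u_healthy", "u_sick",
                          "p_adherent", "p_nonadherent", "cost_model",
                          "cost_adherent", "cost_nonadherent",
                          "followup_cost")
config_keys_optional <- c("bonus", "detection_prob", "admin_share")

#' Load a scenario from a configuration file
#'
#' Reads a JSON or YAML file holding a flat set of scenario parameters and
#' returns a validated \code{\link{scenario}}. The recognized keys are
#' \code{beta}, \code{delta}, \code{u_healthy}, \code{u_sick},
#' \code{p_adherent}, \code{p_nonadherent}, \code{cost_model} (a mapping
#' with a single entry \code{uniform: \{c_max: ...\}}), \code{cost_adherent},
#' \code{cost_nonadherent}, \code{followup_cost}, and optionally
#' \code{bonus} (default 0), \code{detection_prob} (default 1) and
#' \code{admin_share} (default 0). Unknown keys are rejected; invariant
#' violations fail with a message naming the violated constraint.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file
#' @return a validated \code{\link{scenario}}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) yaml::read_yaml(path))
  }
  config_to_scenario(cfg)
}

#' Build a scenario from a configuration list
#'
#' The list counterpart of \code{\link{load_config}}, useful for
#' programmatic construction and round-trip tests.
#'
#' @param cfg a named list of configuration values
#' @return a validated \code{\link{scenario}}.
#' @export
config_to_scenario <- function(cfg) {
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a named mapping of parameters", call. = FALSE)
  known <- c(config_keys_required, config_keys_optional)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(config_keys_required, names(cfg))
  if (length(missing) > 0)
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  cm_spec <- cfg$cost_model
  if (!is.list(cm_spec) || length(cm_spec) != 1 ||
      !identical(names(cm_spec), "uniform"))
    stop("`cost_model` must be a mapping with exactly one entry `uniform`",
         call. = FALSE)
  uni <- cm_spec$uniform
  c_max <- if (is.list(uni)) uni$c_max else uni
  if (is.null(c_max))
    stop("`cost_model.uniform` must provide `c_max`", call. = FALSE)

  scenario(
    preferences(cfg$beta, cfg$delta),
    therapy(cfg$p_adherent, cfg$p_nonadherent),
    health_utilities(cfg$u_healthy, cfg$u_sick),
    uniform_cost_model(c_max),
    incentive_scheme(bonus = cfg$bonus %||% 0,
                     detection_prob = cfg$detection_prob %||% 1,
                     admin_share = cfg$admin_share %||% 0),
    societal_costs(cfg$cost_adherent, cfg$cost_nonadherent, cfg$followup_cost)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario back to a configuration list
#'
#' Inverse of \code{\link{config_to_scenario}} (uniform cost models only):
#' \code{config_to_scenario(scenario_to_config(s))} reproduces \code{s}
#' parameter for parameter.
#'
#' @param scenario a \code{\link{scenario}} with a uniform cost model
#' @return a named list in the configuration-file key set.
#' @export
scenario_to_config <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  if (!inherits(scenario$cost_model, "uniform_cost_model"))
    stop("only uniform cost models can be serialized to a config",
         call. = FALSE)
  list(beta = scenario$preferences$beta,
       delta = scenario$preferences$delta,
       u_healthy = scenario$utilities$u_healthy,
       u_sick = scenario$utilities$u_sick,
       p_adherent = scenario$therapy$p_adherent,
       p_nonadherent = scenario$therapy$p_nonadherent,
       cost_model = list(uniform = list(c_max = scenario$cost_model$c_max)),
       bonus = scenario$incentive$bonus,
       detection_prob = scenario$incentive$detection_prob,
       admin_share = scenario$incentive$admin_share,
       cost_adherent = scenario$societal$cost_adherent,
       cost_nonadherent = scenario$societal$cost_nonadherent,
       followup_cost = scenario$societal$followup_cost)
}

round12 <- function(x) {
  if (is.numeric(x)) signif(x, 12) else x
}

cli_log <- function(quiet, ...) {
  if (!quiet) message("[adherebd] ", ...)
}

#' Run an analysis command on a scenario
#'
#' Programmatic core of the command-line interface. Commands:
#' \describe{
#'   \item{\code{report}}{writes the \code{\link{welfare_report}} as JSON to
#'     \code{<out>.json}.}
#'   \item{\code{simulate}}{runs \code{\link{simulate_population}} (requires
#'     \code{n} and \code{seed}) and writes the per-agent table to
#'     \code{<out>_agents.csv} plus a JSON summary to
#'     \code{<out>_summary.json}.}
#'   \item{\code{sweep}}{runs \code{\link{parameter_sweep}} (requires \code{parameter}
#'     and \code{grid}) and writes the table to \code{<out>.csv}.}
#'   \item{\code{optimize-bonus}}{runs \code{\link{optimal_bonus}} and writes
#'     \code{\{b_star, welfare, feasible, interior, method\}} to
#'     \code{<out>.json}; an infeasible scheme is reported in the JSON, not
#'     raised as an error.}
#' }
#' Numeric output is serialized with 12 significant digits; simulation runs
#' demand an explicit seed so results are reproducible. Progress is logged to
#' standard error unless \code{quiet = TRUE}.
#'
#' @param scenario a \code{\link{scenario}} (e.g. from
#'   \code{\link{load_config}})
#' @param command one of \code{"report"}, \code{"simulate"}, \code{"sweep"},
#'   \code{"optimize-bonus"}
#' @param out output path prefix (extensions are appended per command)
#' @param n agent count for \code{simulate}
#' @param seed integer seed for \code{simulate}
#' @param parameter,grid sweep specification for \code{sweep}
#' @param quiet suppress log messages
#' @return invisibly, a list with \code{status} (0 on success) and
#'   \code{files} (paths written).
#' @export
run_command <- function(scenario, command, out,
                        n = 10000, seed = NULL,
                        parameter = NULL, grid = NULL, quiet = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  command <- match.arg(command,
                       c("report", "simulate", "sweep", "optimize-bonus"))
  if (missing(out) || !is.character(out) || length(out) != 1)
    stop("`out` (output path prefix) is required", call. = FALSE)
  dir <- dirname(out)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  ver <- as.character(utils::packageVersion("adherebd"))
  cli_log(quiet, "adherebd ", ver, " | command: ", command)
  files <- character(0)

  if (command == "report") {
    rep <- welfare_report(scenario)
    path <- paste0(out, ".json")
    jsonlite::write_json(lapply(unclass(rep), round12), path,
                         auto_unbox = TRUE, digits = NA)
    files <- path
  } else if (command == "simulate") {
    if (is.null(seed))
      stop("`seed` is required for simulate (no wall-clock seeding)",
           call. = FALSE)
    cli_log(quiet, "simulating n = ", n, ", seed = ", seed)
    sim <- simulate_population(scenario, n = n, seed = seed)
    csv <- paste0(out, "_agents.csv")
    rec <- sim$records
    num <- vapply(rec, is.numeric, logical(1))
    rec[num] <- lapply(rec[num], round12)
    utils::write.csv(rec, csv, row.names = FALSE, quote = FALSE)
    summ <- list(n = sim$n, seed = sim$seed,
                 empirical_adherence = round12(sim$empirical_adherence),
                 empirical_W_I = round12(sim$empirical_W_I),
                 empirical_W_S = round12(sim$empirical_W_S),
                 standard_errors = lapply(as.list(sim$standard_errors),
                                          round12),
                 analytic = list(
                   adherence = round12(adherence_probability(scenario, 1)),
                   W_I = round12(individual_welfare(scenario)),
                   W_S = round12(societal_welfare(scenario))))
    js <- paste0(out, "_summary.json")
    jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
    files <- c(csv, js)
  } else if (command == "sweep") {
    if (is.null(parameter) || is.null(grid))
      stop("`parameter` and `grid` are required for sweep", call. = FALSE)
    tab <- parameter_sweep(scenario, parameter, grid)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round12)
    path <- paste0(out, ".csv")
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    files <- path
  } else { # optimize-bonus
    sol <- withCallingHandlers(
      optimal_bonus(scenario),
      warning = function(w) {
        cli_log(quiet, "note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    path <- paste0(out, ".json")
    jsonlite::write_json(list(b_star = round12(sol$b_star),
                              welfare = round12(sol$welfare),
                              feasible = sol$feasible,
                              interior = sol$interior,
                              method = sol$method),
                         path, auto_unbox = TRUE, digits = NA)
    files <- path
  }
  cli_log(quiet, "wrote: ", paste(files, collapse = ", "))
  invisible(list(status = 0L, files = files))
}
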