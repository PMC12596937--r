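# Configuration files (YAML recipes, policies, parameter sets), tabular
# results (RFC-4180 CSV), JSON summaries, and the command-line surface.

recipe_keys <- function() c(.solution_fields, "temperature", "na_counterions")

#' Read / write a recipe file (solution composition, mM)
#'
#' A recipe is a YAML mapping of component names to totals in mM (plus
#' optional `temperature` in K and `na_counterions`). Unknown keys are an
#' error, naming the offending key and file.
#'
#' @param path file path.
#' @param sol an [ivt_solution()].
#' @return `read_recipe()` returns an [ivt_solution()].
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), recipe_keys())
  if (length(bad))
    stop("unknown key(s) in recipe ", path, ": ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), setdiff(recipe_keys(), "na_counterions"))]
  args$na_counterions <- isTRUE(y$na_counterions)  # explicit inventory default
  names(args)[names(args) == "mg"] <- "mg"
  do.call(ivt_solution, args)
}

#' @rdname read_recipe
#' @export
write_recipe <- function(sol, path) {
  stopifnot(inherits(sol, "ivt_solution"))
  v <- as.list(unlist(sol[.solution_fields]) * 1000)
  v <- v[unlist(v) != 0]
  v$temperature <- sol$temperature
  v$na_counterions <- FALSE
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Read / write a feed-policy file
#'
#' YAML with `initial` (inline recipe, mM), `volume_L`, `catalysts`
#' (`dna_nM`, `polymerase_nM`), `t_final_s`, and `events`, a list of
#' `{time_min, volume_uL, feed: <inline recipe>}` records.
#'
#' @param path file path.
#' @param policy a [feed_policy()].
#' @return `read_policy()` returns a [feed_policy()].
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("initial", "volume_L", "catalysts", "t_final_s")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("policy file ", path, " missing key(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(names(y), c(need, "events"))
  if (length(bad)) stop("unknown key(s) in policy ", path, ": ",
                        paste(bad, collapse = ", "))
  sol_of <- function(rec) {
    bad <- setdiff(names(rec), recipe_keys())
    if (length(bad)) stop("unknown recipe key(s) in policy ", path, ": ",
                          paste(bad, collapse = ", "))
    rec$na_counterions <- isTRUE(rec$na_counterions)
    do.call(ivt_solution, rec)
  }
  events <- lapply(y$events %||% list(), function(e)
    feed_event(e$time_min * 60, e$volume_uL * 1e-6, sol_of(e$feed)))
  feed_policy(sol_of(y$initial),
              ivt_catalysts(y$catalysts$dna_nM, y$catalysts$polymerase_nM),
              t_final = y$t_final_s, volume_L = y$volume_L, events = events)
}

#' @rdname read_policy
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "ivt_policy"))
  rec_of <- function(sol) {
    v <- as.list(unlist(sol[.solution_fields]) * 1000)
    v <- v[unlist(v) != 0]
    v$na_counterions <- FALSE
    v
  }
  yaml::write_yaml(list(
    initial = rec_of(policy$initial),
    volume_L = policy$volume_L,
    catalysts = list(dna_nM = policy$catalysts$dna * 1e9,
                     polymerase_nM = policy$catalysts$polymerase * 1e9),
    t_final_s = policy$t_final,
    events = lapply(policy$events, function(e)
      list(time_min = e$time_s / 60, volume_uL = e$volume_L * 1e6,
           feed = rec_of(e$solution)))), path)
  invisible(path)
}

#' Read / write kinetic parameter files
#'
#' YAML with fields matching [ivt_kinetics()]; unknown keys are an error.
#' @param path file path.
#' @param params an [ivt_kinetics()].
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(ivt_kinetics))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown key(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  do.call(ivt_kinetics, y)
}

#' @rdname read_kinetics
#' @export
write_kinetics <- function(params, path) {
  stopifnot(inherits(params, "ivt_kinetics"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Write simulation results to a directory
#'
#' Writes `trajectory.csv` (wide, unit-suffixed columns), `trajectory_long.csv`
#' (time, variable, value), `summary.json` (final RNA in M and g/L, final
#' CF, peak supersaturation, final effective salt) and `provenance.json`
#' (package version, seed, input file hashes).
#'
#' @param sim an `ivt_simulation`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the provenance file.
#' @param input_files character vector of input paths to hash.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir, seed = NA, input_files = character()) {
  stopifnot(inherits(sim, "ivt_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(sim), file.path(dir, "trajectory_long.csv"),
                   row.names = FALSE)
  g <- glance(sim)
  jsonlite::write_json(list(
    final_rna_M = g$rna_uM * 1e-6, final_rna_gL = g$rna_gL,
    final_cf = g$cf, peak_sigma = g$peak_sigma,
    final_effective_salt_mM = g$effective_salt_mM, final_pH = g$pH),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(dir, "provenance.json"), seed, input_files)
  invisible(dir)
}

write_provenance <- function(path, seed = NA, input_files = character()) {
  hashes <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  jsonlite::write_json(list(
    package = "ivtsim",
    version = as.character(utils::packageVersion("ivtsim")),
    seed = seed, input_hashes = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE)
  invisible(path)
}

# ---- command-line interface ----------------------------------------------

cli_usage <- paste(
  "usage: ivtsim <subcommand> [options]",
  "",
  "subcommands:",
  "  speciate           solve speciation for a recipe; write species table",
  "  simulate           simulate a feed policy; write trajectories",
  "  optimize           optimize a feed policy under setpoint tracking",
  "  fit-capping        MLE calibration of capping parameters from CSV",
  "  design-experiments D-optimal capping calibration design",
  "  make-fixtures      write the bundled scenario and parameter files",
  "",
  "run 'ivtsim <subcommand> --help' for options", sep = "\n")

#' Command-line entry point
#'
#' Dispatches the subcommands `speciate`, `simulate`, `optimize`,
#' `fit-capping`, `design-experiments` and `make-fixtures`. Returns an exit
#' code (0 on success) rather than quitting, so it is testable in-process;
#' the installed `ivtsim` script wraps it with `quit(status = ...)`.
#' Every run writes a provenance JSON next to its outputs.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
ivt_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    cat(cli_usage, "\n")
    return(0L)
  }
  sub <- argv[1]
  rest <- argv[-1]
  handler <- switch(sub,
    "speciate" = cli_speciate, "simulate" = cli_simulate,
    "optimize" = cli_optimize, "fit-capping" = cli_fit_capping,
    "design-experiments" = cli_design, "make-fixtures" = cli_fixtures,
    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub)
    cat(cli_usage, "\n")
    return(2L)
  }
  tryCatch({
    handler(rest)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

cli_parse <- function(args, spec, usage) {
  parser <- optparse::OptionParser(usage = usage, option_list = spec)
  optparse::parse_args(parser, args = args)
}

cli_speciate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--recipe", type = "character"),
    optparse::make_option("--out", type = "character", default = "speciation")),
    "ivtsim speciate --recipe recipe.yaml --out dir")
  if (is.null(opt$recipe)) stop("--recipe is required")
  sol <- read_recipe(opt$recipe)
  res <- solve_speciation(sol)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res), file.path(opt$out, "species.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(pH = res$pH,
                            effective_salt_mM = res$effective_salt * 1000,
                            sigma = res$sigma),
                       file.path(opt$out, "speciation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(opt$out, "provenance.json"),
                   input_files = opt$recipe)
  cat("pH", round(res$pH, 3), "effective salt",
      round(res$effective_salt * 1000, 2), "mM sigma",
      round(res$sigma, 3), "\n")
}

cli_simulate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--policy", type = "character"),
    optparse::make_option("--params", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "results")),
    "ivtsim simulate --policy policy.yaml [--params params.yaml] --out dir")
  if (is.null(opt$policy)) stop("--policy is required")
  pol <- read_policy(opt$policy)
  kp <- if (!is.null(opt$params)) read_kinetics(opt$params) else ivt_kinetics()
  sim <- simulate_ivt(pol, kparams = kp)
  write_simulation(sim, opt$out,
                   input_files = c(opt$policy, opt$params))
  print(sim)
}

cli_optimize <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--seed", type = "integer", default = 1),
    optparse::make_option("--budget", type = "integer", default = 40),
    optparse::make_option("--n-events", type = "integer", default = 9,
                          dest = "n_events"),
    optparse::make_option("--low-ph", action = "store_true", default = FALSE,
                          dest = "low_ph"),
    optparse::make_option("--out", type = "character", default = "optimized")),
    "ivtsim optimize [--seed N] [--budget M] [--n-events K] [--low-ph] --out dir")
  obj <- ivt_objective()
  if (opt$low_ph) obj <- low_ph_variant(obj)
  tmpl <- decision_template(n_events = opt$n_events, t_final = obj$t_final)
  res <- optimize_policy(obj, tmpl, seed = opt$seed, budget = opt$budget)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  write_policy(res$policy, file.path(opt$out, "best_policy.yaml"))
  utils::write.csv(res$trace, file.path(opt$out, "trace.csv"),
                   row.names = FALSE)
  write_provenance(file.path(opt$out, "provenance.json"), seed = opt$seed)
  cat("best objective", res$objective, "after", nrow(res$trace),
      "evaluations\n")
}

cli_fit_capping <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--data", type = "character"),
    optparse::make_option("--mode", type = "character", default = "integrated"),
    optparse::make_option("--out", type = "character", default = "capping_fit")),
    "ivtsim fit-capping --data measurements.csv [--mode integrated] --out dir")
  m <- if (is.null(opt$data)) capping_calibration_data()
       else utils::read.csv(opt$data)
  fit <- mle_fit_capping(m, mode = opt$mode)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    lambda_per_M = fit$params$lambda, theta_mM = fit$params$theta * 1000,
    covariance = fit$params$cov, logLik = fit$logLik),
    file.path(opt$out, "capping_parameters.json"), digits = NA,
    auto_unbox = TRUE, matrix = "rowmajor")
  utils::write.csv(fit$fitted, file.path(opt$out, "fitted.csv"),
                   row.names = FALSE)
  write_provenance(file.path(opt$out, "provenance.json"),
                   input_files = opt$data %||% character())
  print(fit)
}

cli_design <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--n", type = "integer", default = 2),
    optparse::make_option("--seed", type = "integer", default = 1),
    optparse::make_option("--out", type = "character", default = "design")),
    "ivtsim design-experiments [--n K] [--seed N] --out dir")
  des <- d_optimal_design(n_experiments = opt$n, seed = opt$seed)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(des$design, file.path(opt$out, "design.csv"),
                   row.names = FALSE)
  write_provenance(file.path(opt$out, "provenance.json"), seed = opt$seed)
  print(des)
}

cli_fixtures <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--seed", type = "integer", default = 1),
    optparse::make_option("--out", type = "character", default = "fixtures")),
    "ivtsim make-fixtures [--seed N] --out dir")
  b <- make_scenarios(opt$seed)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(b$policies))
    write_policy(b$policies[[nm]], file.path(opt$out, paste0(nm, ".yaml")))
  write_kinetics(b$kparams[[1]], file.path(opt$out, "kinetics_sensitive.yaml"))
  write_kinetics(b$kparams$continuous_feed_literature_like,
                 file.path(opt$out, "kinetics_ordinary.yaml"))
  write_ivt_constants(b$constants, file.path(opt$out, "constants.yaml"))
  write_provenance(file.path(opt$out, "provenance.json"), seed = opt$seed)
  cat("wrote", length(b$policies), "policies to", opt$out, "\n")
}
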