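# File I/O: the CSV dialects for web inputs (group table, diet matrix,
# fleet table), tidy outputs for trajectories and ensembles, and the JSON
# run manifest.

#' Read and write food-web input tables
#'
#' Group table: columns \code{name, role, B, PB, QB, EE, GS, BA}, empty
#' cells marking unknown B or EE.  Diet matrix: first column \code{prey}
#' (group names plus \code{"import"}), one column per predator.  Fleet
#' table: columns \code{fleet, group, landings}.
#'
#' @param path file path.
#' @return the corresponding data.frame or matrix.
#' @export
read_group_table <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("B", "PB", "QB", "EE", "GS", "BA")
  for (cn in intersect(num, names(g))) g[[cn]] <- as.numeric(g[[cn]])
  check_group_table(g)
  g
}

#' @rdname read_group_table
#' @export
read_diet_matrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  m
}

#' @rdname read_group_table
#' @export
read_fleet_table <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  f$landings <- as.numeric(f$landings)
  f
}

#' @rdname read_group_table
#' @param web a \code{balanced_web}.
#' @param dir output directory (created if needed).
#' @return \code{write_web_csv} returns the paths written, invisibly.
#' @export
write_web_csv <- function(web, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "groups.csv")
  dp <- file.path(dir, "diet.csv")
  fp <- file.path(dir, "fleets.csv")
  rp <- file.path(dir, "balance_report.csv")
  utils::write.csv(web$groups, gp, row.names = FALSE)
  utils::write.csv(data.frame(prey = rownames(web$diet), web$diet,
                              check.names = FALSE),
                   dp, row.names = FALSE)
  utils::write.csv(web$fleets, fp, row.names = FALSE)
  utils::write.csv(data.frame(
    group = web$groups$name, role = web$groups$role,
    B = web$groups$B, EE = web$groups$EE,
    M0 = as.vector(web$M0), TL = as.vector(web$TL),
    landings = as.vector(web$landings)), rp, row.names = FALSE)
  invisible(c(groups = gp, diet = dp, fleets = fp, report = rp))
}

#' Load a web from its CSV files
#'
#' Counterpart of \code{\link{write_web_csv}}: reads the group, diet and
#' fleet tables from \code{dir} and re-solves the mass balance.
#'
#' @param dir directory holding \code{groups.csv}, \code{diet.csv},
#'   \code{fleets.csv}.
#' @param stanza optional \code{\link{stanza_link}} to attach.
#' @return a \code{balanced_web}.
#' @export
read_web_csv <- function(dir, stanza = NULL) {
  g <- read_group_table(file.path(dir, "groups.csv"))
  d <- read_diet_matrix(file.path(dir, "diet.csv"))
  f <- read_fleet_table(file.path(dir, "fleets.csv"))
  web <- solve_mass_balance(g, d, f)
  web$stanza <- stanza
  web
}

#' Tidy exports of simulation output
#'
#' \code{write_trajectory_csv} writes one row per (year, group) with
#' biomass, catch and applied F; \code{write_ensemble_csv} one row per
#' (run, year, group) with biomass, catch, herring F and the closure flag.
#'
#' @param tr a \code{trajectory}.
#' @param path output file.
#' @export
write_trajectory_csv <- function(tr, path) {
  groups <- colnames(tr$B)
  out <- data.frame(
    year = rep(tr$times, times = length(groups)),
    group = rep(groups, each = length(tr$times)),
    biomass = as.vector(tr$B),
    catch = as.vector(tr$catch),
    F_applied = as.vector(tr$F_applied))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param ens an \code{mse_ensemble}.
#' @export
write_ensemble_csv <- function(ens, path) {
  d <- dim(ens$B)
  nr <- d[1]; ny <- d[2]; ng <- d[3]
  out <- data.frame(
    scenario = ens$scenario$code,
    run = rep(seq_len(nr), times = ny * ng),
    year = rep(rep(seq_len(ny), each = nr), times = ng),
    group = rep(ens$groups, each = nr * ny),
    biomass = as.vector(ens$B),
    catch = as.vector(ens$catch),
    F_applied = rep(as.vector(ens$F_applied), times = ng),
    closed = rep(as.vector(ens$closed), times = ng))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: package
#' version, master seed, per-scenario sub-seed rule, B0 and the scenario
#' settings.
#'
#' @param path output file.
#' @param seed master seed.
#' @param b0 the \code{\link{equilibrium_b0}} value used.
#' @param scenarios list of \code{scenario_spec} (optional).
#' @param extra named list merged into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, b0 = NULL, scenarios = NULL,
                           extra = list()) {
  man <- c(list(
    tool = "herringmse",
    version = as.character(utils::packageVersion("herringmse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = as.integer(seed),
    subseed_rule = "(seed %% 1000003) * 1024 + 65537 + 31 * run",
    b0 = if (!is.null(b0)) as.numeric(b0),
    adult_share = if (!is.null(b0)) attr(b0, "adult_share"),
    scenarios = if (!is.null(scenarios)) lapply(scenarios, function(s)
      list(code = s$code, fleets = s$fleets, hcr = unclass(s$hcr),
           pp_regime = s$pp_regime, n_runs = s$n_runs, years = s$years,
           seed = s$seed))
  ), extra)
  man <- man[!vapply(man, is.null, TRUE)]
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

#' Write a metrics report to CSV + JSON
#'
#' @param report a \code{metrics_report}.
#' @param dir output directory; writes
#'   \code{<scenario>_groups.csv} (per-group changes) and
#'   \code{<scenario>_indicators.json} (scalar indicators).
#' @return paths written, invisibly.
#' @export
write_metrics <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, paste0(report$scenario, "_groups.csv"))
  jp <- file.path(dir, paste0(report$scenario, "_indicators.json"))
  utils::write.csv(report$groups, gp, row.names = FALSE)
  jsonlite::write_json(
    report[c("scenario", "p_closure", "p_collapse", "p_closure_run",
             "p_collapse_run", "mean_catch", "max_catch", "catch_ci",
             "mtl", "mtl_pct_change", "shannon_h", "shannon_pct_change")],
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(groups = gp, indicators = jp))
}
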