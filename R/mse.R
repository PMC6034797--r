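# Closed-loop management strategy evaluation: simulated assessment with
# error -> harvest control rule -> quota -> dynamics feedback, over
# Monte Carlo ensembles with common random numbers across scenarios.

#' Define a harvest control rule
#'
#' Three HCR shapes map estimated relative stock biomass to a target
#' fishing mortality: \code{constant} (F_target regardless of biomass),
#' \code{step} (fishery closed below \code{B_lim}, F_target above) and
#' \code{hockey} (closed below \code{B_lim}, linear ramp reaching F_target
#' at \code{B_Ftarget}).  \code{B_lim} and \code{B_Ftarget} are fractions
#' of unfished biomass B0.
#'
#' @param kind one of \code{"constant"}, \code{"step"}, \code{"hockey"}.
#' @param F_target target fishing mortality rate, /yr.
#' @param B_lim limit reference point, fraction of B0 (0 for constant rules).
#' @param B_Ftarget biomass at which F_target is reached, fraction of B0
#'   (hockey rules; defaults to \code{B_lim} otherwise).
#' @return an object of class \code{hcr}.
#' @export
hcr <- function(kind = c("constant", "step", "hockey"), F_target,
                B_lim = 0, B_Ftarget = NULL) {
  kind <- match.arg(kind)
  if (is.null(B_Ftarget)) B_Ftarget <- B_lim
  stopifnot(F_target >= 0, B_lim >= 0, B_Ftarget <= 1)
  if (kind == "constant" && B_lim != 0)
    stop("constant rules have B_lim = 0 (the fishery is always open)")
  if (kind == "hockey" && !(B_lim <= B_Ftarget))
    stop("hockey rule requires 0 <= B_lim <= B_Ftarget <= 1")
  structure(list(kind = kind, F_target = F_target, B_lim = B_lim,
                 B_Ftarget = B_Ftarget), class = "hcr")
}

#' @export
print.hcr <- function(x, ...) {
  cat(sprintf("%s HCR: F_target = %g, B_lim = %g B0, B_Ftarget = %g B0\n",
              x$kind, x$F_target, x$B_lim, x$B_Ftarget))
  invisible(x)
}

#' Evaluate a harvest control rule
#'
#' @param rule an \code{\link{hcr}}.
#' @param B_est estimated (assessed) biomass, t/km^2; vectorized.
#' @param B0 unfished biomass on the same scale as \code{B_est}.
#' @return fishing mortality in [0, F_target], /yr.
#' @export
evaluate_hcr <- function(rule, B_est, B0) {
  stopifnot(inherits(rule, "hcr"), all(B_est >= 0), B0 > 0)
  b <- B_est / B0
  Ft <- rule$F_target
  out <- switch(rule$kind,
    constant = rep(Ft, length(b)),
    step = ifelse(b < rule$B_lim, 0, Ft),
    hockey = {
      ramp <- if (rule$B_Ftarget > rule$B_lim)
        (b - rule$B_lim) / (rule$B_Ftarget - rule$B_lim) else
        as.numeric(b >= rule$B_lim)
      pmin(pmax(ramp, 0), 1) * Ft
    })
  unname(out)
}

#' Simulated stock-assessment biomass estimate
#'
#' Draws an estimate from a normal distribution centred on the true
#' biomass with standard deviation \code{cv * true_B}, truncated below at
#' zero via the inverse-CDF (equivalent to redrawing negative values, and
#' preserving common random numbers when a uniform deviate is supplied).
#'
#' @param true_B true biomass, t/km^2.
#' @param cv assessment coefficient of variation (0.3 for adult herring in
#'   the scenario defaults; 0 returns \code{true_B} exactly).
#' @param u optional uniform(0,1) deviate(s) for reproducible draws; if
#'   \code{NULL}, drawn from the session RNG.
#' @return biomass estimate(s) >= 0.
#' @export
assess_biomass <- function(true_B, cv = 0.3, u = NULL) {
  stopifnot(all(true_B >= 0), cv >= 0)
  if (cv == 0 || all(true_B == 0)) {
    n <- if (is.null(u)) length(true_B) else max(length(u), length(true_B))
    return(rep_len(true_B, n))
  }
  if (is.null(u)) u <- stats::runif(length(true_B))
  sdv <- cv * true_B
  plo <- stats::pnorm(0, mean = true_B, sd = sdv)
  est <- stats::qnorm(plo + u * (1 - plo), mean = true_B, sd = sdv)
  ifelse(rep_len(true_B, length(est)) == 0, 0, est)
}

#' Convert a quota decision into realized fishing mortality
#'
#' The quota is set from the estimated biomass (\code{F_decided * B_est});
#' taking it from the true biomass yields the realized F, capped at
#' \code{F_cap}.  Biomass overestimates therefore translate into realized
#' F above the decided F, the mechanism by which assessment error creates
#' depletion risk.
#'
#' @param F_decided HCR output, /yr.
#' @param B_est assessed biomass, t/km^2.
#' @param true_B true biomass, t/km^2.
#' @param F_cap maximum realizable F (default 2.4, the collapse-scenario
#'   rate).
#' @return list with \code{quota} (t/km^2/yr), \code{realized_F} (/yr) and
#'   \code{removal} (t/km^2/yr at current biomass).
#' @export
apply_quota <- function(F_decided, B_est, true_B, F_cap = 2.4) {
  stopifnot(F_decided >= 0, B_est >= 0, true_B >= 0)
  quota <- F_decided * B_est
  realized_F <- if (true_B > 0) min(quota / true_B, F_cap) else 0
  list(quota = quota, realized_F = realized_F, removal = realized_F * true_B)
}

#' Restrict a productivity series to a climate-regime resampling pool
#'
#' @param values numeric series of annual productivity anomalies.
#' @param regime \code{"all"} (full series), \code{"no_good"} (values
#'   strictly below the 75th percentile) or \code{"only_bad"} (strictly
#'   below the 25th percentile); linear-interpolation sample quantiles.
#' @return the resampling pool (numeric vector).
#' @export
regime_filter <- function(values, regime = c("all", "no_good", "only_bad")) {
  regime <- match.arg(regime)
  stopifnot(length(values) >= 4)
  pool <- switch(regime,
    all = values,
    no_good = values[values < stats::quantile(values, 0.75, names = FALSE)],
    only_bad = values[values < stats::quantile(values, 0.25, names = FALSE)])
  if (!length(pool)) stop("empty resampling pool for regime ", regime)
  pool
}

# ---- scenario grid -------------------------------------------------------

scenario_spec <- function(code, fleets, rule, pp_regime = "all",
                          n_runs = 100, years = 100, seed = 1L) {
  structure(list(code = code, fleets = fleets, hcr = rule,
                 pp_regime = pp_regime, n_runs = n_runs, years = years,
                 seed = as.integer(seed)), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario %-8s fleets=%-8s %-8s F_target=%-4g B_lim=%-4g B_Ftarget=%-4g regime=%s\n",
              x$code, x$fleets, x$hcr$kind, x$hcr$F_target, x$hcr$B_lim,
              x$hcr$B_Ftarget, x$pp_regime))
  invisible(x)
}

#' Build the management-strategy scenario grid
#'
#' Emits the full evaluation grid of herring management strategies:
#' \describe{
#'   \item{Base}{no herring fishery (F = 0); the paired baseline.}
#'   \item{SOK}{spawn-on-kelp only, constant F = 0.01 (incidental
#'     mortality of the non-capture egg fishery).}
#'   \item{K}{all herring fisheries, constant F in \{0.1, 0.2\}.}
#'   \item{MSYs1/MSYs2}{step rule at the single-species FMSY (F = 0.4),
#'     B_lim 0.25 or 0.40 B0.}
#'   \item{MSYe1/MSYe2}{step rule at the ecosystem FMSY (F = 0.6), B_lim
#'     0.25 or 0.40 B0.}
#'   \item{LF1}{step, B_lim = 0.40 B0, F in \{0.1, 0.2\}.}
#'   \item{LF2/LF3}{hockey, B_lim 0.25/0.40 B0, B_Ftarget = 0.95 B0, F in
#'     \{0.1, 0.2\}.}
#'   \item{BC}{step, B_lim = 0.25 B0, F in \{0.1, 0.2\}: the British
#'     Columbia rule.}
#'   \item{BC075/BC025}{BC at F = 0.2 under the "no good" / "only bad"
#'     productivity regimes.}
#' }
#'
#' @param codes optional subset of scenario family codes to emit.
#' @param f_targets F_target variants for the families that have them
#'   (default \code{c(0.1, 0.2)}).
#' @param n_runs,years,seed ensemble settings applied to every scenario.
#' @return named list of \code{scenario_spec} objects; variant codes carry
#'   the F_target suffix, e.g. \code{"K_0.2"}.
#' @export
build_scenarios <- function(codes = NULL, f_targets = c(0.1, 0.2),
                            n_runs = 100, years = 100, seed = 1L) {
  mk <- scenario_spec
  out <- list()
  add <- function(s) out[[s$code]] <<- s
  fam <- function(code) is.null(codes) || code %in% codes

  if (fam("Base")) add(mk("Base", "none", hcr("constant", 0),
                          n_runs = n_runs, years = years, seed = seed))
  if (fam("SOK")) add(mk("SOK", "sok_only", hcr("constant", 0.01),
                         n_runs = n_runs, years = years, seed = seed))
  for (ft in f_targets) {
    sfx <- paste0("_", ft)
    if (fam("K")) add(mk(paste0("K", sfx), "all", hcr("constant", ft),
                         n_runs = n_runs, years = years, seed = seed))
    if (fam("LF1")) add(mk(paste0("LF1", sfx), "all",
                           hcr("step", ft, B_lim = 0.40),
                           n_runs = n_runs, years = years, seed = seed))
    if (fam("LF2")) add(mk(paste0("LF2", sfx), "all",
                           hcr("hockey", ft, B_lim = 0.25, B_Ftarget = 0.95),
                           n_runs = n_runs, years = years, seed = seed))
    if (fam("LF3")) add(mk(paste0("LF3", sfx), "all",
                           hcr("hockey", ft, B_lim = 0.40, B_Ftarget = 0.95),
                           n_runs = n_runs, years = years, seed = seed))
    if (fam("BC")) add(mk(paste0("BC", sfx), "all",
                          hcr("step", ft, B_lim = 0.25),
                          n_runs = n_runs, years = years, seed = seed))
  }
  if (fam("MSYs")) {
    add(mk("MSYs1", "all", hcr("step", 0.4, B_lim = 0.25),
           n_runs = n_runs, years = years, seed = seed))
    add(mk("MSYs2", "all", hcr("step", 0.4, B_lim = 0.40),
           n_runs = n_runs, years = years, seed = seed))
  }
  if (fam("MSYe")) {
    add(mk("MSYe1", "all", hcr("step", 0.6, B_lim = 0.25),
           n_runs = n_runs, years = years, seed = seed))
    add(mk("MSYe2", "all", hcr("step", 0.6, B_lim = 0.40),
           n_runs = n_runs, years = years, seed = seed))
  }
  if (fam("BC075")) add(mk("BC075", "all", hcr("step", 0.2, B_lim = 0.25),
                           pp_regime = "no_good",
                           n_runs = n_runs, years = years, seed = seed))
  if (fam("BC025")) add(mk("BC025", "all", hcr("step", 0.2, B_lim = 0.25),
                           pp_regime = "only_bad",
                           n_runs = n_runs, years = years, seed = seed))
  known <- c("Base", "SOK", "K", "LF1", "LF2", "LF3", "BC", "MSYs", "MSYe",
             "BC075", "BC025")
  if (!is.null(codes)) {
    bad <- setdiff(codes, known)
    if (length(bad)) stop("unknown scenario code(s): ",
                          paste(bad, collapse = ", "))
  }
  out
}

# Deterministic sub-seed for run r under a master seed; scenario-independent
# so that paired scenarios share random draws (common random numbers).
run_subseed <- function(master_seed, r) {
  (as.integer(master_seed) %% 1000003L) * 1024L + 65537L + 31L * as.integer(r)
}

#' Run one closed-loop MSE scenario
#'
#' Per simulated year: resample the phytoplankton productivity anomaly from
#' the scenario's regime pool, assess adult herring biomass with error,
#' evaluate the harvest control rule, fix the year's quota, and advance the
#' food web by twelve monthly steps with the realized fishing mortality.
#' The ensemble repeats this \code{n_runs} times with sub-seeds derived
#' only from the master seed and the run index, so scenarios sharing a
#' master seed see identical forcing and assessment draws (common random
#' numbers, enabling paired comparisons).
#'
#' @param web a \code{balanced_web} with a herring stanza link.
#' @param vul vulnerability setting.
#' @param scenario a \code{scenario_spec}.
#' @param series productivity anomaly series (numeric vector) resampled
#'   annually, e.g. from \code{\link{productivity_series}}.
#' @param b0 precomputed \code{\link{equilibrium_b0}} result (computed here
#'   if \code{NULL}; pass it in when running many scenarios).
#' @param cv assessment CV for adult herring.
#' @param F_cap cap on realized fishing mortality.
#' @param dt integration step.
#' @param params optional precomputed \code{dynamics_params}.
#' @return an \code{mse_ensemble}: biomass and catch arrays
#'   (runs x years x groups), applied/decided F, closure flags, and the B0
#'   bookkeeping.
#' @export
run_closed_loop <- function(web, vul = 2, scenario, series, b0 = NULL,
                            cv = 0.3, F_cap = 2.4, dt = 1 / 12,
                            params = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- if (is.null(params)) derive_dynamics(web, vul) else params
  if (is.null(b0)) b0 <- equilibrium_b0(web, vul, params = p)
  adult_share <- attr(b0, "adult_share")
  b0_adult <- as.numeric(b0) * adult_share
  juv <- web$stanza$juvenile
  adult <- web$stanza$adult
  ia <- match(adult, p$names)
  ij <- match(juv, p$names)
  pool <- regime_filter(series, scenario$pp_regime)
  np <- length(pool)
  nr <- scenario$n_runs
  ny <- scenario$years
  steps <- round(1 / dt)
  rule <- scenario$hcr
  has_fishery <- scenario$fleets != "none"
  closable <- has_fishery && rule$kind != "constant"

  # per-run random streams depend only on master seed and run index, drawn
  # up-front in a fixed order, so paired scenarios see identical draws
  u_force <- matrix(0, nr, ny)
  u_assess <- matrix(0, nr, ny)
  for (r in seq_len(nr)) {
    set.seed(run_subseed(scenario$seed, r))
    u_force[r, ] <- stats::runif(ny)
    u_assess[r, ] <- stats::runif(ny)
  }

  Fmat <- matrix(rep(p$F0, each = nr), nr, p$n)
  Fmat[, c(ia, ij)] <- 0            # herring F comes from the control rule

  Barr <- array(0, c(nr, ny, p$n), dimnames = list(NULL, NULL, p$names))
  Carr <- Barr
  Fdec <- matrix(0, nr, ny)
  Fapp <- matrix(0, nr, ny)
  closed <- matrix(FALSE, nr, ny)
  forcing_used <- matrix(0, nr, ny)

  B <- matrix(rep(p$B0, each = nr), nr, p$n)
  for (y in seq_len(ny)) {
    f <- pool[floor(u_force[, y] * np) + 1L]
    forcing_used[, y] <- f
    if (has_fishery) {
      true_adult <- B[, ia]
      B_est <- assess_biomass(true_adult, cv = cv, u = u_assess[, y])
      F_d <- evaluate_hcr(rule, B_est, b0_adult)
      realized <- ifelse(true_adult > 0,
                         pmin(F_d * B_est / true_adult, F_cap), 0)
      Fdec[, y] <- F_d
      Fapp[, y] <- realized
      closed[, y] <- closable & F_d == 0
      Fmat[, ia] <- realized
    }
    accB <- matrix(0, nr, p$n); accC <- matrix(0, nr, p$n)
    for (k in seq_len(steps)) {
      accC <- accC + Fmat * B * dt
      B <- ensemble_step(B, p, dt, f, Fmat)
      accB <- accB + B
    }
    Barr[, y, ] <- accB / steps
    Carr[, y, ] <- accC
  }
  structure(list(
    scenario = scenario, B = Barr, catch = Carr,
    F_decided = Fdec, F_applied = Fapp, closed = closed,
    forcing = forcing_used,
    b0 = as.numeric(b0), adult_share = adult_share,
    herring = c(juvenile = juv, adult = adult),
    groups = p$names, has_fishery = has_fishery
  ), class = "mse_ensemble")
}

#' @export
print.mse_ensemble <- function(x, ...) {
  d <- dim(x$B)
  cat(sprintf("MSE ensemble '%s': %d runs x %d years x %d groups\n",
              x$scenario$code, d[1], d[2], d[3]))
  hb <- apply(x$B[, , x$herring, drop = FALSE], 1:2, sum)
  cat(sprintf("  grand-mean herring biomass %.3f t/km^2 (B0 = %.3f), closure rate %.3f\n",
              mean(hb), x$b0, mean(x$closed)))
  invisible(x)
}

#' Run a set of scenarios with shared forcing and seeds
#'
#' Convenience wrapper: computes B0 and the dynamic calibration once, then
#' runs \code{run_closed_loop} for every scenario in the list.
#'
#' @inheritParams run_closed_loop
#' @param scenarios named list from \code{\link{build_scenarios}}.
#' @return named list of \code{mse_ensemble} objects.
#' @export
run_scenario_grid <- function(web, vul = 2, scenarios, series, b0 = NULL,
                              cv = 0.3, dt = 1 / 12) {
  p <- derive_dynamics(web, vul)
  if (is.null(b0)) b0 <- equilibrium_b0(web, vul, params = p)
  lapply(scenarios, function(sc)
    run_closed_loop(web, vul, sc, series, b0 = b0, cv = cv, dt = dt,
                    params = p))
}
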