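# Synthetic reference food web: a reduced (~17 living groups + detritus)
# herring-centric Northeast Pacific shelf web whose statistical structure
# matches the system under study -- adult herring at trophic level 3.14,
# four predators taking >= 20% of their diet as herring, planktivorous
# competitors sharing euphausiid prey, and roe / spawn-on-kelp / groundfish
# fleets -- without reproducing any particular regional parameterization.

#' Generator configuration for the reference web
#'
#' @param seed integer seed; the web is deterministic given the seed.
#' @param herring_diet_floor minimum herring diet fraction for the
#'   designated herring-dependent predators.
#' @param target_herring_tl target adult-herring trophic level and
#'   half-width of the accepted band.
#' @param baseline_herring_F baseline fishing mortality on adult herring
#'   split between the roe (90\%) and spawn-on-kelp (10\%) fleets.
#' @param productivity_cv interannual CV of the phytoplankton anomaly
#'   series.
#' @param series_length length of the anomaly series (51 annual values,
#'   a 1950-2000-like record).
#' @param jitter relative lognormal jitter applied to non-pinned
#'   parameters.
#' @export
generator_config <- function(seed = 42L, herring_diet_floor = 0.20,
                             target_herring_tl = c(3.14, 0.05),
                             baseline_herring_F = 0.2,
                             productivity_cv = 0.25,
                             series_length = 51L, jitter = 0.03) {
  list(seed = as.integer(seed), herring_diet_floor = herring_diet_floor,
       target_herring_tl = target_herring_tl,
       baseline_herring_F = baseline_herring_F,
       productivity_cv = productivity_cv,
       series_length = as.integer(series_length), jitter = jitter)
}

# Template parameter table: biomasses t/km^2, rates /yr.  These are
# desk-scale values in the ranges typical of temperate shelf Ecopath
# models, chosen so the web balances with all EE in [0, 1] and the dynamic
# model is stable at its calibrated equilibrium.
reference_template <- function() {
  groups <- data.frame(
    name = c("phytoplankton", "copepods", "euphausiids",
             "juvenile herring", "adult herring", "forage fish", "eulachon",
             "pollock", "piscivorous fish", "hake", "seals", "sea lions",
             "dolphins", "humpback whales", "sei whales", "transient orcas",
             "seabirds", "detritus"),
    role = c("producer", rep("consumer", 16), "detritus"),
    B  = c(22, 14, 16, 0.36, 2.4, 6.0, 1.5, 6.0, 3.0, 0.8,
           0.10, 0.05, 0.05, 0.30, 0.6, 0.0008, 0.015, 30),
    PB = c(50, 15, 5, 1.0, 1.0, 1.6, 1.3, 0.7, 0.55, 0.6,
           0.09, 0.07, 0.12, 0.04, 0.035, 0.03, 0.12, NA),
    QB = c(0, 42, 16, 10, 4.5, 6.5, 5.5, 3.2, 2.8, 2.5,
           12, 11, 14, 4.5, 5, 8, 50, NA),
    EE = NA_real_,
    GS = c(0, 0.3, 0.3, 0.25, 0.25, 0.25, 0.25, 0.2, 0.2, 0.2,
           0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, NA),
    BA = 0
  )
  d <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x[seq(2, length(x), 2)]),
                    x[seq(1, length(x), 2)])
  }
  diets <- list(
    "copepods" = d("phytoplankton", 0.85, "detritus", 0.15),
    "euphausiids" = d("phytoplankton", 0.8, "copepods", 0.2),
    "juvenile herring" = d("copepods", 0.65, "euphausiids", 0.35),
    "adult herring" = d("euphausiids", 0.7, "copepods", 0.3),
    "forage fish" = d("copepods", 0.5, "euphausiids", 0.5),
    "eulachon" = d("euphausiids", 0.6, "copepods", 0.4),
    "pollock" = d("euphausiids", 0.55, "copepods", 0.3, "forage fish", 0.15),
    "piscivorous fish" = d("adult herring", 0.05, "juvenile herring", 0.015,
                           "forage fish", 0.35, "eulachon", 0.1,
                           "pollock", 0.2, "euphausiids", 0.285),
    "hake" = d("adult herring", 0.20, "juvenile herring", 0.02,
               "euphausiids", 0.48, "forage fish", 0.2, "eulachon", 0.1),
    "seals" = d("adult herring", 0.25, "juvenile herring", 0.02,
                "euphausiids", 0.08, "forage fish", 0.15, "eulachon", 0.1,
                "pollock", 0.2, "piscivorous fish", 0.2),
    "sea lions" = d("adult herring", 0.1, "forage fish", 0.15,
                    "pollock", 0.35, "piscivorous fish", 0.3,
                    "eulachon", 0.1),
    "dolphins" = d("adult herring", 0.25, "juvenile herring", 0.02,
                   "euphausiids", 0.08, "forage fish", 0.3, "eulachon", 0.15,
                   "pollock", 0.2),
    "humpback whales" = d("adult herring", 0.20, "juvenile herring", 0.02,
                          "euphausiids", 0.68, "forage fish", 0.1),
    "sei whales" = d("euphausiids", 0.8, "copepods", 0.15,
                     "forage fish", 0.05),
    "transient orcas" = d("seals", 0.5, "sea lions", 0.3, "dolphins", 0.2),
    "seabirds" = d("juvenile herring", 0.05, "forage fish", 0.35,
                   "euphausiids", 0.5, "eulachon", 0.1)
  )
  diet <- matrix(0, nrow(groups) + 1, length(diets),
                 dimnames = list(c(groups$name, "import"), names(diets)))
  for (pred in names(diets)) diet[names(diets[[pred]]), pred] <- diets[[pred]]
  list(groups = groups, diet = diet)
}

# Predators designated as herring-dependent (>= 20% herring diets).
herring_dependent_predators <- function() {
  c("hake", "seals", "dolphins", "humpback whales")
}

#' Generate the deterministic reference food web
#'
#' Builds the packaged synthetic web: applies a small seeded lognormal
#' jitter to biomasses, rates and non-pinned diet entries of the template
#' (diets of copepods, euphausiids and both herring pools are pinned so
#' the adult-herring trophic level stays in the target band, and the
#' herring fractions of the four herring-dependent predators are pinned at
#' or above the diet floor), renormalizes diet columns, attaches the roe,
#' spawn-on-kelp and groundfish fleets, solves the mass balance, and
#' verifies the structural constraints.
#'
#' @param config a \code{\link{generator_config}}.
#' @param max_tries bounded retries of the jitter draw before failing.
#' @return a \code{balanced_web} with the herring stanza link attached.
#' @export
generate_reference_web <- function(config = generator_config(),
                                   max_tries = 20) {
  tpl <- reference_template()
  pinned_cols <- c("copepods", "euphausiids", "juvenile herring",
                   "adult herring")
  pinned_rows <- c("adult herring", "juvenile herring")
  hdp <- herring_dependent_predators()

  last_viol <- "mass-balance solver failed on every jitter draw"
  for (try in seq_len(max_tries)) {
    rng_seed <- config$seed + (try - 1L) * 1009L
    set.seed(rng_seed)
    g <- tpl$groups
    liv <- g$role != "detritus"
    jit <- function(n) exp(stats::rnorm(n, 0, config$jitter))
    g$B[liv] <- g$B[liv] * jit(sum(liv))
    g$PB[liv] <- g$PB[liv] * jit(sum(liv))
    cons <- g$role == "consumer"
    g$QB[cons] <- pmax(g$QB[cons] * jit(sum(cons)), g$PB[cons] * 1.5)

    diet <- tpl$diet
    for (pred in setdiff(colnames(diet), pinned_cols)) {
      nz <- diet[, pred] > 0
      free <- nz & !(rownames(diet) %in% pinned_rows)
      diet[free, pred] <- diet[free, pred] * jit(sum(free))
      # renormalize the free mass so pinned herring fractions are exact
      pin_mass <- sum(diet[nz & !free, pred])
      diet[free, pred] <- diet[free, pred] * (1 - pin_mass) /
        sum(diet[free, pred])
    }

    ia <- match("adult herring", g$name)
    f_roe <- 0.9 * config$baseline_herring_F
    f_sok <- 0.1 * config$baseline_herring_F
    fleets <- data.frame(
      fleet = c("roe", "SOK", "groundfish", "groundfish", "groundfish"),
      group = c("adult herring", "adult herring", "hake", "pollock",
                "piscivorous fish"),
      landings = c(f_roe * g$B[ia], f_sok * g$B[ia],
                   0.15 * g$B[g$name == "hake"],
                   0.10 * g$B[g$name == "pollock"],
                   0.10 * g$B[g$name == "piscivorous fish"]))

    web <- tryCatch(solve_mass_balance(g, diet, fleets),
                    error = function(e) e)
    if (inherits(web, "error")) next
    web$stanza <- stanza_link("juvenile herring", "adult herring",
                              transition_age = 1)

    viol <- character(0)
    tl_ah <- web$TL["adult herring"]
    band <- config$target_herring_tl
    if (abs(tl_ah - band[1]) > band[2])
      viol <- c(viol, sprintf("adult herring TL %.3f outside %.2f +/- %.2f",
                              tl_ah, band[1], band[2]))
    for (pr in hdp) {
      hshare <- sum(web$diet[pinned_rows, pr])
      if (hshare < config$herring_diet_floor - 1e-9)
        viol <- c(viol, sprintf("%s herring diet share %.3f < %.2f", pr,
                                hshare, config$herring_diet_floor))
    }
    if (web$groups$EE[ia] < 0.5)
      viol <- c(viol, sprintf("adult herring EE %.3f < 0.5",
                              web$groups$EE[ia]))
    if (!length(viol)) {
      attr(web, "generator_seed") <- rng_seed
      return(web)
    }
    last_viol <- viol
  }
  stop("reference web generation failed after ", max_tries, " tries; ",
       "violated constraints: ", paste(last_viol, collapse = "; "))
}

#' Generate the phytoplankton productivity anomaly series
#'
#' 51 annual multiplicative anomalies (a 1950-2000-like record), i.i.d.
#' lognormal about 1 with the configured CV and mean-corrected so the
#' arithmetic mean is exactly 1 (baseline calibration preserved).  An
#' optional AR(1) coefficient induces autocorrelation before the mean
#' correction.
#'
#' @param config a \code{\link{generator_config}}.
#' @param ar1 lag-1 autocorrelation of the log-anomalies (default 0:
#'   independent years).
#' @return numeric vector of length \code{series_length} with mean 1.
#' @export
generate_productivity_series <- function(config = generator_config(),
                                         ar1 = 0) {
  n <- config$series_length
  stopifnot(n >= 4, ar1 >= 0, ar1 < 1)
  cv <- config$productivity_cv
  if (cv == 0) return(rep(1, n))
  set.seed(config$seed + 777L)
  sdlog <- sqrt(log(1 + cv^2))
  z <- stats::rnorm(n)
  if (ar1 > 0) {
    for (i in 2:n) z[i] <- ar1 * z[i - 1] + sqrt(1 - ar1^2) * z[i]
  }
  x <- exp(sdlog * z - sdlog^2 / 2)
  x / mean(x)
}

#' Whale-recovery biomass forcing ramp
#'
#' Synthetic stand-in for a projected whale-recovery series: a logistic
#' ramp of biomass multipliers from 1 to \code{peak} applied to the whale
#' groups as forced biomass.  Deactivated (all ones) when
#' \code{active = FALSE}.
#'
#' @param years horizon of the ramp.
#' @param peak final multiplier of baseline biomass.
#' @param midpoint ramp midpoint, years.
#' @param active toggle; inactive returns a constant-1 series.
#' @param groups whale group names the ramp applies to.
#' @return named list of per-year multiplier series, suitable for the
#'   \code{forced_biomass} argument of \code{\link{run_dynamics}}.
#' @export
whale_recovery_forcing <- function(years, peak = 1.5, midpoint = 40,
                                   active = TRUE,
                                   groups = c("humpback whales",
                                              "sei whales")) {
  ramp <- if (active)
    1 + (peak - 1) / (1 + exp(-(seq_len(years) - midpoint) / 8))
  else rep(1, years)
  stats::setNames(rep(list(ramp), length(groups)), groups)
}

#' Perturb a balanced web for robustness suites
#'
#' Applies multiplicative lognormal jitter to B, P/B and Q/B of all living
#' groups, re-solves every EE, and rejects candidates that do not balance
#' (any EE outside [0, 1]); used to check that qualitative MSE results are
#' robust to parameter uncertainty.
#'
#' @param web a \code{balanced_web}.
#' @param seed integer seed.
#' @param sd_fraction lognormal sd of the jitter (0 returns the input web).
#' @param max_tries rejection-sampling budget.
#' @return a \code{balanced_web} variant with the same stanza link.
#' @export
perturb_web <- function(web, seed, sd_fraction = 0.1, max_tries = 100) {
  if (sd_fraction == 0) return(web)
  g0 <- web$groups
  liv <- g0$role != "detritus"
  cons <- g0$role == "consumer"
  for (try in seq_len(max_tries)) {
    set.seed(as.integer(seed) + 7919L * (try - 1L))
    g <- g0
    g$EE <- NA_real_
    g$B[liv] <- g$B[liv] * exp(stats::rnorm(sum(liv), 0, sd_fraction))
    g$PB[liv] <- g$PB[liv] * exp(stats::rnorm(sum(liv), 0, sd_fraction))
    g$QB[cons] <- pmax(g$QB[cons] * exp(stats::rnorm(sum(cons), 0,
                                                     sd_fraction)),
                       g$PB[cons] * 1.2)
    # rescale fleet landings so baseline F is preserved on the jittered B
    fl <- web$fleets
    if (nrow(fl)) {
      sc <- g$B[match(fl$group, g$name)] / g0$B[match(fl$group, g0$name)]
      fl$landings <- fl$landings * sc
    }
    cand <- tryCatch(solve_mass_balance(g, web$diet, fl),
                     error = function(e) NULL)
    if (!is.null(cand)) {
      cand$stanza <- web$stanza
      return(cand)
    }
  }
  stop("perturb_web: rejection rate too high (", max_tries,
       " candidates all unbalanced)")
}
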