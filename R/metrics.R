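# Evaluation statistics for MSE ensembles: grand-mean biomass changes,
# the mu - 0.675 sigma risk statistic, closure/collapse probabilities,
# food-web structure indicators (MTL, Shannon H') and catch summaries.

#' Metrics configuration
#'
#' @param risk_multiplier standard-deviation multiplier of the risk
#'   statistic (0.675: for a normal distribution mu - 0.675 sigma is the
#'   25th percentile).
#' @param collapse_fraction stock-collapse threshold as a fraction of B0.
#' @param ci_multiplier half-width of confidence intervals in standard
#'   errors.
#' @export
metrics_config <- function(risk_multiplier = 0.675, collapse_fraction = 0.05,
                           ci_multiplier = 2) {
  stopifnot(risk_multiplier > 0, collapse_fraction > 0, ci_multiplier > 0)
  list(risk_multiplier = risk_multiplier,
       collapse_fraction = collapse_fraction,
       ci_multiplier = ci_multiplier)
}

# grand mean over runs x years, per group
grand_means <- function(ens) apply(ens$B, 3, mean)

# per-run means (runs x groups)
run_means <- function(ens) apply(ens$B, c(1, 3), mean)

#' Grand-mean biomass change against a paired baseline
#'
#' Per group, \eqn{100 (\langle B\rangle_s - \langle B\rangle_b) /
#' \langle B\rangle_b} where the grand mean is taken over all runs and
#' years of the ensemble.
#'
#' @param ens,baseline \code{mse_ensemble} objects from paired runs (same
#'   master seed, runs and years).
#' @return named vector of percentage changes (NA where the baseline grand
#'   mean is zero).
#' @export
grand_mean_change <- function(ens, baseline) {
  stopifnot(identical(dim(ens$B), dim(baseline$B)))
  gs <- grand_means(ens)
  gb <- grand_means(baseline)
  ifelse(gb > 0, 100 * (gs - gb) / gb, NA_real_)
}

#' Risk statistic: change at mu - 0.675 sigma
#'
#' sigma is the standard deviation of per-run mean biomass across the
#' Monte Carlo runs (between-run variability), so the statistic expresses
#' the lower quartile of scenario outcomes; the change is computed against
#' the baseline grand mean.
#'
#' @inheritParams grand_mean_change
#' @param config a \code{\link{metrics_config}}.
#' @return named vector of percentage changes at mu - 0.675 sigma.
#' @export
risk_stat <- function(ens, baseline, config = metrics_config()) {
  rm_ <- run_means(ens)
  if (nrow(rm_) < 2) stop("risk statistic requires at least 2 runs")
  mu <- colMeans(rm_)
  sg <- apply(rm_, 2, stats::sd)
  low <- mu - config$risk_multiplier * sg
  gb <- grand_means(baseline)
  ifelse(gb > 0, 100 * (low - gb) / gb, NA_real_)
}

#' Fishery closure and stock collapse probabilities
#'
#' Closure: fraction of fishery-years in which the harvest control rule
#' returned F = 0 (exactly zero for constant rules, whose B_lim is 0).
#' Collapse: fraction of run-years with total (adult + juvenile) herring
#' biomass below \code{collapse_fraction * B0}.  Per-run variants (fraction
#' of runs with at least one event) are attached alongside.
#'
#' @param ens an \code{mse_ensemble}.
#' @param b0 unfished total herring biomass (defaults to the ensemble's).
#' @param config a \code{\link{metrics_config}}.
#' @return list with \code{p_closure}, \code{p_collapse} (per-year,
#'   primary) and \code{p_closure_run}, \code{p_collapse_run}.
#' @export
closure_and_collapse <- function(ens, b0 = ens$b0,
                                 config = metrics_config()) {
  herring_B <- apply(ens$B[, , ens$herring, drop = FALSE], 1:2, sum)
  collapsed <- herring_B < config$collapse_fraction * as.numeric(b0)
  list(
    p_closure = mean(ens$closed),
    p_collapse = mean(collapsed),
    p_closure_run = mean(apply(ens$closed, 1, any)),
    p_collapse_run = mean(apply(collapsed, 1, any))
  )
}

#' Biomass-weighted mean trophic level
#'
#' \eqn{MTL = \sum B_i TL_i / \sum B_i} over living (non-detritus) groups;
#' optionally catch-weighted when \code{weights} are supplied.
#'
#' @param B named biomass vector (t/km^2), detritus excluded by the caller
#'   or via \code{exclude}.
#' @param TL trophic levels aligned with \code{B}.
#' @param exclude names of groups to drop (e.g. detritus).
#' @return mean trophic level.
#' @export
mtl <- function(B, TL, exclude = NULL) {
  if (!is.null(exclude)) {
    keep <- !(names(B) %in% exclude)
    B <- B[keep]; TL <- TL[keep]
  }
  stopifnot(length(B) == length(TL), all(B >= 0))
  if (sum(B) == 0) stop("all-zero biomass vector")
  sum(B * TL) / sum(B)
}

#' Shannon-Wiener diversity of biomass proportions
#'
#' \eqn{H' = -\sum p_i \log p_i} with \eqn{p_i = B_i / \sum B_i};
#' zero-biomass groups contribute nothing.
#'
#' @param B biomass vector, not all zero.
#' @return H' in nats.
#' @export
shannon_h <- function(B) {
  stopifnot(all(B >= 0))
  tot <- sum(B)
  if (tot == 0) stop("all-zero biomass vector")
  p <- B[B > 0] / tot
  -sum(p * log(p))
}

# per run-year structure indicators for an ensemble (web supplies TL and
# the detritus roster)
structure_series <- function(ens, web) {
  det <- web$groups$name[web$groups$role == "detritus"]
  keep <- setdiff(ens$groups, det)
  TL <- web$TL[keep]
  d <- dim(ens$B)
  Bm <- ens$B[, , keep, drop = FALSE]
  flat <- matrix(Bm, d[1] * d[2], length(keep))
  mtl_v <- as.vector(flat %*% TL) / rowSums(flat)
  p <- flat / rowSums(flat)
  h_v <- -rowSums(ifelse(p > 0, p * log(p), 0))
  list(mtl = matrix(mtl_v, d[1], d[2]), h = matrix(h_v, d[1], d[2]))
}

#' Herring catch summaries
#'
#' @param ens an \code{mse_ensemble}.
#' @param config a \code{\link{metrics_config}}.
#' @return list with the grand \code{mean} catch, its \code{ci} (+/- 2SE
#'   across per-run means) and the \code{max} over all run-years
#'   (t/km^2/yr, herring pools combined).
#' @export
catch_summaries <- function(ens, config = metrics_config()) {
  hc <- apply(ens$catch[, , ens$herring, drop = FALSE], 1:2, sum)
  per_run <- rowMeans(hc)
  se <- stats::sd(per_run) / sqrt(length(per_run))
  list(mean = mean(hc), ci = config$ci_multiplier * se, max = max(hc))
}

#' Full metrics report for a scenario against its baseline
#'
#' @param ens scenario \code{mse_ensemble}.
#' @param baseline paired baseline ensemble (the unfished \code{Base}
#'   scenario).
#' @param web the \code{balanced_web} the ensembles were run on (supplies
#'   trophic levels).
#' @param config a \code{\link{metrics_config}}.
#' @return a \code{metrics_report}: per-group data frame (grand-mean and
#'   risk percentage changes, +/- 2SE of the scenario per-run means) and
#'   scenario-level indicators (closure/collapse probabilities, catch
#'   summaries, MTL and H' with percentage changes vs baseline).
#' @export
metrics_report <- function(ens, baseline, web, config = metrics_config()) {
  gm <- grand_mean_change(ens, baseline)
  rs <- risk_stat(ens, baseline, config)
  rm_ <- run_means(ens)
  se <- apply(rm_, 2, stats::sd) / sqrt(nrow(rm_))
  gb <- grand_means(baseline)
  se_pct <- ifelse(gb > 0, 100 * config$ci_multiplier * se / gb, NA_real_)

  st_s <- structure_series(ens, web)
  st_b <- structure_series(baseline, web)
  mtl_s <- mean(st_s$mtl); mtl_b <- mean(st_b$mtl)
  h_s <- mean(st_s$h); h_b <- mean(st_b$h)

  probs <- closure_and_collapse(ens, config = config)
  cs <- catch_summaries(ens, config)

  structure(list(
    scenario = ens$scenario$code,
    groups = data.frame(
      group = ens$groups,
      grand_mean_pct = as.vector(gm),
      risk_pct = as.vector(rs),
      ci2se_pct = as.vector(se_pct)),
    p_closure = probs$p_closure,
    p_collapse = probs$p_collapse,
    p_closure_run = probs$p_closure_run,
    p_collapse_run = probs$p_collapse_run,
    mean_catch = cs$mean, max_catch = cs$max, catch_ci = cs$ci,
    mtl = mtl_s, mtl_pct_change = 100 * (mtl_s - mtl_b) / mtl_b,
    shannon_h = h_s, shannon_pct_change = 100 * (h_s - h_b) / h_b
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics for scenario '%s' vs baseline\n", x$scenario))
  cat(sprintf("  p(closure) = %.3f  p(collapse) = %.3f\n",
              x$p_closure, x$p_collapse))
  cat(sprintf("  herring catch: mean %.4f (+/- %.4f), max %.4f t/km^2/yr\n",
              x$mean_catch, x$catch_ci, x$max_catch))
  cat(sprintf("  MTL %.4f (%+.2f%%)  H' %.4f (%+.2f%%)\n",
              x$mtl, x$mtl_pct_change, x$shannon_h, x$shannon_pct_change))
  g <- x$groups
  g$grand_mean_pct <- round(g$grand_mean_pct, 1)
  g$risk_pct <- round(g$risk_pct, 1)
  g$ci2se_pct <- round(g$ci2se_pct, 2)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Bar plot of grand-mean biomass changes by group
#'
#' @param report a \code{metrics_report}.
#' @param risk plot the risk statistic instead of the grand mean.
#' @param ... passed to \code{barplot}.
#' @export
plot_biomass_changes <- function(report, risk = FALSE, ...) {
  g <- report$groups
  v <- if (risk) g$risk_pct else g$grand_mean_pct
  graphics::barplot(v, names.arg = g$group, las = 2, cex.names = 0.7,
                    ylab = if (risk) "% change at mu - 0.675 sigma"
                           else "% change in grand-mean biomass",
                    main = report$scenario, ...)
  graphics::abline(h = 0)
  invisible(report)
}
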