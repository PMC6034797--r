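# ---- input validation helpers -------------------------------------------

living_roles <- c("producer", "consumer")

check_group_table <- function(groups) {
  req <- c("name", "role", "B", "PB", "QB", "EE", "GS", "BA")
  missing_cols <- setdiff(req, names(groups))
  if (length(missing_cols))
    stop("group table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(groups$name))
    stop("duplicate group names: ",
         paste(unique(groups$name[duplicated(groups$name)]), collapse = ", "))
  bad_role <- !groups$role %in% c(living_roles, "detritus")
  if (any(bad_role))
    stop("unknown role for group(s): ", paste(groups$name[bad_role], collapse = ", "))
  liv <- groups$role %in% living_roles
  if (any(liv & (is.na(groups$PB) | groups$PB <= 0)))
    stop("PB must be > 0 for living groups: ",
         paste(groups$name[liv & (is.na(groups$PB) | groups$PB <= 0)], collapse = ", "))
  cons <- groups$role == "consumer"
  if (any(cons & !is.na(groups$QB) & groups$QB < groups$PB))
    stop("QB < PB (growth efficiency > 1) for: ",
         paste(groups$name[cons & !is.na(groups$QB) & groups$QB < groups$PB],
               collapse = ", "))
  both_unknown <- liv & is.na(groups$B) & is.na(groups$EE)
  if (any(both_unknown))
    stop("both B and EE unknown (under-determined) for: ",
         paste(groups$name[both_unknown], collapse = ", "))
  invisible(TRUE)
}

check_diet_matrix <- function(diet, groups, tol = 1e-9) {
  prey_names <- rownames(diet)
  if (!"import" %in% prey_names)
    stop("diet matrix must contain an 'import' row (all zero if unused)")
  if (!setequal(setdiff(prey_names, "import"), groups$name))
    stop("diet matrix rows must be the group names plus 'import'")
  if (!all(colnames(diet) %in% groups$name))
    stop("diet matrix columns must be group names")
  if (any(diet < -tol) || any(diet > 1 + tol))
    stop("diet fractions must lie in [0, 1]")
  roles <- groups$role[match(colnames(diet), groups$name)]
  sums <- colSums(diet)
  is_cons <- roles == "consumer"
  bad <- is_cons & abs(sums - 1) > tol
  if (any(bad))
    stop("diet column(s) do not sum to 1: ",
         paste(sprintf("%s (%.6f)", colnames(diet)[bad], sums[bad]), collapse = ", "))
  bad0 <- !is_cons & sums > tol
  if (any(bad0))
    stop("non-consumer group(s) have nonzero diet columns: ",
         paste(colnames(diet)[bad0], collapse = ", "))
  invisible(TRUE)
}

# Total landings per group, t/km^2/yr.
fleet_landings <- function(fleets, group_names) {
  y <- stats::setNames(numeric(length(group_names)), group_names)
  if (is.null(fleets) || nrow(fleets) == 0) return(y)
  if (any(fleets$landings < 0)) stop("fleet landings must be >= 0")
  unknown <- !fleets$group %in% group_names
  if (any(unknown))
    stop("fleet rows reference unknown group(s): ",
         paste(unique(fleets$group[unknown]), collapse = ", "))
  agg <- tapply(fleets$landings, fleets$group, sum)
  y[names(agg)] <- agg
  y
}

# Full square diet matrix (prey x predator) over the group roster, plus the
# import row kept separately.
expand_diet <- function(diet, group_names) {
  dc <- matrix(0, length(group_names), length(group_names),
               dimnames = list(group_names, group_names))
  prey <- intersect(rownames(diet), group_names)
  dc[prey, colnames(diet)] <- diet[prey, , drop = FALSE]
  imp <- stats::setNames(numeric(length(group_names)), group_names)
  imp[colnames(diet)] <- diet["import", ]
  list(dc = dc, import = imp)
}

# ---- mass balance --------------------------------------------------------

# Internal solver: fills in unknown B / EE by solving the induced linear
# system; performs no EE range check so that rebalance_predators() can probe
# infeasible candidates.
solve_balance_core <- function(groups, diet, fleets, tol = 1e-9) {
  check_group_table(groups)
  check_diet_matrix(diet, groups, tol = tol)
  n <- nrow(groups)
  nm <- groups$name
  ed <- expand_diet(diet, nm)
  dc <- ed$dc
  Y <- fleet_landings(fleets, nm)
  liv <- which(groups$role %in% living_roles)

  B <- groups$B
  EE <- groups$EE
  QB <- ifelse(is.na(groups$QB), 0, groups$QB)
  PB <- ifelse(is.na(groups$PB), 0, groups$PB)
  BA <- ifelse(is.na(groups$BA), 0, groups$BA)

  unk <- character(0)  # one entry per unknown: "B:<name>" or "EE:<name>"
  for (i in liv) {
    if (is.na(B[i])) unk <- c(unk, paste0("B:", nm[i]))
    if (is.na(EE[i])) unk <- c(unk, paste0("EE:", nm[i]))
  }
  if (length(unk)) {
    A <- matrix(0, length(liv), length(unk),
                dimnames = list(nm[liv], unk))
    b <- numeric(length(liv))
    for (r in seq_along(liv)) {
      i <- liv[r]
      # production term B_i PB_i EE_i
      if (is.na(EE[i])) {
        A[r, paste0("EE:", nm[i])] <- A[r, paste0("EE:", nm[i])] + B[i] * PB[i]
      } else if (is.na(B[i])) {
        A[r, paste0("B:", nm[i])] <- A[r, paste0("B:", nm[i])] + PB[i] * EE[i]
      } else {
        b[r] <- b[r] - B[i] * PB[i] * EE[i]
      }
      # predation term sum_j B_j QB_j DC_ij
      for (j in seq_len(n)) {
        coef <- QB[j] * dc[i, j]
        if (coef == 0) next
        if (is.na(B[j])) {
          A[r, paste0("B:", nm[j])] <- A[r, paste0("B:", nm[j])] - coef
        } else {
          b[r] <- b[r] + coef * B[j]
        }
      }
      b[r] <- b[r] + Y[i] + BA[i]
    }
    qrA <- qr(A)
    if (qrA$rank < length(unk)) {
      und <- sub("^(B|EE):", "", unk)
      stop("mass-balance system is singular; under-determined group(s): ",
           paste(unique(und), collapse = ", "))
    }
    x <- qr.coef(qrA, b)
    for (k in seq_along(unk)) {
      kind <- sub(":.*$", "", unk[k])
      g <- sub("^(B|EE):", "", unk[k])
      i <- match(g, nm)
      if (kind == "B") B[i] <- x[k] else EE[i] <- x[k]
    }
  }
  # groups with no predation demand and no catch get EE = 0 even if B = 0
  EE[is.nan(EE)] <- 0
  list(B = B, EE = EE, PB = PB, QB = QB, BA = BA, Y = Y,
       dc = dc, import = ed$import, living = liv, names = nm)
}

balance_residuals <- function(sol) {
  n <- length(sol$names)
  res <- stats::setNames(numeric(n), sol$names)
  demand <- as.vector(sol$dc %*% (sol$B * sol$QB))
  for (i in sol$living) {
    res[i] <- sol$B[i] * sol$PB[i] * sol$EE[i] -
      demand[i] - sol$Y[i] - sol$BA[i]
  }
  res
}

#' Solve an Ecopath-style mass balance
#'
#' For every living functional group the balance
#' \deqn{B_i (P/B)_i EE_i = \sum_j B_j (Q/B)_j DC_{ij} + Y_i + BA_i}
#' must hold: production retained in the system (via the ecotrophic
#' efficiency \eqn{EE_i}) equals predation by all consumers plus fishery
#' landings \eqn{Y_i} and biomass accumulation \eqn{BA_i}.  Per group at
#' most one of \code{B} or \code{EE} may be unknown (\code{NA}); the
#' unknowns are solved jointly from the induced linear system.
#'
#' Detritus is treated as a passive pool: it receives egestion
#' (\code{GS * Q}) and non-predation deaths, and its implied EE is reported
#' but not constrained to [0, 1].
#'
#' @param groups data.frame with columns \code{name, role, B, PB, QB, EE,
#'   GS, BA}; \code{role} is one of \code{"producer"}, \code{"consumer"},
#'   \code{"detritus"}.  \code{NA} marks an unknown \code{B} or \code{EE}.
#' @param diet prey-by-predator matrix of diet fractions whose rows are the
#'   group names plus an \code{"import"} row; consumer columns sum to 1.
#' @param fleets data.frame with columns \code{fleet, group, landings}
#'   (baseline landings, t/km^2/yr), or \code{NULL} for an unfished web.
#' @param import_tl trophic level assigned to imported diet (default 1).
#' @param tol numeric tolerance on balance residuals and EE range checks.
#' @return an object of class \code{balanced_web}: the resolved group table
#'   (with \code{M0 = PB (1 - EE)} and trophic levels \code{TL}), the diet
#'   matrix, fleets, and per-group balance residuals.
#' @examples
#' gr <- data.frame(
#'   name = c("phyto", "grazer"), role = c("producer", "consumer"),
#'   B = c(10, 1), PB = c(10, 2), QB = c(0, 5), EE = c(NA, 0),
#'   GS = c(0, 0.2), BA = 0)
#' dm <- matrix(c(0, 1, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
#'              dimnames = list(c("phyto", "grazer", "import"),
#'                              c("phyto", "grazer")))
#' web <- solve_mass_balance(gr, dm, NULL)
#' ee(web)["phyto"]  # 0.05
#' @export
solve_mass_balance <- function(groups, diet, fleets = NULL, import_tl = 1,
                               tol = 1e-9) {
  groups <- as.data.frame(groups)
  sol <- solve_balance_core(groups, diet, fleets, tol = tol)
  liv <- sol$living
  ee_lo <- sol$EE[liv] < -tol
  ee_hi <- sol$EE[liv] > 1 + tol
  if (any(ee_lo | ee_hi)) {
    off <- sol$names[liv][ee_lo | ee_hi]
    vals <- sol$EE[liv][ee_lo | ee_hi]
    stop("imbalance: solved EE outside [0, 1] for ",
         paste(sprintf("%s (EE = %.4f)", off, vals), collapse = ", "))
  }
  sol$EE[liv] <- pmin(pmax(sol$EE[liv], 0), 1)  # shave numerical fuzz only
  res <- balance_residuals(sol)
  if (any(abs(res) > 1e-6))
    stop("imbalance: residual exceeds tolerance for ",
         paste(sol$names[abs(res) > 1e-6], collapse = ", "))

  groups$B <- sol$B
  groups$EE <- sol$EE
  groups$GS[is.na(groups$GS)] <- 0
  groups$BA[is.na(groups$BA)] <- 0
  is_liv <- groups$role %in% living_roles
  M0 <- ifelse(is_liv, groups$PB * (1 - groups$EE), 0)

  # passive detritus bookkeeping
  det <- which(groups$role == "detritus")
  det_in <- sum(groups$GS * sol$QB * sol$B) +
    sum((sol$PB * sol$B * (1 - sol$EE))[is_liv])
  if (length(det)) {
    det_demand <- as.vector(sol$dc %*% (sol$B * sol$QB))[det]
    groups$EE[det] <- if (det_in > 0) det_demand / det_in else 0
  }

  web <- structure(list(
    groups = groups,
    diet = diet,
    fleets = if (is.null(fleets)) data.frame(fleet = character(),
                                             group = character(),
                                             landings = numeric()) else fleets,
    landings = sol$Y,
    stanza = NULL,
    M0 = stats::setNames(M0, groups$name),
    import_tl = import_tl,
    residuals = res
  ), class = "balanced_web")
  web$TL <- compute_trophic_levels(web)
  web
}

#' @export
print.balanced_web <- function(x, ...) {
  g <- x$groups
  cat(sprintf("balanced food web: %d groups (%d producers, %d consumers, %d detritus), %d fleet rows\n",
              nrow(g), sum(g$role == "producer"), sum(g$role == "consumer"),
              sum(g$role == "detritus"), nrow(x$fleets)))
  tab <- data.frame(group = g$name, role = g$role,
                    B = round(g$B, 4), PB = g$PB, QB = g$QB,
                    EE = round(g$EE, 4), TL = round(x$TL, 3),
                    M0 = round(x$M0, 4), Y = round(x$landings, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$stanza))
    cat(sprintf("stanza link: %s -> %s (transition %g yr)\n",
                x$stanza$juvenile, x$stanza$adult, x$stanza$transition_age))
  invisible(x)
}

#' Accessors for balanced webs
#'
#' @param web a \code{balanced_web}.
#' @return named numeric vectors over the group roster.
#' @export
biomass <- function(web) stats::setNames(web$groups$B, web$groups$name)

#' @rdname biomass
#' @export
ee <- function(web) stats::setNames(web$groups$EE, web$groups$name)

#' @rdname biomass
#' @export
trophic_level <- function(web) web$TL

# ---- trophic levels ------------------------------------------------------

#' Trophic levels of a food web
#'
#' Solves the fixed point \eqn{TL_j = 1 + \sum_i DC_{ij} TL_i} with
#' producers and detritus anchored at TL = 1 and imported diet at
#' \code{import_tl}.
#'
#' @param web a \code{balanced_web} (or any list with \code{groups},
#'   \code{diet} and \code{import_tl} entries).
#' @return named vector of trophic levels.
#' @export
compute_trophic_levels <- function(web) {
  groups <- web$groups
  nm <- groups$name
  ed <- expand_diet(web$diet, nm)
  n <- length(nm)
  anchored <- groups$role %in% c("producer", "detritus")
  # (I - t(DC)) TL = 1 + import_tl * imp  for consumers; TL = 1 anchored
  A <- diag(n) - t(ed$dc)
  b <- 1 + web$import_tl * ed$import
  A[anchored, ] <- 0
  A[cbind(which(anchored), which(anchored))] <- 1
  b[anchored] <- 1
  tl <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(tl) || anyNA(tl)) {
    bad <- diet_cycle_groups(ed$dc, anchored, ed$import)
    stop("trophic-level system is singular; diet cycle with no producer ",
         "input among: ", paste(bad, collapse = ", "))
  }
  stats::setNames(as.vector(tl), nm)
}

# Consumers with no dietary path down to a producer/detritus/import source.
diet_cycle_groups <- function(dc, anchored, import) {
  n <- nrow(dc)
  grounded <- anchored | import > 0
  repeat {
    # a consumer is grounded once any of its prey is grounded
    new <- grounded | (t(dc) %*% grounded > 0)[, 1]
    if (all(new == grounded)) break
    grounded <- new
  }
  rownames(dc)[!grounded]
}

# ---- predator rebalancing ------------------------------------------------

#' Reduce predator biomasses until the web balances
#'
#' Reproduces the procedure of setting predator (e.g. marine mammal)
#' biomasses to the highest values compatible with mass balance after a
#' reduction in prey biomass: each adjustable group's biomass is raised to
#' the largest value not exceeding its bound such that every EE stays
#' within [0, 1], by per-group bisection iterated to joint feasibility.
#'
#' @param groups,diet,fleets as in \code{\link{solve_mass_balance}}; the
#'   adjustable groups must have a (candidate) \code{B} and known or
#'   unknown EE as usual.
#' @param adjustable character vector of group names whose biomass may be
#'   lowered.
#' @param bounds named numeric vector of maximum biomasses for the
#'   adjustable groups (defaults to their candidate \code{B}).
#' @param tol bisection tolerance on biomass (t/km^2).
#' @return a \code{balanced_web} with the adjusted biomasses.
#' @export
rebalance_predators <- function(groups, diet, fleets = NULL, adjustable,
                                bounds = NULL, tol = 1e-8) {
  groups <- as.data.frame(groups)
  idx <- match(adjustable, groups$name)
  if (anyNA(idx)) stop("unknown adjustable group(s): ",
                       paste(adjustable[is.na(idx)], collapse = ", "))
  if (is.null(bounds)) bounds <- stats::setNames(groups$B[idx], adjustable)
  bounds <- bounds[adjustable]

  max_ee <- function(gtab) {
    sol <- solve_balance_core(gtab, diet, fleets)
    max(sol$EE[sol$living], na.rm = TRUE)
  }
  feasible <- function(gtab) max_ee(gtab) <= 1 + 1e-9

  g0 <- groups
  g0$B[idx] <- 0
  if (!feasible(g0))
    stop("imbalance: web infeasible even with zero biomass for ",
         paste(adjustable, collapse = ", "))

  cur <- groups
  cur$B[idx] <- bounds
  if (feasible(cur))
    return(solve_mass_balance(cur, diet, fleets))

  # phase 1: largest common scale of the bounds that is jointly feasible
  # (shared prey constraints bind all adjustable groups symmetrically)
  lo <- 0; hi <- 1
  probe <- cur
  while (hi - lo > tol / max(bounds)) {
    mid <- (lo + hi) / 2
    probe$B[idx] <- mid * bounds
    if (feasible(probe)) lo <- mid else hi <- mid
  }
  cur$B[idx] <- lo * bounds
  # phase 2: re-raise each group towards its own bound while staying
  # feasible (restores maximality when a group's own prey have slack)
  for (round in 1:20) {
    prev <- cur$B[idx]
    for (k in seq_along(idx)) {
      blo <- cur$B[idx[k]]; bhi <- bounds[k]
      probe <- cur
      probe$B[idx[k]] <- bhi
      if (feasible(probe)) { cur$B[idx[k]] <- bhi; next }
      while (bhi - blo > tol) {
        mid <- (blo + bhi) / 2
        probe$B[idx[k]] <- mid
        if (feasible(probe)) blo <- mid else bhi <- mid
      }
      cur$B[idx[k]] <- blo
    }
    if (max(abs(cur$B[idx] - prev)) < tol) break
  }
  solve_mass_balance(cur, diet, fleets)
}

# ---- stock-recruitment ---------------------------------------------------

#' Beverton-Holt recruitment
#'
#' \eqn{R(S) = \alpha S / (1 + S/\beta)}: linear with slope \eqn{\alpha}
#' near the origin (high steepness, characteristic of forage fish) and
#' saturating at \eqn{\alpha\beta} for large spawner biomass.
#'
#' @param spawner_B spawner (adult) biomass, t/km^2; vectorized.
#' @param link list with \code{bh_alpha} (maximum recruits per unit spawner)
#'   and \code{bh_beta} (density-dependence scale, t/km^2).
#' @return recruitment, i.e. juvenile biomass inflow (t/km^2/yr).
#' @export
recruitment <- function(spawner_B, link) {
  stopifnot(all(spawner_B >= 0), link$bh_alpha > 0, link$bh_beta > 0)
  link$bh_alpha * spawner_B / (1 + spawner_B / link$bh_beta)
}

#' Define a juvenile-adult stanza link
#'
#' @param juvenile,adult group names of the linked pools.
#' @param transition_age years spent in the juvenile pool; maturation is
#'   modelled as a flow at rate 1/transition_age per year.
#' @param bh_alpha,bh_beta Beverton-Holt parameters; left \code{NA} they are
#'   calibrated when dynamics are derived so that baseline recruitment
#'   balances baseline maturation with spawners at 50\% of the recruitment
#'   asymptote.
#' @export
stanza_link <- function(juvenile, adult, transition_age = 2,
                        bh_alpha = NA_real_, bh_beta = NA_real_) {
  stopifnot(transition_age > 0)
  list(juvenile = juvenile, adult = adult, transition_age = transition_age,
       bh_alpha = bh_alpha, bh_beta = bh_beta)
}
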