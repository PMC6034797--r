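# Static mass balance, trophic levels, predator rebalancing and the
# stock-recruitment link.

two_group_web <- function(ee_phyto = NA_real_, b_grazer = 1, qb = 5,
                          fleets = NULL) {
  gr <- data.frame(
    name = c("phyto", "grazer"), role = c("producer", "consumer"),
    B = c(10, b_grazer), PB = c(10, 2), QB = c(0, qb),
    EE = c(ee_phyto, 0), GS = c(0, 0.2), BA = 0)
  dm <- matrix(c(0, 1, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("phyto", "grazer", "import"),
                               c("phyto", "grazer")))
  list(groups = gr, diet = dm, fleets = fleets)
}

test_that("mass balance solves single unknowns and flags imbalance", {
  w <- two_group_web()
  web <- solve_mass_balance(w$groups, w$diet, w$fleets)
  # hand-solved: EE = (1 * 5 * 1.0) / (10 * 10)
  expect_equal(unname(ee(web)["phyto"]), 0.05)
  # a group with no predators and no catch has EE = 0
  expect_equal(unname(ee(web)["grazer"]), 0)
  expect_lt(max(abs(web$residuals)), 1e-9)

  # unknown biomass instead: grazer B solved from phyto balance
  gr <- w$groups
  gr$B[1] <- 10; gr$EE[1] <- 0.05
  gr$B[2] <- NA
  web2 <- solve_mass_balance(gr, w$diet)
  expect_equal(unname(biomass(web2)["grazer"]), 1)

  # demand exceeding production must error, not silently clip
  w_bad <- two_group_web(b_grazer = 25)
  expect_error(solve_mass_balance(w_bad$groups, w_bad$diet),
               "EE outside")

  # both unknown per group is rejected up-front
  gr_bad <- w$groups
  gr_bad$B[1] <- NA
  expect_error(solve_mass_balance(gr_bad, w$diet), "under-determined|both B and EE")
})

test_that("diet matrix validation names the offending predator", {
  w <- two_group_web()
  d_bad <- w$diet
  d_bad["phyto", "grazer"] <- 0.9
  expect_error(solve_mass_balance(w$groups, d_bad), "grazer")
})

test_that("reference web balances with EE in [0, 1] everywhere", {
  web <- ref_web()
  liv <- web$groups$role != "detritus"
  expect_true(all(web$groups$EE[liv] >= 0 & web$groups$EE[liv] <= 1))
  expect_lt(max(abs(web$residuals)), 1e-9)
  expect_true(all(web$M0 >= 0))
})

test_that("trophic levels solve the diet fixed point", {
  web <- ref_web()
  tl <- compute_trophic_levels(web)
  expect_equal(unname(tl["phytoplankton"]), 1)
  expect_equal(unname(tl["detritus"]), 1)
  # consumer on 100% producers sits exactly at TL 2
  expect_equal(unname(tl["copepods"]), 2)
  # 50/50 producer + TL-2 herbivore -> 2.5
  gr <- data.frame(
    name = c("p", "h", "c"), role = c("producer", "consumer", "consumer"),
    B = c(100, 10, 1), PB = c(10, 5, 2), QB = c(0, 15, 8),
    EE = c(NA, NA, 0), GS = 0.2, BA = 0)
  dm <- matrix(0, 4, 3, dimnames = list(c("p", "h", "c", "import"),
                                        c("p", "h", "c")))
  dm["p", "h"] <- 1
  dm["p", "c"] <- 0.5; dm["h", "c"] <- 0.5
  web2 <- solve_mass_balance(gr, dm)
  expect_equal(unname(web2$TL), c(1, 2, 2.5))
})

test_that("trophic levels agree with a brute-force Jacobi solver", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 10
    roles <- c(rep("producer", 3), rep("consumer", 7))
    gr <- data.frame(name = paste0("g", 1:n), role = roles,
                     B = runif(n, 1, 10), PB = runif(n, 1, 5),
                     QB = c(rep(0, 3), runif(7, 5, 10)),
                     EE = 0, GS = 0.2, BA = 0)
    gr$EE <- NA_real_
    dm <- matrix(0, n + 1, n, dimnames = list(c(gr$name, "import"), gr$name))
    for (j in 4:n) {             # each consumer eats lower-indexed groups
      prey <- seq_len(j - 1)
      w <- runif(length(prey))
      dm[prey, j] <- w / sum(w)
    }
    weblike <- list(groups = gr, diet = dm, import_tl = 1)
    tl <- compute_trophic_levels(weblike)
    # independent oracle: 200 Jacobi sweeps of TL = 1 + t(DC) %*% TL
    dc <- dm[seq_len(n), ]
    tlj <- rep(1, n)
    for (k in 1:200) tlj <- 1 + as.vector(t(dc) %*% tlj)
    tlj[1:3] <- 1
    expect_lt(max(abs(tl - tlj)), 1e-8)
  }
})

test_that("trophic-level cycles without producer input are reported", {
  gr <- data.frame(name = c("a", "b"), role = "consumer",
                   B = c(1, 1), PB = c(2, 2), QB = c(5, 5),
                   EE = c(NA, NA), GS = 0.2, BA = 0)
  dm <- matrix(c(0, 1, 1, 0, 0, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "import"), c("a", "b")))
  weblike <- list(groups = gr, diet = dm, import_tl = 1)
  expect_error(compute_trophic_levels(weblike), "a, b")
})

test_that("predator rebalancing is maximal, analytic and symmetric", {
  # single predator driving prey EE to 1.2 at B = 1: linear scaling gives
  # the feasible biomass 10/12 exactly
  gr <- data.frame(
    name = c("prey", "pred"), role = c("producer", "consumer"),
    B = c(10, 1), PB = c(1, 0.5), QB = c(0, 12), EE = c(NA, 0),
    GS = c(0, 0.2), BA = 0)
  dm <- matrix(c(0, 1, 0, 0, 0, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("prey", "pred", "import"),
                               c("prey", "pred")))
  web <- rebalance_predators(gr, dm, adjustable = "pred")
  expect_equal(unname(biomass(web)["pred"]), 10 / 12, tolerance = 1e-6)
  expect_equal(unname(ee(web)["prey"]), 1, tolerance = 1e-6)
  # maximality: +0.1% breaks the EE constraint
  g_up <- web$groups
  g_up$B[2] <- g_up$B[2] * 1.001
  g_up$EE[1] <- NA
  expect_error(solve_mass_balance(g_up, dm), "EE outside")

  # two symmetric predators sharing the prey end up with equal biomass
  gr2 <- data.frame(
    name = c("prey", "p1", "p2"), role = c("producer", rep("consumer", 2)),
    B = c(10, 1, 1), PB = c(1, 0.5, 0.5), QB = c(0, 12, 12),
    EE = c(NA, 0, 0), GS = c(0, 0.2, 0.2), BA = 0)
  dm2 <- matrix(0, 4, 3, dimnames = list(c("prey", "p1", "p2", "import"),
                                         c("prey", "p1", "p2")))
  dm2["prey", c("p1", "p2")] <- 1
  web2 <- rebalance_predators(gr2, dm2, adjustable = c("p1", "p2"))
  b <- biomass(web2)
  expect_equal(unname(b["p1"]), unname(b["p2"]), tolerance = 1e-6)
  expect_equal(unname(b["p1"] + b["p2"]), 10 / 12, tolerance = 1e-4)

  # an already-feasible web keeps its bounds
  gr3 <- gr
  gr3$B[2] <- 0.1
  web3 <- rebalance_predators(gr3, dm, adjustable = "pred")
  expect_equal(unname(biomass(web3)["pred"]), 0.1)

  # infeasible even at zero adjustable biomass -> imbalance report
  gr4 <- gr
  gr4$PB[1] <- 0.001
  fl <- data.frame(fleet = "f", group = "prey", landings = 5)
  expect_error(rebalance_predators(gr4, dm, fl, adjustable = "pred"),
               "infeasible")
})

test_that("Beverton-Holt recruitment is steep, saturating and calibrated", {
  link <- list(bh_alpha = 2, bh_beta = 1)
  expect_equal(recruitment(0, link), 0)
  expect_equal(recruitment(1, link), 1)             # 2*1/(1+1)
  expect_equal(recruitment(1e9, link), 2, tolerance = 1e-6)  # asymptote a*b
  # strict concavity: slope at origin exceeds R(S)/S for all S > 0
  S <- 10^seq(-3, 3, length.out = 25)
  expect_true(all(link$bh_alpha > recruitment(S, link) / S))
  # calibration contract: at baseline adult biomass, recruitment equals
  # the baseline maturation outflow of the juvenile pool
  p <- ref_params()
  st <- p$stanza
  R0 <- recruitment(p$B0[st$adult], list(bh_alpha = st$bh_alpha,
                                         bh_beta = st$bh_beta))
  expect_equal(R0, st$m * p$B0[st$juv], tolerance = 1e-12)
})
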