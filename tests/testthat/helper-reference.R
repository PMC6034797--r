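# Shared fixtures, computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_web <- function() memo("web", generate_reference_web())

ref_params <- function() memo("params", derive_dynamics(ref_web(), 2))

ref_b0 <- function() memo("b0", equilibrium_b0(ref_web(), 2,
                                               params = ref_params()))

ref_series <- function() memo("series", generate_productivity_series())

ref_fmsy_s <- function() memo("fmsy_s",
  estimate_fmsy(ref_web(), 2, "stationary", F_grid = seq(0, 1.5, by = 0.02),
                years = 80, params = ref_params()))

ref_fmsy_e <- function() memo("fmsy_e",
  estimate_fmsy(ref_web(), 2, "ecosystem", F_grid = seq(0, 1.5, by = 0.02),
                years = 80, params = ref_params()))

# The main evaluation ensemble grid: every strategy with F_target <= 0.2
# plus the climate-regime variants, at full size (100 runs x 100 years).
ref_grid <- function() memo("grid", {
  scens <- build_scenarios(codes = c("Base", "SOK", "K", "LF1", "LF2",
                                     "LF3", "BC", "BC075", "BC025"),
                           n_runs = 100, years = 100, seed = 1)
  run_scenario_grid(ref_web(), 2, scens, ref_series(), b0 = ref_b0())
})

grid_f_le_02 <- function() {
  g <- ref_grid()
  g[setdiff(names(g), c("Base", "BC075", "BC025"))]
}

herring_grand_mean <- function(ens) {
  mean(apply(ens$B[, , ens$herring, drop = FALSE], c(1, 2), sum))
}

# Minimal hand-built ensemble for metrics unit tests: B is a
# runs x years x groups array.
fake_ensemble <- function(B, catch = array(0, dim(B), dimnames = dimnames(B)),
                          closed = NULL,
                          groups = dimnames(B)[[3]], b0 = 1,
                          herring = groups[1], code = "fake") {
  if (is.null(closed)) closed <- matrix(FALSE, dim(B)[1], dim(B)[2])
  structure(list(
    scenario = structure(list(code = code, fleets = "all",
                              hcr = hcr("constant", 0.2),
                              pp_regime = "all", n_runs = dim(B)[1],
                              years = dim(B)[2], seed = 1L),
                         class = "scenario_spec"),
    B = B, catch = catch, closed = closed,
    F_decided = matrix(0, dim(B)[1], dim(B)[2]),
    F_applied = matrix(0, dim(B)[1], dim(B)[2]),
    forcing = matrix(1, dim(B)[1], dim(B)[2]),
    b0 = b0, adult_share = 1,
    herring = herring, groups = groups, has_fishery = TRUE
  ), class = "mse_ensemble")
}
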