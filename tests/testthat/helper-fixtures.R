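# Shared fixtures, all built in code.

# Closed-form 3-balance fit: S_o = -I3 so the whitened response is v_o
# itself, S_c a column of ones.  With V = I this is OLS of (2,3,4) on 1,
# i.e. vHat = 3, residuals (-1, 0, 1).
toy3Partition <- function() {
  methods::new("FluxPartition",
               Sc = matrix(1, 3, 1), So = -diag(3),
               calcNames = "r", obsNames = c("o1", "o2", "o3"),
               calcIdx = 1L, obsIdx = 2:4)
}

toy3Obs <- function(values = c(2, 3, 4)) {
  observedFluxes(structure(values, names = c("o1", "o2", "o3")),
                 sd = rep(1, 3))
}

toy3Fit <- function(values = c(2, 3, 4), ...) {
  fitGLS(toy3Partition(), toy3Obs(values), noiseModel(diag(3)), ...)
}

# Linear pathway with transports at both ends and a dead side branch
# (true flux exactly zero): A -> B -> out, plus A -> C -> out carrying
# nothing.  Observed: the three transports.
deadBranchScenario <- function(vMain = 10) {
  m <- parseReactionTable(c(
    "upA: -> A",
    "R1: A -> B",
    "R2: A -> C",
    "exB: B ->",
    "exC: C ->"))
  # exB/exC are written in the secretion direction, so their flux equals
  # the producing pathway's flux with positive sign
  v <- structure(c(vMain, vMain, 0, vMain, 0),
                 names = c("upA", "R1", "R2", "exB", "exC"))
  stopifnot(max(abs(stoichiometry(m) %*% v)) < 1e-12)
  obs <- observedFluxes(v[c("upA", "exB", "exC")],
                        sd = c(0.5, 0.5, 0.5))
  methods::new("ToyScenario", model = m, trueFluxes = v,
               observed = c("upA", "exB", "exC"), obs = obs,
               cv = 0.05, seed = 0L)
}

# unit box [lo, hi]^d as a FluxSpace with K = I
boxSpace <- function(d, lo = 0, hi = 1) {
  suppressMessages(buildConstraints(diag(d), seq_len(d),
                                    lower = rep(lo, d), upper = rep(hi, d)))
}

quietFluxSpace <- function(...) suppressMessages(fluxSpace(...))
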