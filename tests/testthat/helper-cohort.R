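# Small-scale simulation parameters for fast module tests, plus memoized
# study-scale runs shared by the acceptance blocks (simulated once per
# session; only scan outputs are kept, never the raw series).

smallParams <- function(seed = 1, ...) {
  simParams(nParticipants = 10, groupSizes = c(meditation = 6, writing = 4),
            nRoi = 15, networkSizes = rep(3L, 5), nTimepoints = 40,
            seed = seed, ...)
}

.adhTestCache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .adhTestCache))
    assign(key, force(expr), envir = .adhTestCache)
  get(key, envir = .adhTestCache)
}

# One study-scale cohort with the planted effect: global scan over the four
# non-modularity global metrics plus the nodal clustering scan.
effectRun <- function(i) memoize(paste0("effect", i), {
  cfg <- runConfig()
  coh <- simulateCohort(simParams(seed = 1000L + i))
  mt <- cohortMetrics(coh$series, coh$affiliation, cfg,
                      metrics = c("clustering", "local_efficiency", "degree",
                                  "global_efficiency", "system_segregation"))
  gs <- globalScan(mt, coh$adherence, cfg, seed = 1000L + i)
  ns <- nodalScan(mt, coh$adherence, cfg, metric = "clustering",
                  seed = 1000L + i)
  list(globalScan = gs, robustNodes = ns$robustNodes,
       associations = ns$associations,
       networks = networkNames(coh$affiliation),
       affiliation = coh$affiliation)
})

# One study-scale null cohort (no planted effect): nodal clustering scan.
nullRun <- function(i) memoize(paste0("null", i), {
  cfg <- runConfig()
  coh <- simulateNullCohort(simParams(seed = 2000L + i))
  mt <- cohortMetrics(coh$series, coh$affiliation, cfg,
                      metrics = c("clustering", "degree"))
  ns <- nodalScan(mt, coh$adherence, cfg, metric = "clustering",
                  seed = 2000L + i)
  list(robustNodes = ns$robustNodes,
       nSignificant = sum(ns$associations$significant),
       nTests = sum(!is.na(ns$associations$p)))
})
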