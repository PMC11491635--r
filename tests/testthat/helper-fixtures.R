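# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tinyTemplate <- function() fixture("tinyTemplate", function()
  makePhantomTemplate(c(16, 16, 16), seed = 0, roleRegionFrac = 0.03))

tinyBank <- function() fixture("tinyBank", function()
  makePhantomFieldBank(tinyTemplate(), nFields = 8, smoothnessSigma = 2.5,
                       amplitude = 1.5, seed = 1))

tinyModels <- function() fixture("tinyModels", function()
  synthbias:::fitTrialModels(tinyTemplate(), deskTrialConfig()))

# a small two-scenario counterfactual dataset (60 subjects) for classifier
# and mitigation unit tests
tinyData <- function() fixture("tinyData", function() {
  cfg <- compositionConfig(nDisease = 30, nNondisease = 30, seed = 7)
  suppressWarnings(buildCounterfactualDatasets(
    tinyTemplate(), tinyModels(), cfg,
    scenarios = c("no_bias", "near_bias"), boundarySigma = 0))
})

tinyDataset <- function(scenario = "near_bias") {
  d <- tinyData()
  list(x = d$volumes[[scenario]], manifest = d$manifests[[scenario]])
}

withSeed <- synthbias:::withSeed

# deterministic synthetic velocity field (not from the phantom bank)
syntheticField <- function(gridDim, seed, sigma = 2, amplitude = 1) {
  withSeed(seed, {
    f <- array(0, c(gridDim, 3L))
    for (c in 1:3)
      f[, , , c] <- gaussianSmooth(array(rnorm(prod(gridDim)), gridDim), sigma)
    m <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
    f * (amplitude / max(m))
  })
}
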