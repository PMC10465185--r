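# Small fixtures built in code; no files on disk.

# a fast, small cohort for structural tests
smallConfig <- function(seed = 1, nDonors = 2L, days = c(2.5, 3.5),
                        cells = 1500L, nk = 150L, ...) {
  simConfig(nDonors = nDonors, dayAssignment = days,
            cellsPerPopulation = cells, nkEventsPerPopulation = nk,
            seed = seed, ...)
}

# hand-built event table: one row block per (subset, condition, stratum spec)
# specs: list(list(subset=, condition=, n=, dead=, generation=), ...)
makeEvents <- function(specs, donor = "D01", day = 2.5, mu0 = 4.5) {
  rows <- lapply(specs, function(s) {
    isT <- s$subset %in% c("Tconv", "Treg")
    data.frame(
      donor_id = donor, subset = s$subset, condition = s$condition, day = day,
      dye_log_intensity = if (isT) mu0 - s$generation * log10(2) else NA_real_,
      dead = rep(c(TRUE, FALSE), c(s$dead, s$n - s$dead)),
      true_generation = if (isT) s$generation else NA_integer_
    )
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new("EventTable", S4Vectors::DataFrame(df))
}

# random generation profiles for property tests
randomProfile <- function(gmax = 6) {
  counts <- stats::rpois(gmax + 1, lambda = stats::runif(gmax + 1, 0, 50))
  if (sum(counts) == 0) counts[1] <- 1
  generationProfile(counts)
}

# fabricate a PosteriorDraws object with known parameter values
fakeDraws <- function(mat, data) {
  new("PosteriorDraws", draws = mat, chain = rep(1L, nrow(mat)),
      nChains = 1L, nWarmup = 0L, nKept = nrow(mat), data = data,
      rhat = stats::setNames(rep(1, ncol(mat)), colnames(mat)),
      accept = 1, kernel = "fixture", converged = TRUE)
}
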