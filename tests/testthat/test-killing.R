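# Gating rules and the specific-killing statistic.

test_that("gateTargets keeps every T cell, dead ones included", {
  ev <- makeEvents(list(
    list(subset = "Tconv", condition = "cocult_br", n = 70, dead = 30, generation = 1),
    list(subset = "Treg", condition = "cocult_br", n = 30, dead = 0, generation = 0),
    list(subset = "NK_br", condition = "cocult_br", n = 500, dead = 10)))
  gated <- gateTargets(ev)
  expect_equal(nrow(gated), 100)
  expect_equal(sum(gated$dead), 30)

  nkOnly <- makeEvents(list(list(subset = "NK_br", condition = "cocult_br",
                                 n = 10, dead = 0)))
  expect_error(gateTargets(nkOnly), class = "nkassay_input_error")
})

test_that("deathFraction is the plain dead proportion", {
  ev <- makeEvents(list(list(subset = "Tconv", condition = "alone", n = 50,
                             dead = 0, generation = 0)))
  expect_equal(deathFraction(ev), 0)
  ev2 <- makeEvents(list(list(subset = "Tconv", condition = "alone", n = 10,
                              dead = 3, generation = 0)))
  expect_equal(deathFraction(ev2), 0.3)
  expect_error(deathFraction(ev2[0, ]), class = "nkassay_input_error")
})

test_that("death fraction on generator output matches configured background", {
  zero <- list(high = 0, low = 0)
  bg10 <- list(high = 0.10, low = 0.10)
  cfg <- smallConfig(seed = 23, nDonors = 1L, days = 2.5, cells = 10000L,
                     donorSdLogit = 0, wellSdLogit = 0,
                     backgroundDeath = list(Tconv = list("2.5" = bg10, "3.5" = bg10),
                                            Treg = list("2.5" = bg10, "3.5" = bg10)),
                     killMeans = list(CD56br = list(Tconv = zero, Treg = zero),
                                      CD56dim = list(Tconv = zero, Treg = zero)))
  panel <- simulatePanel(cfg)
  alone <- panel[panel$subset == "Tconv" & panel$condition == "alone", ]
  se <- 3 * sqrt(0.1 * 0.9 / nrow(alone))
  expect_true(abs(deathFraction(alone) - 0.10) < se)
})

test_that("specificKilling subtracts the matched background and flags negatives", {
  expect_equal(as.numeric(specificKilling(0.25, 0.084)), 0.166)
  expect_equal(as.numeric(specificKilling(0.10, 0.10)), 0)
  neg <- specificKilling(0.05, 0.096)
  expect_equal(as.numeric(neg), -0.046)
  expect_true(attr(neg, "negative"))
  expect_false(attr(specificKilling(0.25, 0.084), "negative"))
  expect_error(specificKilling(1.2, 0.1), class = "nkassay_input_error")
})

test_that("stratification thresholds are day-specific", {
  expect_identical(stratifyGeneration(2, 2.5), "high")
  expect_identical(stratifyGeneration(2, 3.5), "low")
  expect_identical(stratifyGeneration(3, 3.5), "high")
  expect_identical(stratifyGeneration(0, 2.5), "low")
  expect_identical(stratifyGeneration(0, 3.5), "low")
  expect_error(stratifyGeneration(1, 4.5), class = "nkassay_input_error")
  expect_error(stratifyGeneration(-1, 2.5), class = "nkassay_input_error")
})

test_that("buildKillingTable subtracts the same donor's matched stratum", {
  # day 2.5: generations >= 2 are "high"; 0.256 vs 0.126 -> 0.130
  ev <- makeEvents(list(
    list(subset = "Tconv", condition = "cocult_br", n = 1000, dead = 256, generation = 2),
    list(subset = "Tconv", condition = "cocult_br", n = 1000, dead = 90, generation = 1),
    list(subset = "Tconv", condition = "alone", n = 500, dead = 63, generation = 2),
    list(subset = "Tconv", condition = "alone", n = 500, dead = 38, generation = 1)))
  kt <- buildKillingTable(ev, ev$true_generation)
  high <- kt[kt$stratum == "high", ]
  expect_equal(high$dead_fraction, 0.256)
  expect_equal(high$background_fraction, 0.126)
  expect_equal(high$specific_killing, 0.130)
  low <- kt[kt$stratum == "low", ]
  expect_equal(low$specific_killing, 0.090 - 0.076)
  # co-culture identical to control in every stratum -> all zero
  ev0 <- makeEvents(list(
    list(subset = "Tconv", condition = "cocult_br", n = 100, dead = 20, generation = 2),
    list(subset = "Tconv", condition = "alone", n = 100, dead = 20, generation = 2),
    list(subset = "Tconv", condition = "cocult_br", n = 100, dead = 5, generation = 0),
    list(subset = "Tconv", condition = "alone", n = 100, dead = 5, generation = 0)))
  kt0 <- buildKillingTable(ev0, ev0$true_generation)
  expect_true(all(kt0$specific_killing == 0))
})

test_that("a co-culture without its alone control is an error naming it", {
  ev <- makeEvents(list(
    list(subset = "Tconv", condition = "cocult_br", n = 50, dead = 5, generation = 1)))
  expect_error(buildKillingTable(ev, ev$true_generation),
               class = "nkassay_input_error", regexp = "D01.*Tconv")
})

test_that("all-cells dead fraction decomposes exactly over strata", {
  panel <- simulatePanel(smallConfig(seed = 29, cells = 3000L))
  kt <- buildKillingTable(panel, panel$true_generation)
  df <- as.data.frame(kt)
  key <- paste(df$donor_id, df$effector, df$target)
  for (k in unique(key)) {
    sub <- df[key == k, ]
    all <- sub[sub$stratum == "all", ]
    hi <- sub[sub$stratum == "high", ]
    lo <- sub[sub$stratum == "low", ]
    if (nrow(hi) == 0 || nrow(lo) == 0) next
    # weights are the stratum sizes; recover them from the day's threshold
    sel <- panel$subset == all$target & panel$donor_id == all$donor_id &
      panel$condition == ifelse(all$effector == "CD56br", "cocult_br", "cocult_dim")
    str <- stratifyGeneration(panel$true_generation[sel], as.numeric(panel$day[sel]))
    w <- mean(str == "high")
    expect_equal(all$dead_fraction,
                 w * hi$dead_fraction + (1 - w) * lo$dead_fraction,
                 tolerance = 1e-12)
  }
})

test_that("specific killing is invariant to equal death shifts in both arms", {
  base <- list(
    list(subset = "Tconv", condition = "cocult_br", n = 200, dead = 50, generation = 2),
    list(subset = "Tconv", condition = "alone", n = 200, dead = 20, generation = 2))
  shifted <- list(
    list(subset = "Tconv", condition = "cocult_br", n = 200, dead = 70, generation = 2),
    list(subset = "Tconv", condition = "alone", n = 200, dead = 40, generation = 2))
  ev1 <- makeEvents(base); ev2 <- makeEvents(shifted)
  kt1 <- buildKillingTable(ev1, ev1$true_generation)
  kt2 <- buildKillingTable(ev2, ev2$true_generation)
  expect_equal(kt1$specific_killing[kt1$stratum == "high"],
               kt2$specific_killing[kt2$stratum == "high"])
})

test_that("estimated specific killing tracks the configured kill mean", {
  zero <- list(high = 0, low = 0)
  kills <- c(0.05, 0.15, 0.25)
  est <- vapply(kills, function(k) {
    km <- list(CD56br = list(Tconv = list(high = k, low = 0.05), Treg = zero),
               CD56dim = list(Tconv = zero, Treg = zero))
    cfg <- smallConfig(seed = 37, nDonors = 1L, days = 2.5, cells = 20000L,
                       donorSdLogit = 0, wellSdLogit = 0, killMeans = km)
    panel <- simulatePanel(cfg)
    kt <- buildKillingTable(panel, panel$true_generation)
    kt$specific_killing[kt$effector == "CD56br" & kt$target == "Tconv" &
                        kt$stratum == "high"]
  }, numeric(1))
  expect_true(all(abs(est - kills) < 0.015))
  # slope ~ 1 against truth
  expect_equal(unname(coef(lm(est ~ kills))[2]), 1, tolerance = 0.1)
})
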