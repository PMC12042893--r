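test_that("quintile composition reproduces a hand-computed toy table", {
  # 10 tracts, two groups with hand-set shares and populations
  n <- 10
  shares <- cbind(hispanic = seq(0.1, 0.55, by = 0.05),
                  nh_white = seq(0.9, 0.45, by = -0.05),
                  nh_black = 0, nh_asian = 0, nh_aian = 0, nh_other = 0)
  P <- c(100, 200, 300, 400, 500, 500, 400, 300, 200, 100)
  tr <- toyTracts(n, population = P, shares = shares)
  E <- setNames(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), tractIds(tr))
  tab <- quintileComposition(E, tr, groups = c("hispanic", "nh_white"))
  # spreadsheet oracle: quintile breaks at 20/40/60/80th pctls of 0..9
  brk <- quantile(E, c(.2, .4, .6, .8), type = 7, names = FALSE)
  q <- 1 + rowSums(outer(E, brk, ">"))
  for (g in c("hispanic", "nh_white")) {
    gpop <- P * shares[, g]
    for (k in 1:5) {
      want <- 100 * sum(gpop[q == k]) / sum(gpop)
      got <- tab$percent[tab$category == paste0("Q", k) & tab$group == g]
      expect_equal(got, want)
    }
  }
  # conservation: per-group percents total 100
  sums <- tapply(tab$percent, tab$group, sum)
  expect_equal(as.numeric(sums), rep(100, 2), tolerance = 0.1)
})

test_that("quintiles hold ~20% of tracts and catch concentration", {
  set.seed(12)
  n <- 100
  tr <- toyTracts(n, population = rep(1000, n))
  E <- setNames(sample(1000, n), tractIds(tr))  # distinct values
  brk <- quantile(E, c(.2, .4, .6, .8), type = 7, names = FALSE)
  q <- 1 + rowSums(outer(E, brk, ">"))
  expect_true(all(abs(table(q) - 20) <= 1))
  # group living only in the max-exposure tract lands 100% in Q5
  shares <- matrix(0, n, 6,
                   dimnames = list(NULL, c("hispanic", "nh_white",
                                           "nh_black", "nh_asian",
                                           "nh_aian", "nh_other")))
  shares[, "nh_white"] <- 1
  imax <- which.max(E)
  shares[imax, ] <- c(0.5, 0.5, 0, 0, 0, 0)
  tr2 <- toyTracts(n, population = rep(1000, n), shares = shares)
  tab <- quintileComposition(E, tr2, groups = "hispanic")
  expect_equal(tab$percent[tab$category == "Q5"], 100)
})

test_that("exposure independent of composition gives ~20% per quintile", {
  set.seed(33)
  n <- 500
  g <- matrix(rgamma(n * 6, shape = rep(c(9, 15, 1.2, 2.4, 0.6, 1.8),
                                        each = n)), nrow = n)
  shares <- g / rowSums(g)
  colnames(shares) <- c("hispanic", "nh_white", "nh_black", "nh_asian",
                        "nh_aian", "nh_other")
  tr <- toyTracts(n, population = rpois(n, 4000), shares = shares)
  E <- setNames(sample(10000, n), tractIds(tr))  # independent of shares
  tab <- quintileComposition(E, tr)
  expect_true(all(abs(tab$percent - 20) < 6))
})

test_that("degenerate exposure distribution points to manual categories", {
  tr <- toyTracts(5)
  expect_error(quintileComposition(setNames(rep(3, 5), tractIds(tr)), tr),
               "manual")
})

test_that("manual categories bin day counts as labelled", {
  n <- 8
  tr <- toyTracts(n)
  E <- setNames(c(0, 1, 2, 3, 5, 6, 10, 11), tractIds(tr))
  tab <- manualCategoryComposition(E, tr, edges = c(0, 2, 5, 10),
                                   groups = "nh_white")
  # equal populations and identical shares: percent = tract share
  want <- c("0" = 1, "1-2" = 2, "3-5" = 2, "6-10" = 2, ">=11" = 1) / 8 * 100
  expect_equal(setNames(tab$percent, tab$category), want)
  expect_equal(sum(tab$percent), 100, tolerance = 0.1)
  # all-zero exposure: a single category holds everyone
  tabZ <- manualCategoryComposition(setNames(rep(0, n), tractIds(tr)), tr,
                                    groups = "nh_white")
  expect_equal(tabZ$percent[tabZ$category == "0"], 100)
  expect_error(manualCategoryComposition(E, tr, edges = c(1, 2)),
               "start at 0")
  expect_error(manualCategoryComposition(E, tr, edges = c(0, 5, 5)),
               "increasing")
})

test_that("SVI overlay uses a strict cut and needs exposure", {
  tr <- toyTracts(4, svi = c(0.95, 0.91, 0.90, 0.5))
  E <- setNames(c(0, 3, 10, 10), tractIds(tr))
  ov <- sviOverlay(E, tr)
  expect_equal(ov$tracts$flagged, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ov$states$n_flagged, 1)
  # raising the cut never grows the flagged set
  ov99 <- sviOverlay(E, tr, sviCut = 0.99)
  expect_true(all(ov$tracts$flagged | !ov99$tracts$flagged))
  # populated tract with missing SVI (violating the usual invariant,
  # as unvalidated external data can) is excluded with a warning
  trBad <- tr
  trBad@tracts$svi[4] <- NA
  expect_warning(sviOverlay(E, trBad), "missing SVI")
})

test_that("group comparison splits means correctly", {
  tr <- toyTracts(6, tribal = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  E <- setNames(c(24, 24, 10, 10, 10, 100), tractIds(tr))
  restrict <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  cmp <- compareGroups(E, tr, restrict = restrict)
  expect_equal(cmp$mean_days[cmp$group], 24)
  expect_equal(cmp$mean_days[!cmp$group], 10)
  expect_equal(cmp$n_tracts, c(2, 3))
  # single-tract sides report those tracts' values
  cmp1 <- compareGroups(E, tr, restrict = c(TRUE, FALSE, TRUE, rep(FALSE, 3)))
  expect_equal(sort(cmp1$mean_days), c(10, 24))
  expect_error(compareGroups(E, tr, restrict = tractData(tr)$tribal_overlap),
               "empty side")
})

test_that("top tracts rank by days with id tie-breaks", {
  tr <- toyTracts(5)
  E <- setNames(c(5, 9, 9, 1, 0), tractIds(tr))
  top <- topTracts(E, tr, n = 3)
  expect_equal(top$tract_id, c("T02", "T03", "T01"))  # tie T02/T03 by id
  expect_equal(top$days, c(9, 9, 5))
  expect_equal(top$cohort_avg_days, rep(mean(E), 3))
  expect_equal(top$pct_nonwhite, rep(50, 3))  # nh_white share 0.5
  # n beyond the tract count returns everything; all-zero returns zeros
  expect_equal(nrow(topTracts(E, tr, n = 50)), 5)
  z <- topTracts(setNames(rep(0, 5), tractIds(tr)), tr, n = 2)
  expect_equal(z$days, c(0, 0))
  expect_equal(z$cohort_avg_days, c(0, 0))
})
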