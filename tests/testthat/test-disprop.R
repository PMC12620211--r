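# Independent scalar oracle: the four statistics written out long-hand,
# kept deliberately separate from the package's vectorized implementation.
oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  list(
    ror = ror,
    ror_lo = exp(log(ror) - 1.96 * se),
    ror_hi = exp(log(ror) + 1.96 * se),
    prr = a * (c + d) / (c * (a + b)),
    chi2 = (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d)),
    ic = log2(a * n / ((a + c) * (a + b))),
    ebgm = a * n / ((a + c) * (a + b)),
    ebgm05 = exp(log(a * n / ((a + c) * (a + b))) - 1.96 * se))
}

grid_tables <- function(cells = 1:6) {
  expand.grid(a = cells, b = cells, c = cells, d = cells)
}

test_that("contingency tables count report-PT pairs", {
  target <- data.frame(primaryid = c("r1", "r2", "r2"),
                       pt = c("X", "X", "Y"))
  comp <- data.frame(primaryid = c("r3", "r4", "r4"),
                     pt = c("X", "Y", "Z"))
  tabs <- build_tables(target, comp)
  x <- tabs[tabs$pt == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(2L, 1L, 1L, 2L))
  y <- tabs[tabs$pt == "Y", ]
  expect_equal(c(y$a, y$b, y$c, y$d), c(1L, 2L, 1L, 2L))
  # PT absent from the comparator: c = 0, flagged for the correction path
  target2 <- data.frame(primaryid = "r1", pt = "W")
  tabs2 <- build_tables(rbind(target, target2), comp)
  w <- tabs2[tabs2$pt == "W", ]
  expect_equal(w$c, 0L)
  expect_true(faersignal:::apply_correction(w)$corrected)
})

test_that("all four statistics match the arithmetic oracle on the small-table grid", {
  g <- grid_tables()
  got <- cbind(ror_stats(g), prr_stats(g), bcpnn_stats(g), mgps_stats(g))
  want <- t(vapply(seq_len(nrow(g)),
                   function(i) unlist(oracle(g$a[i], g$b[i], g$c[i], g$d[i])),
                   numeric(8)))
  for (stat in colnames(want)) {
    expect_equal(got[[stat]], unname(want[, stat]), tolerance = 1e-12,
                 info = stat)
  }
})

test_that("worked 2x2 example reproduces the direct arithmetic", {
  t <- data.frame(a = 20, b = 80, c = 100, d = 9800)
  r <- ror_stats(t)
  expect_equal(r$ror, 24.5)
  expect_equal(r$ror_lo, 14.4480, tolerance = 1e-4)
  p <- prr_stats(t)
  expect_equal(p$prr, 19.8)
  expect_equal(p$chi2, 301.1, tolerance = 1e-3)
  b <- bcpnn_stats(t)
  expect_equal(b$ic, log2(50 / 3), tolerance = 1e-12)
  m <- mgps_stats(t)
  expect_equal(m$ebgm, 50 / 3, tolerance = 1e-12)
  expect_lt(m$ebgm05, m$ebgm)
})

test_that("the independence table gives null statistics", {
  t <- data.frame(a = 10, b = 10, c = 10, d = 10)
  expect_equal(ror_stats(t)$ror, 1)
  expect_lt(ror_stats(t)$ror_lo, 1)
  expect_gt(ror_stats(t)$ror_hi, 1)
  expect_equal(prr_stats(t)$prr, 1)
  expect_equal(prr_stats(t)$chi2, 0)
  expect_equal(bcpnn_stats(t)$ic, 0)
  expect_equal(mgps_stats(t)$ebgm, 1)
})

test_that("IC equals log2(EBGM) and both share scale invariances", {
  g <- grid_tables()
  ic <- bcpnn_stats(g)$ic
  ebgm <- mgps_stats(g)$ebgm
  expect_equal(ic, log2(ebgm), tolerance = 1e-12)
  # multiplying all cells by k preserves ROR/PRR/EBGM and scales chi2 by k
  t1 <- data.frame(a = 3, b = 7, c = 11, d = 90)
  t3 <- t1 * 3
  expect_equal(ror_stats(t3)$ror, ror_stats(t1)$ror)
  expect_equal(prr_stats(t3)$prr, prr_stats(t1)$prr)
  expect_equal(mgps_stats(t3)$ebgm, mgps_stats(t1)$ebgm)
  expect_equal(prr_stats(t3)$chi2, 3 * prr_stats(t1)$chi2)
})

test_that("point estimates increase strictly in a for fixed b, c, d", {
  for (a in 1:9) {
    lo <- data.frame(a = a, b = 40, c = 25, d = 900)
    hi <- data.frame(a = a + 1, b = 40, c = 25, d = 900)
    expect_lt(ror_stats(lo)$ror, ror_stats(hi)$ror)
    expect_lt(prr_stats(lo)$prr, prr_stats(hi)$prr)
    expect_lt(bcpnn_stats(lo)$ic, bcpnn_stats(hi)$ic)
    expect_lt(mgps_stats(lo)$ebgm, mgps_stats(hi)$ebgm)
  }
})

test_that("zero cells trigger the all-cells correction; the a-gate stays raw", {
  tabs <- data.frame(pt = c("X", "Y"), a = c(5L, 4L), b = c(20L, 30L),
                     c = c(0L, 10L), d = c(500L, 400L))
  s <- disprop_stats(tabs)
  x <- s[s$pt == "X", ]
  expect_true(x$corrected)
  expect_false(s[s$pt == "Y", ]$corrected)
  # corrected cells feed the statistics (finite results, no NA)
  expect_true(is.finite(x$ror) && is.finite(x$ic025))
  expect_equal(x$n, 5L)                       # raw a preserved for screening
  expect_equal(x$ror, (5.5 * 500.5) / (20.5 * 0.5))
  # without correction the zero-cell table is undefined
  s2 <- disprop_stats(tabs, correction = FALSE)
  expect_true(is.na(s2[s2$pt == "X", ]$ror))
  expect_false(s2[s2$pt == "X", ]$positive)   # undefined fails its criterion
})

test_that("screening applies the four criteria and their conjunction", {
  row <- data.frame(n = 26L, ror_lo = 4.3, prr = 6.36, chi2 = 110.97,
                    ic025 = 2.03, ebgm05 = 4.34)
  s <- screen(row)
  expect_true(all(s$ror_pos, s$prr_pos, s$bcpnn_pos, s$mgps_pos, s$positive))

  # a >= 3 gates ROR and PRR regardless of effect size
  tiny <- screen(data.frame(n = 2L, ror_lo = 50, prr = 60, chi2 = 100,
                            ic025 = 3, ebgm05 = 30))
  expect_false(tiny$ror_pos)
  expect_false(tiny$prr_pos)
  expect_false(tiny$positive)

  # strict inequalities at the boundary
  edge <- screen(data.frame(n = 10L, ror_lo = 1, prr = 2, chi2 = 4,
                            ic025 = 0, ebgm05 = 2))
  expect_false(edge$ror_pos)     # ror_lo must exceed 1
  expect_true(edge$prr_pos)      # prr/chi2 thresholds are >=
  expect_false(edge$bcpnn_pos)   # ic025 must exceed 0
  expect_false(edge$mgps_pos)    # ebgm05 must exceed 2
})

test_that("the Bate-style IC variance is an accepted alternative", {
  t <- data.frame(a = 20, b = 80, c = 100, d = 9800)
  delta <- bcpnn_stats(t, variance = "delta")
  bate <- bcpnn_stats(t, variance = "bate")
  expect_equal(delta$ic, bate$ic)            # same point estimate
  expect_false(isTRUE(all.equal(delta$ic_sd, bate$ic_sd)))
  expect_true(bate$ic025 < bate$ic)
})

test_that("a planted strong signal is recovered as positive by the full scan", {
  fix <- shared_sim()
  store <- deduplicate(fix$sim$quarters)
  res <- run_signal_scan(store, abro_spec(), packaged_soc_map())
  eh <- res[res$pt == "ECZEMA HERPETICUM", ]
  expect_equal(nrow(eh), 1L)
  expect_true(eh$positive)
  expect_gt(eh$ror, 5)
  # deterministic ordering: n descending, PT ascending
  expect_true(all(diff(res$n) <= 0))
  # scan never reports a PT outside the SOC filter
  expect_true(all(soc_lookup(packaged_soc_map(), res$pt) ==
                    "Infections and infestations"))
})

test_that("the scan is invariant to input row order and empty cohorts", {
  fix <- shared_sim()
  store <- deduplicate(fix$sim$quarters)
  res <- run_signal_scan(store, abro_spec(), packaged_soc_map())
  set.seed(99)
  shuffled <- store
  for (comp in names(unclass(store))) {
    shuffled[[comp]] <- store[[comp]][sample(nrow(store[[comp]])), ,
                                      drop = FALSE]
    rownames(shuffled[[comp]]) <- NULL
  }
  res2 <- run_signal_scan(shuffled, abro_spec(), packaged_soc_map())
  expect_equal(as.data.frame(res2), as.data.frame(res))

  none <- cohort_spec("NOT A DRUG")
  empty <- run_signal_scan(store, none, packaged_soc_map())
  expect_equal(nrow(empty), 0L)
})
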