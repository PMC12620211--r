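make_store <- function(demo_rows, drug_rows = NULL, reac_rows = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_faers_files(
    dir, demo = demo_rows,
    drug = drug_rows %||% "11$1$PS$A$A",
    reac = reac_rows %||% "11$X")
  read_quarter(paths, "2024Q1")
}

test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  q <- make_store(
    demo_rows = c("1111$111$20230101$45$YR$F$MD$US",
                  "1112$111$20230301$45$YR$F$MD$US",   # later receipt wins
                  "2221$222$20230301$30$YR$M$CN$US",
                  "2229$222$20230301$30$YR$M$CN$US",   # tie: higher id wins
                  "3331$333$20230401$50$YR$F$OT$CA"),
    drug_rows = c("1111$1$PS$OLD$OLD", "1112$1$PS$NEW$NEW",
                  "2229$1$PS$A$A", "3331$1$PS$B$B"),
    reac_rows = c("1111$Sepsis", "1112$Herpes zoster", "2229$Sepsis",
                  "3331$Cellulitis"))
  store <- deduplicate(list(q))
  expect_setequal(store$demo$primaryid, c("1112", "2229", "3331"))
  # children of losing versions are gone
  expect_setequal(store$drug$drugname, c("NEW", "A", "B"))
  expect_setequal(store$reac$pt, c("Herpes zoster", "Sepsis", "Cellulitis"))
})

test_that("deduplication is idempotent and count-preserving on unique caseids", {
  q <- make_store(demo_rows = c("11$1001$20240115$45$YR$F$MD$US",
                                "12$1002$20240210$30$YR$M$CN$US",
                                "13$1003$20240301$70$YR$F$CN$CA"))
  once <- deduplicate(list(q))
  expect_equal(n_reports(once), 3L)          # no duplicates: count preserved
  twice <- deduplicate(once)
  expect_equal(twice$demo, once$demo)
  expect_false(any(duplicated(once$demo$caseid)))
})

test_that("non-numeric primaryids fall back to zero-padded comparison with warning", {
  q <- make_store(demo_rows = c("A9$444$20230301$45$YR$F$MD$US",
                                "B10$444$20230301$45$YR$F$MD$US"))
  expect_warning(store <- deduplicate(list(q)), "zero-padded")
  # width-3 padding: "0A9" < "B10"
  expect_equal(store$demo$primaryid, "B10")
})

test_that("age conversion applies the unit arithmetic and plausibility gate", {
  yrs <- normalize_age(c(730, 6, 45, NA, 500, 24),
                       c("DY", "DEC", "", NA, "YR", "MON"))
  expect_equal(yrs[1], 730 / 365.25, tolerance = 1e-12)
  expect_equal(assign_age_band(yrs[1]), "<18")
  expect_equal(yrs[2], 60)
  expect_equal(assign_age_band(yrs[2]), "18-65")
  expect_equal(yrs[3], 45)             # missing unit, value present: years
  expect_equal(attr(yrs, "n_assumed_years"), 1L)
  expect_true(is.na(yrs[4]))
  expect_true(is.na(yrs[5]))           # 500 years -> implausible
  expect_equal(attr(yrs, "n_implausible"), 1L)
  expect_equal(yrs[6], 2)
})

test_that("age bands use a closed 18-65 interval and partition every report", {
  expect_equal(assign_age_band(c(17.99, 18, 65, 65.01, NA)),
               c("<18", "18-65", "18-65", ">65", "Missing"))
  ages <- c(runif(50, 0, 100), rep(NA, 5))
  bands <- assign_age_band(ages)
  expect_equal(length(bands), 55L)
  expect_true(all(bands %in% c("<18", "18-65", ">65", "Missing")))
})

test_that("outcome classification picks the single most severe category", {
  expect_equal(classify_outcome(c("HO", "DE")), "Death")
  expect_equal(classify_outcome(c("HO", "LT")), "Life-threatening")
  expect_equal(classify_outcome(c("OT", "CA")), "Other")
  expect_equal(classify_outcome(character(0)), "Other")
  expect_warning(res <- classify_outcome(c("ZZ")), "unknown outcome")
  expect_equal(res, "Other")
})

test_that("per-report outcome categories conserve the cohort size", {
  sim <- shared_sim()$sim
  store <- deduplicate(sim$quarters)
  cats <- faersignal:::classify_outcomes_by_report(store)
  expect_equal(length(cats), n_reports(store))
  expect_equal(sum(table(cats)), n_reports(store))
})

test_that("cohort selection requires role, linked indication, SOC and window", {
  store <- demo_store(withr::local_tempdir())
  map <- mini_map()
  spec <- abro_spec()
  sel <- select_cases(store, spec, map)
  expect_setequal(sel$demo$primaryid, c("11", "12", "13"))

  # same report with role C instead of PS is not selected
  store2 <- store
  store2$drug$role_cod[store2$drug$primaryid == "11" &
                         store2$drug$drug_seq == "1"] <- "C"
  expect_false("11" %in% select_cases(store2, spec, map)$demo$primaryid)

  # receipt date before the window excludes the report
  store3 <- store
  store3$demo$fda_dt[store3$demo$primaryid == "11"] <- "20190615"
  expect_false("11" %in% select_cases(store3, spec, map)$demo$primaryid)

  # indication must hang off the target drug's own drug_seq
  store4 <- store
  store4$indi$indi_drug_seq[store4$indi$primaryid == "13"] <- "2"
  expect_false("13" %in% select_cases(store4, spec, map)$demo$primaryid)

  # a PT missing from the map never matches the SOC filter
  small_map <- soc_map("Sepsis", "Infections and infestations")
  sel5 <- select_cases(store, spec, small_map)
  expect_setequal(sel5$demo$primaryid, "12")
  expect_gt(attr(sel5, "unmapped_pts"), 0)
})

test_that("selection output is a subset and sub-filters commute", {
  sim <- shared_sim()$sim
  store <- deduplicate(sim$quarters)
  map <- packaged_soc_map()
  spec <- abro_spec()
  sel <- select_cases(store, spec, map)
  expect_true(all(sel$demo$primaryid %in% store$demo$primaryid))
  # commutation probe: pre-restricting the store to the window first must
  # give the same cohort as applying all filters at once
  fda <- as.integer(store$demo$fda_dt)
  windowed <- faersignal:::subset_case_set(
    store, store$demo$primaryid[fda >= spec$window_start &
                                  fda <= spec$window_end])
  sel2 <- select_cases(windowed, spec, map)
  expect_setequal(sel2$demo$primaryid, sel$demo$primaryid)
})

test_that("infection pairs are SOC-restricted and unique within report", {
  store <- demo_store(withr::local_tempdir())
  map <- mini_map()
  # duplicate PT within report 11 plus a non-infection PT
  store$reac <- rbind(store$reac,
                      data.frame(primaryid = "11", pt = "Herpes zoster"))
  pairs <- extract_infection_pts(store, map)
  expect_equal(sum(pairs$primaryid == "11"), 1L)   # Pyrexia out, PT deduped
  expect_false(any(pairs$pt == "PYREXIA"))
  expect_false(any(duplicated(paste(pairs$primaryid, pairs$pt))))
})

test_that("SOC map rejects conflicting duplicates and misses loudly", {
  expect_error(soc_map(c("Sepsis", "SEPSIS"),
                       c("Infections and infestations", "Other SOC")),
               "more than one SOC")
  map <- mini_map()
  expect_true(is.na(soc_lookup(map, "Not a term")))
  expect_equal(soc_lookup(map, "  herpes   ZOSTER "),
               "Infections and infestations")
})
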