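#' Occupation codes counted as healthcare professionals
#'
#' FAERS OCCP_COD values mapped to reporter type: MD (physician), PH
#' (pharmacist) and HP (other health professional) count as healthcare
#' professionals; CN (consumer), LW (lawyer) and OT (other) as
#' non-healthcare; anything else is missing. The mapping is a convention,
#' not a FAERS rule, and is override-able.
#'
#' @return list with elements `healthcare`, `non_healthcare`
#' @export
default_reporter_map <- function() {
  list(healthcare = c("MD", "PH", "HP"), non_healthcare = c("CN", "LW", "OT"))
}

count_table <- function(values, levels, n) {
  counts <- vapply(levels, function(l) sum(values == l), integer(1))
  pct <- if (n > 0) round_half_up(100 * counts / n, 1) else rep(0, length(levels))
  data.frame(level = levels, count = unname(counts), pct = unname(pct),
             stringsAsFactors = FALSE)
}

#' Summarize the clinical characteristics of a cohort
#'
#' Produces the descriptive layout conventional for spontaneous-report
#' studies: counts and percentages by sex, age band, single most-severe
#' outcome, top three reporter countries, reporter type and reporting year
#' (from FDA_DT). Within each category the counts sum to the cohort size;
#' percentages are count/size rounded half-up to one decimal.
#'
#' @param case_set a selected `case_set`
#' @param reporter_map occupation-code mapping, see [default_reporter_map()]
#' @return a `cohort_summary`: list of data.frames (`sex`, `age`,
#'   `outcome`, `country`, `reporter`, `year`) plus `n_reports`; attribute
#'   `empty` is TRUE for an empty cohort (all percentages reported as 0)
#' @export
summarize_cohort <- function(case_set, reporter_map = default_reporter_map()) {
  n <- n_reports(case_set)
  demo <- case_set$demo

  sex <- norm_term(demo$sex)
  sex[!sex %in% c("F", "M")] <- "Missing"
  sex[sex == "F"] <- "Female"
  sex[sex == "M"] <- "Male"

  age_years <- normalize_age(demo$age, demo$age_cod)
  band <- assign_age_band(age_years)

  outcome <- classify_outcomes_by_report(case_set)

  country <- trimws(demo$reporter_country)
  country[!nzchar(country)] <- "Missing"
  top <- table(country)
  # top-3 with lexicographic tie-break
  top3 <- if (length(top) > 0) {
    ord <- order(-as.integer(top), names(top))
    names(top)[ord][seq_len(min(3, length(top)))]
  } else {
    character(0)
  }

  occ <- norm_term(demo$occp_cod)
  rmap <- reporter_map
  rep_type <- ifelse(occ %in% rmap$healthcare, "Healthcare professional",
                     ifelse(occ %in% rmap$non_healthcare,
                            "Non-healthcare professional", "Missing"))

  year <- substr(demo$fda_dt, 1, 4)
  years <- sort(unique(year))

  out <- list(
    n_reports = n,
    sex = count_table(sex, c("Female", "Male", "Missing"), n),
    age = count_table(band, c("<18", "18-65", ">65", "Missing"), n),
    outcome = count_table(outcome, c("Death", "Disability", "Hospitalization",
                                     "Life-threatening", "Other"), n),
    country = count_table(country, top3, n),
    reporter = count_table(rep_type, c("Healthcare professional",
                                       "Non-healthcare professional",
                                       "Missing"), n),
    year = count_table(year, years, n))
  attr(out, "empty") <- n == 0L
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_reports, "reports\n")
  for (cat_name in c("sex", "age", "outcome", "country", "reporter", "year")) {
    cat("--", cat_name, "--\n")
    df <- x[[cat_name]]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-28s %6d (%.1f%%)\n", df$level[i], df$count[i],
                  df$pct[i]))
    }
  }
  invisible(x)
}

#' Compare the positive signal sets of two drugs
#'
#' Set algebra over the preferred terms flagged positive in each drug's
#' screened signal table: shared signals, signals unique to each drug, and
#' per-shared-PT side-by-side ROR intervals for forest plotting.
#'
#' @param results_a,results_b screened `signal_stats` data.frames
#' @param labels length-2 character vector naming the two drugs
#' @return a `signal_comparison`: list with `shared`, `only_a`, `only_b`
#'   (sorted PT character vectors), `paired_rows` (data.frame `pt`, `drug`,
#'   `ror`, `ror_lo`, `ror_hi`, two rows per shared PT) and `labels`
#' @export
compare_signals <- function(results_a, results_b,
                            labels = c("drug_a", "drug_b")) {
  pos_a <- results_a$pt[results_a$positive]
  pos_b <- results_b$pt[results_b$positive]
  shared <- sort(intersect(pos_a, pos_b))
  only_a <- sort(setdiff(pos_a, pos_b))
  only_b <- sort(setdiff(pos_b, pos_a))
  if (length(shared) > 0) {
    ia <- match(shared, results_a$pt)
    ib <- match(shared, results_b$pt)
    paired <- data.frame(
      pt = rep(shared, each = 2),
      drug = rep(labels, times = length(shared)),
      ror = as.vector(rbind(results_a$ror[ia], results_b$ror[ib])),
      ror_lo = as.vector(rbind(results_a$ror_lo[ia], results_b$ror_lo[ib])),
      ror_hi = as.vector(rbind(results_a$ror_hi[ia], results_b$ror_hi[ib])),
      stringsAsFactors = FALSE)
  } else {
    paired <- data.frame(pt = character(0), drug = character(0),
                         ror = numeric(0), ror_lo = numeric(0),
                         ror_hi = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(shared = shared, only_a = only_a, only_b = only_b,
                 paired_rows = paired, labels = labels),
            class = "signal_comparison")
}

#' @export
print.signal_comparison <- function(x, ...) {
  cat("<signal_comparison>", x$labels[1], "vs", x$labels[2], "\n")
  cat("  shared:", length(x$shared), " only", x$labels[1], ":",
      length(x$only_a), " only", x$labels[2], ":", length(x$only_b), "\n")
  invisible(x)
}

#' Default concomitant-medication exclusion list
#'
#' Medications commonly co-prescribed in atopic dermatitis whose presence
#' in a report triggers exclusion in the sensitivity re-analysis: topical
#' corticosteroids and calcineurin inhibitors, mupirocin, second-generation
#' antihistamines, and dupilumab.
#'
#' @return character vector of drug names (normalized form)
#' @export
default_exclusion_list <- function() {
  norm_term(c("Betamethasone valerate", "Beclometasone", "Tacrolimus",
              "Pimecrolimus", "Mupirocin", "Desloratadine", "Levocetirizine",
              "Dupilumab"))
}

#' Concomitant-medication sensitivity re-analysis
#'
#' Re-runs the signal scan after dropping every target-cohort report that
#' contains any drug entry (any role) whose name or active ingredient
#' matches the exclusion set. The comparator population is left untouched,
#' so only the target cells of each 2x2 table can change. An empty
#' exclusion set reproduces the primary analysis exactly.
#'
#' @param store deduplicated `case_set`
#' @param spec a [cohort_spec()]
#' @param map a [soc_map()]
#' @param exclusion_names drug names to exclude on, normalized like the
#'   drug dictionary; default [default_exclusion_list()]
#' @param ... further arguments passed to [run_signal_scan()]
#' @return screened `signal_stats` for the reduced cohort; attribute
#'   `excluded_reports` gives the number of cohort reports removed
#' @export
sensitivity_rerun <- function(store, spec, map,
                              exclusion_names = default_exclusion_list(),
                              ...) {
  target <- select_cases(store, spec, map)
  excl <- norm_term(exclusion_names)
  hit_rows <- match_drug_reports(target$drug, excl)
  drop_ids <- unique(hit_rows$primaryid)
  reduced <- subset_case_set(target, setdiff(target$demo$primaryid, drop_ids))
  out <- run_signal_scan(store, spec, map, target = reduced, ...)
  attr(out, "excluded_reports") <- length(drop_ids)
  out
}

#' Export forest-plot data for shared signals
#'
#' Writes a CSV with two rows per shared preferred term (one per drug),
#' columns `pt`, `drug`, `ror`, `ror_lo`, `ror_hi`, PTs in deterministic
#' sorted order; the plotting-tool-agnostic contract for a side-by-side
#' forest plot.
#'
#' @param comparison a [compare_signals()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
export_forest_data <- function(comparison, path) {
  stopifnot(inherits(comparison, "signal_comparison"))
  df <- comparison$paired_rows
  df <- df[order(df$pt, match(df$drug, comparison$labels)), , drop = FALSE]
  utils::write.csv(format_full_precision(df, c("ror", "ror_lo", "ror_hi")),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
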