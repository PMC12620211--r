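#' Build 2x2 contingency tables for each preferred term
#'
#' For every PT reported at least once with the target drug, forms the
#' classic fourfold table against the comparator population. The counting
#' unit is the report-PT pair (each PT at most once per report): `a` =
#' target reports mentioning the PT, `b` = the target drug's other AE
#' pairs, `c` = comparator reports mentioning the PT, `d` = the
#' comparator's other AE pairs.
#'
#' @param target_pairs data.frame of `(primaryid, pt)` pairs for the target
#'   drug, de-duplicated within report
#' @param comparator_pairs same for the comparator population
#' @return data.frame with columns `pt`, `a`, `b`, `c`, `d`, sorted by `a`
#'   descending then PT; attributes `target_total_pairs`,
#'   `comparator_total_pairs`, `counting_unit`
#' @export
build_tables <- function(target_pairs, comparator_pairs) {
  tt <- nrow(target_pairs)
  ct <- nrow(comparator_pairs)
  if (tt == 0L) {
    out <- data.frame(pt = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0))
  } else {
    a_tab <- table(target_pairs$pt)
    c_tab <- table(comparator_pairs$pt)
    pt <- names(a_tab)
    a <- as.integer(a_tab)
    cc <- as.integer(c_tab[pt])
    cc[is.na(cc)] <- 0L
    if (any(a > tt)) stop("inconsistent pair counts: a exceeds total target pairs")
    out <- data.frame(pt = pt, a = a, b = tt - a, c = cc, d = ct - cc,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$a, out$pt), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "target_total_pairs") <- tt
  attr(out, "comparator_total_pairs") <- ct
  attr(out, "counting_unit") <- "report-PT pair (PT at most once per report)"
  out
}

# Haldane-Anscombe continuity correction: if any cell is zero, add 0.5 to
# all four cells. Screening's "a >= 3" gate always uses the raw a.
apply_correction <- function(t) {
  corrected <- t$a == 0 | t$b == 0 | t$c == 0 | t$d == 0
  for (col in c("a", "b", "c", "d")) {
    t[[col]] <- t[[col]] + 0.5 * corrected
  }
  t$corrected <- corrected
  t
}

#' Reporting odds ratio with 95 percent confidence interval
#'
#' ROR = ad/(bc); the interval is log-normal,
#' exp(ln ROR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param t data.frame (or list) with numeric fields `a`, `b`, `c`, `d`;
#'   vectorized over rows. Cells must be positive (apply the continuity
#'   correction first if any cell is zero); zero cells yield NA with a
#'   reason.
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`
#' @export
ror_stats <- function(t) {
  bad <- t$a <= 0 | t$b <= 0 | t$c <= 0 | t$d <= 0
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  ror <- (t$a * t$d) / (t$b * t$c)
  out <- data.frame(ror = ror,
                    ror_lo = exp(log(ror) - 1.96 * se),
                    ror_hi = exp(log(ror) + 1.96 * se))
  out[bad, ] <- NA_real_
  if (any(bad)) attr(out, "undefined") <- "zero cell without correction"
  out
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' PRR = a(c+d) / (c(a+b)); chi2 is the uncorrected Pearson statistic
#' (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @inheritParams ror_stats
#' @return data.frame with columns `prr`, `chi2`
#' @export
prr_stats <- function(t) {
  n <- t$a + t$b + t$c + t$d
  bad <- t$c <= 0 | (t$a + t$b) <= 0 | (t$a + t$c) <= 0 | (t$b + t$d) <= 0 |
    (t$c + t$d) <= 0
  prr <- t$a * (t$c + t$d) / (t$c * (t$a + t$b))
  chi2 <- (t$a * t$d - t$b * t$c)^2 * n /
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
  out <- data.frame(prr = prr, chi2 = chi2)
  out[bad, ] <- NA_real_
  out
}

#' Information component (BCPNN) with its lower interval bound
#'
#' IC = log2( a N / ((a+c)(a+b)) ), the base-2 log of the observed to
#' expected joint reporting ratio. The default interval is
#' IC +- 2 * sd with sd obtained by the delta method from the log-scale
#' standard error, sd = sqrt(1/a + 1/b + 1/c + 1/d) / ln 2. The
#' alternative `variance = "bate"` uses the Bayesian posterior variance of
#' the early BCPNN literature.
#'
#' @inheritParams ror_stats
#' @param variance `"delta"` (default) or `"bate"`
#' @return data.frame with columns `ic`, `ic_sd`, `ic025`
#' @export
bcpnn_stats <- function(t, variance = c("delta", "bate")) {
  variance <- match.arg(variance)
  n <- t$a + t$b + t$c + t$d
  bad <- t$a <= 0 | (t$a + t$c) <= 0 | (t$a + t$b) <= 0
  ic <- log2(t$a * n / ((t$a + t$c) * (t$a + t$b)))
  if (variance == "delta") {
    ic_sd <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d) / log(2)
  } else {
    ic_sd <- sqrt(bate_vic(t$a, t$a + t$b, t$a + t$c, n))
  }
  out <- data.frame(ic = ic, ic_sd = ic_sd, ic025 = ic - 2 * ic_sd)
  out[bad, ] <- NA_real_
  out
}

# Posterior variance of the information component with the conventional
# BCPNN priors (gamma11 = alpha1 = beta1 = 1, alpha = beta = 2).
bate_vic <- function(a, row1, col1, n) {
  g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
  gam <- g11 * (n + al) * (n + be) / ((row1 + a1) * (col1 + b1))
  ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
     (n - row1 + al - a1) / ((row1 + a1) * (1 + n + al)) +
     (n - col1 + be - b1) / ((col1 + b1) * (1 + n + be))) / log(2)^2
}

#' Empirical Bayes geometric mean (relative reporting ratio form)
#'
#' EBGM = a N / ((a+c)(a+b)) with the log-normal lower bound
#' EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). This is the
#' relative reporting ratio with a log-normal interval, the form used in
#' much of the recent FAERS signal-detection literature; it applies no
#' gamma-mixture shrinkage (DuMouchel's MGPS fit is out of scope). Note the
#' point estimate is identical to 2^IC.
#'
#' @inheritParams ror_stats
#' @return data.frame with columns `ebgm`, `ebgm05`
#' @export
mgps_stats <- function(t) {
  n <- t$a + t$b + t$c + t$d
  bad <- t$a <= 0 | t$b <= 0 | t$c <= 0 | t$d <= 0
  ebgm <- t$a * n / ((t$a + t$c) * (t$a + t$b))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  out <- data.frame(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se))
  out[bad, ] <- NA_real_
  out
}

#' Default screening thresholds
#'
#' The four-algorithm screening criteria: ROR lower 95 percent bound > 1
#' with a >= 3; PRR >= 2 with chi2 >= 4 and a >= 3; IC025 > 0;
#' EBGM05 > 2.
#'
#' @return named list of thresholds
#' @export
default_thresholds <- function() {
  list(ror_lo = 1, prr = 2, chi2 = 4, min_a = 3L, ic025 = 0, ebgm05 = 2)
}

#' Apply the combined screening criteria
#'
#' Sets the per-algorithm flags and the combined verdict: a PT is a
#' positive signal only if it meets all four criteria simultaneously
#' (the conjunction deliberately trades sensitivity for a low
#' false-positive rate). The `a >= 3` gates always use the raw count `n`,
#' never the continuity-corrected cell. Inequalities are exact IEEE
#' comparisons; an undefined statistic fails its criterion.
#'
#' @param s data.frame with columns `n`, `ror_lo`, `prr`, `chi2`, `ic025`,
#'   `ebgm05` (a `signal_stats` frame or the reference-table layout)
#' @param thresholds list as from [default_thresholds()]
#' @return `s` with logical columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `positive` added or replaced
#' @export
screen <- function(s, thresholds = default_thresholds()) {
  th <- thresholds
  flag <- function(x) !is.na(x) & x
  s$ror_pos <- flag(s$ror_lo > th$ror_lo & s$n >= th$min_a)
  s$prr_pos <- flag(s$prr >= th$prr & s$chi2 >= th$chi2 & s$n >= th$min_a)
  s$bcpnn_pos <- flag(s$ic025 > th$ic025)
  s$mgps_pos <- flag(s$ebgm05 > th$ebgm05)
  s$positive <- s$ror_pos & s$prr_pos & s$bcpnn_pos & s$mgps_pos
  s
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' @param tables data.frame from [build_tables()]
#' @param correction apply the all-cells +0.5 continuity correction to
#'   tables with a zero cell (default TRUE)
#' @param ic_variance variance convention for the information component,
#'   see [bcpnn_stats()]
#' @param thresholds screening thresholds, see [default_thresholds()]
#' @return a `signal_stats` data.frame: `pt`, `n` (raw a), raw cells
#'   `a`,`b`,`c`,`d`, the statistics, flags and `corrected`
#' @export
disprop_stats <- function(tables, correction = TRUE,
                          ic_variance = c("delta", "bate"),
                          thresholds = default_thresholds()) {
  ic_variance <- match.arg(ic_variance)
  if (nrow(tables) == 0L) {
    return(empty_signal_stats())
  }
  raw <- tables
  work <- if (correction) apply_correction(tables) else
    cbind(tables, corrected = FALSE)
  out <- data.frame(pt = raw$pt, n = raw$a, a = raw$a, b = raw$b, c = raw$c,
                    d = raw$d, stringsAsFactors = FALSE)
  out <- cbind(out, ror_stats(work), prr_stats(work),
               bcpnn_stats(work, variance = ic_variance), mgps_stats(work))
  out$corrected <- work$corrected
  out <- screen(out, thresholds)
  class(out) <- c("signal_stats", "data.frame")
  out
}

empty_signal_stats <- function() {
  out <- data.frame(pt = character(0), n = integer(0), a = integer(0),
                    b = integer(0), c = integer(0), d = integer(0),
                    ror = numeric(0), ror_lo = numeric(0),
                    ror_hi = numeric(0), prr = numeric(0), chi2 = numeric(0),
                    ic = numeric(0), ic_sd = numeric(0), ic025 = numeric(0),
                    ebgm = numeric(0), ebgm05 = numeric(0),
                    ror_pos = logical(0), prr_pos = logical(0),
                    bcpnn_pos = logical(0), mgps_pos = logical(0),
                    positive = logical(0), corrected = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("signal_stats", "data.frame")
  out
}

# comparator primaryids: reports whose required-role drug set does not
# include any target drug name; optionally restricted to reports carrying
# one of the cohort's indication PTs (scope = "ad")
comparator_ids <- function(store, spec, scope = c("full", "indication")) {
  scope <- match.arg(scope)
  target_rows <- match_drug_reports(store$drug, spec$target_drug_names,
                                    role = spec$role_required)
  ids <- setdiff(store$demo$primaryid, unique(target_rows$primaryid))
  if (scope == "indication") {
    with_indi <- unique(store$indi$primaryid[
      norm_term(store$indi$indi_pt) %in% spec$indication_pts])
    ids <- intersect(ids, with_indi)
  }
  ids
}

#' Run the full disproportionality signal scan
#'
#' Selects the target cohort with [select_cases()], takes as comparator
#' every deduplicated report whose primary-suspect drug is not a target
#' drug (optionally restricted to the same indication), builds one 2x2
#' table per preferred term, restricts to PTs mapping to the cohort's SOC
#' filter, computes the four statistics and applies the combined screen.
#'
#' @param store deduplicated `case_set` (the full database)
#' @param spec a [cohort_spec()]
#' @param map a [soc_map()]
#' @param correction,ic_variance,thresholds passed to [disprop_stats()]
#' @param comparator_scope `"full"` (whole database background, default) or
#'   `"indication"` (background restricted to reports with the cohort's
#'   indication)
#' @param target optional pre-selected target `case_set` (used by the
#'   sensitivity re-analysis); when supplied, `select_cases()` is skipped
#' @return a `signal_stats` data.frame, one row per SOC-filtered PT with
#'   `a >= 1`, ordered by `n` descending then PT; attrition counts in
#'   `attr(, "attrition")`
#' @export
run_signal_scan <- function(store, spec, map, correction = TRUE,
                            ic_variance = c("delta", "bate"),
                            thresholds = default_thresholds(),
                            comparator_scope = c("full", "indication"),
                            target = NULL) {
  ic_variance <- match.arg(ic_variance)
  comparator_scope <- match.arg(comparator_scope)
  if (is.null(target)) target <- select_cases(store, spec, map)
  comp_ids <- comparator_ids(store, spec, scope = comparator_scope)
  comparator <- subset_case_set(store, comp_ids)
  target_pairs <- all_ae_pairs(target)
  comp_pairs <- all_ae_pairs(comparator)
  tables <- build_tables(target_pairs, comp_pairs)
  socs <- soc_lookup(map, tables$pt)
  tables <- tables[!is.na(socs) & socs == spec$soc_filter, , drop = FALSE]
  out <- disprop_stats(tables, correction = correction,
                       ic_variance = ic_variance, thresholds = thresholds)
  out <- out[order(-out$n, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_stats", "data.frame")
  attr(out, "attrition") <- list(
    store_reports = n_reports(store),
    target_reports = n_reports(target),
    comparator_reports = length(comp_ids),
    target_pairs = nrow(target_pairs),
    comparator_pairs = nrow(comp_pairs),
    soc_pts = nrow(tables))
  attr(out, "counting_unit") <- "report-PT pair (PT at most once per report)"
  out
}
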