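#' Deduplicate FAERS reports across quarters
#'
#' FAERS distributes successive versions of the same case as separate rows:
#' reports sharing a CASEID are versions of one case. Per FDA practice, for
#' each CASEID the entry with the most recent FDA_DT is retained; when both
#' CASEID and FDA_DT tie, the record with the highest PRIMARYID wins. Child
#' records (DRUG/REAC/OUTC/RPSR/THER/INDI) of non-retained versions, and
#' orphan child records without a DEMO parent, are dropped.
#'
#' @param quarters list of `faers_quarter` objects, or a single `case_set`
#'   (in which case deduplication is re-applied, which is a no-op on an
#'   already deduplicated store).
#' @return A `case_set`: list of data.frames `demo`, `drug`, `reac`, `outc`,
#'   `rpsr`, `ther`, `indi` restricted to the retained report versions.
#'   `demo` gains integer columns `fda_dt_int` and the retained flag is
#'   implicit (one row per caseid).
#' @export
deduplicate <- function(quarters) {
  if (inherits(quarters, "case_set")) {
    tabs <- unclass(quarters)
  } else {
    if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
    tabs <- combine_quarters(quarters)
  }
  demo <- tabs$demo
  if (nrow(demo) == 0L) {
    return(structure(tabs, class = "case_set"))
  }
  demo <- demo[!duplicated(demo$primaryid), , drop = FALSE]
  fda <- suppressWarnings(as.integer(demo$fda_dt))
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  if (anyNA(pid_num)) {
    warning("non-numeric primaryid(s) present; ties broken on zero-padded string")
    width <- max(nchar(demo$primaryid))
    pid_rank <- rank(formatC(demo$primaryid, width = width, flag = "0"))
  } else {
    pid_rank <- pid_num
  }
  ord <- order(fda, pid_rank, decreasing = TRUE)
  demo <- demo[ord, , drop = FALSE]
  demo <- demo[!duplicated(demo$caseid), , drop = FALSE]
  demo <- demo[order(demo$caseid), , drop = FALSE]  # deterministic row order
  keep <- demo$primaryid
  out <- list(demo = demo)
  for (comp in setdiff(names(tabs), "demo")) {
    child <- tabs[[comp]]
    out[[comp]] <- child[child$primaryid %in% keep, , drop = FALSE]
    attr(out[[comp]], "orphan") <- NULL
    rownames(out[[comp]]) <- NULL
  }
  rownames(out$demo) <- NULL
  structure(out, class = "case_set")
}

# stack quarter tables, excluding orphan-flagged child rows
combine_quarters <- function(quarters) {
  comps <- names(faers_components)
  out <- list()
  for (comp in comps) {
    parts <- lapply(quarters, function(q) {
      tab <- q$tables[[comp]]
      orphan <- attr(tab, "orphan")
      if (!is.null(orphan) && any(orphan)) tab <- tab[!orphan, , drop = FALSE]
      tab
    })
    out[[comp]] <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    if (is.null(out[[comp]])) out[[comp]] <- empty_df(faers_components[[comp]])
  }
  out
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set>", nrow(x$demo), "deduplicated reports\n")
  invisible(x)
}

#' Number of reports in a case set
#' @param case_set a `case_set`
#' @return integer count
#' @export
n_reports <- function(case_set) nrow(case_set$demo)

subset_case_set <- function(case_set, primaryids) {
  out <- lapply(unclass(case_set), function(tab) {
    tab[tab$primaryid %in% primaryids, , drop = FALSE]
  })
  structure(out, class = "case_set")
}

#' Convert an age value/unit pair to years
#'
#' FAERS ages come with a unit code: DEC (decades), YR (years), MON
#' (months), WK (weeks), DY (days), HR (hours). A present value with a
#' missing unit is assumed to be years. Implausible results (negative or
#' above 120 years) are set to missing.
#'
#' @param age_value numeric vector (or character coercible to numeric)
#' @param age_unit character vector of unit codes
#' @return numeric vector of ages in years (NA where unusable), with
#'   attributes `n_assumed_years` and `n_implausible`
#' @export
normalize_age <- function(age_value, age_unit) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- norm_term(age_unit)
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_map[u])
  assumed <- is.na(f) & !is.na(v)        # unit missing/unknown, value present
  f[assumed] <- 1
  yrs <- v * f
  implausible <- !is.na(yrs) & (yrs < 0 | yrs > 120)
  yrs[implausible] <- NA_real_
  structure(yrs, n_assumed_years = sum(assumed),
            n_implausible = sum(implausible))
}

#' Assign an age band
#'
#' Bands follow the usual spontaneous-report summary layout: `<18`,
#' `18-65` (closed interval, both bounds included), `>65`, `Missing`.
#'
#' @param age_years numeric vector of ages in years (NA = missing)
#' @return character vector of band labels
#' @export
assign_age_band <- function(age_years) {
  out <- rep("Missing", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years <= 65] <- "18-65"
  out[!is.na(age_years) & age_years > 65] <- ">65"
  out
}

#' Collapse a report's outcome codes to its single most severe category
#'
#' FAERS OUTC codes: DE death, LT life-threatening, DS disability, HO
#' hospitalization, CA congenital anomaly, RI required intervention, OT
#' other. Each report is assigned one category by severity priority
#' DE > LT > DS > HO; everything else (CA, RI, OT, no code) is "Other", so
#' category counts always sum to the cohort size.
#'
#' @param outcomes character vector of OUTC codes for one report
#' @return one of "Death", "Life-threatening", "Disability",
#'   "Hospitalization", "Other"
#' @export
classify_outcome <- function(outcomes) {
  codes <- norm_term(outcomes)
  known <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")
  if (length(codes) > 0 && any(!codes %in% c(known, ""))) {
    warning("unknown outcome code(s) treated as Other: ",
            paste(unique(codes[!codes %in% c(known, "")]), collapse = ", "))
  }
  if ("DE" %in% codes) return("Death")
  if ("LT" %in% codes) return("Life-threatening")
  if ("DS" %in% codes) return("Disability")
  if ("HO" %in% codes) return("Hospitalization")
  "Other"
}

# vectorized over a case set: one category per demo row
classify_outcomes_by_report <- function(case_set) {
  codes <- norm_term(case_set$outc$outc_cod)
  pid <- case_set$outc$primaryid
  sev <- c(DE = 4, LT = 3, DS = 2, HO = 1)
  s <- unname(sev[codes])
  s[is.na(s)] <- 0
  best <- tapply(s, pid, max)
  lvl <- c("Other", "Hospitalization", "Disability", "Life-threatening",
           "Death")
  out <- rep("Other", nrow(case_set$demo))
  hit <- match(case_set$demo$primaryid, names(best))
  out[!is.na(hit)] <- lvl[best[hit[!is.na(hit)]] + 1]
  out
}

#' Read a PT to SOC mapping table
#'
#' MedDRA is licensed and cannot ship with the package; analyses take the
#' preferred-term to System Organ Class mapping as an input CSV with
#' columns `pt` and `soc`. Both sides are whitespace/case-normalized. A
#' lookup of an unmapped PT is a detectable miss (NA), never a silent
#' default.
#'
#' @param path CSV path with columns `pt`, `soc`
#' @return a `soc_map` object
#' @export
read_soc_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pt", "soc") %in% names(df)))
  soc_map(df$pt, df$soc)
}

#' Build a PT to SOC map from vectors
#'
#' @param pt character vector of preferred terms
#' @param soc character vector of System Organ Classes, same length
#' @return a `soc_map`: named character vector keyed by normalized PT
#' @export
soc_map <- function(pt, soc) {
  key <- norm_term(pt)
  val <- trimws(as.character(soc))
  dup <- duplicated(key)
  if (any(dup & val[match(key, key)] != val)) {
    stop("PT maps to more than one SOC: ",
         paste(unique(pt[dup & val[match(key, key)] != val]), collapse = ", "))
  }
  structure(setNames(val[!dup], key[!dup]), class = "soc_map")
}

#' Look up the SOC of preferred terms
#'
#' @param map a `soc_map`
#' @param pts character vector of PTs (normalized internally)
#' @return character vector of SOC strings, NA for unmapped PTs
#' @export
soc_lookup <- function(map, pts) {
  unname(unclass(map)[norm_term(pts)])
}

#' Cohort selection parameters
#'
#' @param target_drug_names drug name variants (generic, brand, salt)
#'   identifying the suspect drug of interest; matched case-insensitively
#'   after whitespace normalization against DRUG.drugname and DRUG.prod_ai
#' @param indication_pts PT strings accepted as the indication of interest
#' @param soc_filter System Organ Class the reaction must map to
#' @param window_start,window_end inclusive YYYYMMDD bounds on FDA_DT
#' @param role_required drug role code the matching drug entry must carry
#'   (default "PS", primary suspect)
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(target_drug_names,
                        indication_pts = c("Dermatitis atopic",
                                           "Atopic dermatitis"),
                        soc_filter = "Infections and infestations",
                        window_start = 20190701L,
                        window_end = 20250331L,
                        role_required = "PS") {
  stopifnot(length(target_drug_names) >= 1, window_start <= window_end)
  structure(list(target_drug_names = norm_term(target_drug_names),
                 indication_pts = norm_term(indication_pts),
                 soc_filter = trimws(soc_filter),
                 window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 role_required = norm_term(role_required)),
            class = "cohort_spec")
}

# primaryids whose DRUG table has a row in `role` matching `names` on
# drugname or active ingredient
match_drug_reports <- function(drug_tab, names_norm, role = NULL) {
  hit <- norm_term(drug_tab$drugname) %in% names_norm |
    norm_term(drug_tab$prod_ai) %in% names_norm
  if (!is.null(role)) hit <- hit & norm_term(drug_tab$role_cod) %in% role
  drug_tab[hit, , drop = FALSE]
}

#' Select the analysis cohort
#'
#' Retains deduplicated reports that satisfy all of: (i) some drug entry
#' with the required role whose name or active ingredient matches the
#' target set; (ii) an indication record linked to that same drug entry
#' (via `indi_drug_seq`) in the accepted indication PTs; (iii) at least one
#' reaction PT mapping to the SOC filter; (iv) FDA_DT inside the window.
#' PTs absent from the SOC map never match the filter and are tallied in
#' the `unmapped_pts` attribute of the result.
#'
#' @param store a deduplicated `case_set`
#' @param spec a [cohort_spec()]
#' @param map a [soc_map()]
#' @return the selected `case_set` (subset of `store`), with attribute
#'   `unmapped_pts` (count of distinct reaction PTs not in the map)
#' @export
select_cases <- function(store, spec, map) {
  stopifnot(inherits(store, "case_set"), inherits(spec, "cohort_spec"))
  target_rows <- match_drug_reports(store$drug, spec$target_drug_names,
                                    role = spec$role_required)
  # indication linked to the matched drug entry itself
  indi_key <- paste(store$indi$primaryid, store$indi$indi_drug_seq)
  indi_ok <- indi_key[norm_term(store$indi$indi_pt) %in% spec$indication_pts]
  drug_key <- paste(target_rows$primaryid, target_rows$drug_seq)
  ids_drug_indi <- unique(target_rows$primaryid[drug_key %in% indi_ok])

  socs <- soc_lookup(map, store$reac$pt)
  unmapped <- unique(norm_term(store$reac$pt)[is.na(socs)])
  ids_soc <- unique(store$reac$primaryid[!is.na(socs) &
                                           socs == spec$soc_filter])

  fda <- suppressWarnings(as.integer(store$demo$fda_dt))
  ids_window <- store$demo$primaryid[!is.na(fda) &
                                       fda >= spec$window_start &
                                       fda <= spec$window_end]

  keep <- Reduce(intersect, list(ids_drug_indi, ids_soc, ids_window))
  out <- subset_case_set(store, keep)
  attr(out, "unmapped_pts") <- length(unmapped)
  out
}

#' Extract a cohort's infection-SOC report/PT pairs
#'
#' Returns each report's reaction PTs restricted to one System Organ
#' Class, counted at most once per report (the standard disproportionality
#' counting unit).
#'
#' @param case_set a selected `case_set`
#' @param map a [soc_map()]
#' @param soc SOC to restrict to
#' @return data.frame with columns `primaryid`, `pt` (normalized)
#' @export
extract_infection_pts <- function(case_set, map,
                                  soc = "Infections and infestations") {
  pt <- norm_term(case_set$reac$pt)
  socs <- soc_lookup(map, pt)
  keep <- !is.na(socs) & socs == soc
  pairs <- data.frame(primaryid = case_set$reac$primaryid[keep],
                      pt = pt[keep], stringsAsFactors = FALSE)
  pairs[!duplicated(paste(pairs$primaryid, pairs$pt)), , drop = FALSE]
}

# all (report, PT) pairs of a case set, de-duplicated within report
all_ae_pairs <- function(case_set) {
  pt <- norm_term(case_set$reac$pt)
  pairs <- data.frame(primaryid = case_set$reac$primaryid, pt = pt,
                      stringsAsFactors = FALSE)
  pairs[!duplicated(paste(pairs$primaryid, pairs$pt)), , drop = FALSE]
}
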