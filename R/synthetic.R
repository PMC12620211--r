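#' Sequence of calendar quarters
#'
#' @param from,to quarter labels like "2019Q3"
#' @return character vector of consecutive quarter labels, inclusive
#' @export
quarter_seq <- function(from, to) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", from), grepl("^[0-9]{4}Q[1-4]$", to))
  idx <- function(l) as.integer(substr(l, 1, 4)) * 4L +
    as.integer(substr(l, 6, 6)) - 1L
  i <- idx(from):idx(to)
  paste0(i %/% 4, "Q", i %% 4 + 1)
}

#' Default synthetic drug universe
#'
#' The two JAK-1 inhibitors of interest plus a background of common
#' primary-suspect drugs, with sampling prevalences. The background is
#' deliberately generic; it stands in for "all other drugs" in the
#' database, not for any real reporting distribution.
#'
#' @return data.frame with columns `name`, `prevalence`
#' @export
default_drug_universe <- function() {
  data.frame(
    name = c("ABROCITINIB", "UPADACITINIB", "DUPILUMAB", "METHOTREXATE",
             "ADALIMUMAB", "IBUPROFEN", "AMOXICILLIN", "ATORVASTATIN"),
    prevalence = c(0.03, 0.07, 0.10, 0.10, 0.25, 0.20, 0.10, 0.15),
    stringsAsFactors = FALSE)
}

#' Default background PT distribution
#'
#' Baseline per-draw reaction probabilities over a mix of infection-SOC
#' preferred terms and common non-infection PTs; pairs with the packaged
#' PT-to-SOC mini-map. Probabilities are normalized at sampling time.
#'
#' @return data.frame with columns `pt`, `soc`, `prob`
#' @export
default_pt_background <- function() {
  inf <- "Infections and infestations"
  data.frame(
    pt = c("HERPES ZOSTER", "ECZEMA HERPETICUM", "CELLULITIS",
           "HERPES SIMPLEX", "SEPSIS", "SKIN INFECTION", "FOLLICULITIS",
           "PNEUMONIA", "INFLUENZA", "URINARY TRACT INFECTION",
           "APPENDICITIS", "SEPTIC SHOCK", "ERYSIPELAS", "OSTEOMYELITIS",
           "NASOPHARYNGITIS",
           "PRURITUS", "DERMATITIS ATOPIC", "RASH", "HEADACHE", "NAUSEA",
           "FATIGUE", "DIARRHOEA", "ARTHRALGIA", "DIZZINESS", "VOMITING",
           "ALOPECIA", "INSOMNIA", "PYREXIA", "COUGH", "DYSPNOEA",
           "HYPERTENSION", "ANXIETY", "PAIN", "WEIGHT INCREASED",
           "DRUG INEFFECTIVE"),
    soc = c(rep(inf, 15),
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Nervous system disorders",
            "Gastrointestinal disorders",
            "General disorders and administration site conditions",
            "Gastrointestinal disorders",
            "Musculoskeletal and connective tissue disorders",
            "Nervous system disorders",
            "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders",
            "Psychiatric disorders",
            "General disorders and administration site conditions",
            "Respiratory, thoracic and mediastinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Vascular disorders",
            "Psychiatric disorders",
            "General disorders and administration site conditions",
            "Investigations",
            "General disorders and administration site conditions"),
    prob = c(0.010, 0.002, 0.006, 0.004, 0.004, 0.004, 0.003, 0.010, 0.008,
             0.008, 0.003, 0.002, 0.002, 0.002, 0.010,
             0.10, 0.06, 0.09, 0.08, 0.08, 0.07, 0.06, 0.05, 0.05, 0.04,
             0.03, 0.03, 0.04, 0.03, 0.03, 0.03, 0.02, 0.04, 0.02, 0.048),
    stringsAsFactors = FALSE)
}

#' Parameters of the synthetic FAERS generator
#'
#' Defines a fully specified sampling model for FAERS-like data with known
#' ground truth: report counts, a background PT distribution, planted
#' drug-PT reporting-rate ratios, a duplication process exercising the
#' CASEID/FDA_DT/PRIMARYID deduplication rule, demographic missingness and
#' a concomitant-medication model. The same spec and seed always generate
#' byte-identical files.
#'
#' @param n_reports number of unique reports (before duplication)
#' @param quarters quarter labels the reports are spread over
#' @param drugs data.frame `name`, `prevalence` of primary-suspect drugs
#'   (prevalences are normalized to sum to 1)
#' @param pt_background data.frame `pt`, `soc`, `prob`: per-draw reaction
#'   probabilities
#' @param planted_signals data.frame `drug`, `pt`, `rate_ratio`: the named
#'   drug's per-draw probability of the PT is multiplied by `rate_ratio`
#'   (and the drug's distribution renormalized)
#' @param indication_model probability a target-drug report carries the
#'   atopic dermatitis indication on its suspect drug
#' @param background_indication same probability for non-target drugs
#' @param target_drugs drug names treated as targets by `indication_model`
#' @param duplication_rate fraction of caseids emitted as two report
#'   versions
#' @param tie_rate fraction of duplicate versions whose FDA_DT equals the
#'   winner's (exercising the PRIMARYID tie-break)
#' @param missingness list with elements `age`, `sex`, `occupation`:
#'   per-field missing probabilities
#' @param concomitant_prob per-report probability of each concomitant
#'   medication from [default_exclusion_list()]
#' @param seed integer random seed
#' @return a validated `synthetic_spec`
#' @export
synthetic_spec <- function(n_reports = 5000,
                           quarters = quarter_seq("2019Q3", "2025Q1"),
                           drugs = default_drug_universe(),
                           pt_background = default_pt_background(),
                           planted_signals = data.frame(
                             drug = character(0), pt = character(0),
                             rate_ratio = numeric(0)),
                           indication_model = 0.8,
                           background_indication = 0.1,
                           target_drugs = c("ABROCITINIB", "UPADACITINIB"),
                           duplication_rate = 0.2,
                           tie_rate = 0.2,
                           missingness = list(age = 0.15, sex = 0.06,
                                              occupation = 0.10),
                           concomitant_prob = 0.03,
                           seed = 1L) {
  quarters <- as.character(unlist(quarters))
  probs <- c(indication_model, background_indication, duplication_rate,
             tie_rate, unlist(missingness), concomitant_prob)
  stopifnot(n_reports >= 1, all(probs >= 0 & probs <= 1),
            all(grepl("^[0-9]{4}Q[1-4]$", quarters)),
            all(c("name", "prevalence") %in% names(drugs)),
            all(drugs$prevalence > 0),
            all(c("pt", "soc", "prob") %in% names(pt_background)),
            all(pt_background$prob > 0),
            all(c("drug", "pt", "rate_ratio") %in% names(planted_signals)),
            all(planted_signals$rate_ratio > 0))
  drugs$name <- norm_term(drugs$name)
  drugs$prevalence <- drugs$prevalence / sum(drugs$prevalence)
  pt_background$pt <- norm_term(pt_background$pt)
  pt_background$prob <- pt_background$prob / sum(pt_background$prob)
  planted_signals$drug <- norm_term(planted_signals$drug)
  planted_signals$pt <- norm_term(planted_signals$pt)
  bad_drug <- !planted_signals$drug %in% drugs$name
  bad_pt <- !planted_signals$pt %in% pt_background$pt
  if (any(bad_drug | bad_pt)) {
    stop("planted signal refers to unknown drug/PT: ",
         paste(planted_signals$drug[bad_drug | bad_pt],
               planted_signals$pt[bad_drug | bad_pt], collapse = ", "))
  }
  p0 <- pt_background$prob[match(planted_signals$pt, pt_background$pt)]
  infeasible <- planted_signals$rate_ratio * p0 > 1
  if (any(infeasible)) {
    stop("planted rate ratio pushes a probability above 1 for: ",
         paste(planted_signals$drug[infeasible], planted_signals$pt[infeasible],
               sep = "/", collapse = ", "))
  }
  structure(list(n_reports = as.integer(n_reports), quarters = quarters,
                 drugs = drugs, pt_background = pt_background,
                 planted_signals = planted_signals,
                 indication_model = indication_model,
                 background_indication = background_indication,
                 target_drugs = norm_term(target_drugs),
                 duplication_rate = duplication_rate, tie_rate = tie_rate,
                 missingness = missingness,
                 concomitant_prob = concomitant_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-drug tilted PT sampling distribution (planted ratios applied,
# renormalized); matrix [n_pt x n_drug]
tilted_pt_probs <- function(spec) {
  p <- spec$pt_background$prob
  m <- matrix(p, nrow = length(p), ncol = nrow(spec$drugs))
  colnames(m) <- spec$drugs$name
  ps <- spec$planted_signals
  if (nrow(ps) > 0) {
    for (i in seq_len(nrow(ps))) {
      j <- match(ps$pt[i], spec$pt_background$pt)
      d <- match(ps$drug[i], spec$drugs$name)
      m[j, d] <- m[j, d] * ps$rate_ratio[i]
    }
  }
  sweep(m, 2, colSums(m), "/")
}

#' Generate a synthetic FAERS-like dataset with ground truth
#'
#' Samples `n_reports` independent reports: a primary-suspect drug from the
#' prevalence table; 1 to 5 reaction draws (with replacement, then
#' de-duplicated within report) from the drug's tilted PT distribution;
#' demographics, outcomes, an indication linked to the suspect drug, and
#' concomitant medications. A `duplication_rate` fraction of caseids is
#' then emitted as two versions with non-decreasing FDA_DT (ties at
#' `tie_rate` exercising the PRIMARYID rule), so the deduplication contract
#' has a unique designated winner per caseid. Reports are split into
#' quarterly files by FDA_DT.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `quarters` (list of `faers_quarter`) and `truth`
#'   (a `ground_truth`: `reports` per-report attribute frame, `pairs`
#'   realized report-PT pairs, `pair_counts` realized per-(drug, PT)
#'   counts, `winners` caseid-to-primaryid designated winners,
#'   `unique_report_count`)
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_reports
  drugs <- spec$drugs
  ptb <- spec$pt_background
  npt <- nrow(ptb)

  caseid <- as.character(1000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")          # winner = version 2
  drug_idx <- sample.int(nrow(drugs), n, replace = TRUE,
                         prob = drugs$prevalence)
  drug_name <- drugs$name[drug_idx]

  # reaction draws: k iid draws per report from the drug-tilted PT
  # distribution, de-duplicated within report
  k <- sample.int(5L, n, replace = TRUE)
  probs <- tilted_pt_probs(spec)
  rid <- rep.int(seq_len(n), k)
  pt_idx <- integer(length(rid))
  draw_drug <- rep.int(drug_idx, k)
  for (d in unique(drug_idx)) {
    sel <- draw_drug == d
    pt_idx[sel] <- sample.int(npt, sum(sel), replace = TRUE,
                              prob = probs[, d])
  }
  keep <- !duplicated((rid - 1) * npt + pt_idx)
  pairs <- data.frame(report = rid[keep], pt_idx = pt_idx[keep])

  # demographics
  miss <- spec$missingness
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.52, 0.48))
  sex[stats::runif(n) < miss$sex] <- ""
  age_years <- ifelse(stats::runif(n) < 0.10,
                      stats::runif(n, 2, 17.5),
                      ifelse(stats::runif(n) < 0.80,
                             stats::runif(n, 18, 65),
                             stats::runif(n, 66, 90)))
  unit_pick <- sample(c("YR", "DEC", "MON", "DY"), n, replace = TRUE,
                      prob = c(0.90, 0.04, 0.03, 0.03))
  age_val <- round(ifelse(unit_pick == "YR", age_years,
                          ifelse(unit_pick == "DEC", age_years / 10,
                                 ifelse(unit_pick == "MON", age_years * 12,
                                        age_years * 365.25))), 1)
  age_missing <- stats::runif(n) < miss$age
  age_chr <- ifelse(age_missing, "", as.character(age_val))
  unit_chr <- ifelse(age_missing, "", unit_pick)
  occ <- sample(c("MD", "PH", "HP", "CN", "LW", "OT"), n, replace = TRUE,
                prob = c(0.18, 0.08, 0.10, 0.50, 0.02, 0.12))
  occ[stats::runif(n) < miss$occupation] <- ""
  country <- sample(c("US", "CA", "JP", "GB", "DE"), n, replace = TRUE,
                    prob = c(0.60, 0.15, 0.08, 0.10, 0.07))

  # FDA receipt date: uniform quarter, then a day within it
  q_lab <- sample(spec$quarters, n, replace = TRUE)
  qy <- as.integer(substr(q_lab, 1, 4))
  qq <- as.integer(substr(q_lab, 6, 6))
  month <- (qq - 1) * 3 + sample.int(3L, n, replace = TRUE)
  day <- sample.int(28L, n, replace = TRUE)
  fda_date <- as.Date(sprintf("%04d-%02d-%02d", qy, month, day))
  fda_dt <- format(fda_date, "%Y%m%d")

  # outcomes: independent code draws; priority collapse happens downstream
  outc_list <- list(DE = 0.02, LT = 0.02, DS = 0.01, HO = 0.30, OT = 0.35)
  outc_rows <- do.call(rbind, lapply(names(outc_list), function(code) {
    hit <- stats::runif(n) < outc_list[[code]]
    data.frame(report = which(hit), outc_cod = code,
               stringsAsFactors = FALSE)
  }))

  # indication linked to the suspect drug (drug_seq 1)
  is_target <- drug_name %in% spec$target_drugs
  ind_p <- ifelse(is_target, spec$indication_model,
                  spec$background_indication)
  has_ad <- stats::runif(n) < ind_p
  other_ind <- sample(c("RHEUMATOID ARTHRITIS", "PAIN", "PSORIASIS",
                        "HYPERCHOLESTEROLAEMIA"), n, replace = TRUE)
  indi_pt <- ifelse(has_ad, "Dermatitis atopic", other_ind)

  # concomitant medications (role C, drug_seq 2+)
  con_drugs <- default_exclusion_list()
  con_rows <- do.call(rbind, lapply(seq_along(con_drugs), function(i) {
    hit <- stats::runif(n) < spec$concomitant_prob
    data.frame(report = which(hit), drugname = con_drugs[i],
               stringsAsFactors = FALSE)
  }))
  con_rows <- con_rows[order(con_rows$report), , drop = FALSE]
  con_seq <- stats::ave(con_rows$report, con_rows$report,
                        FUN = seq_along) + 1L

  # duplication: chosen caseids also get an earlier version 1
  n_dup <- round(spec$duplication_rate * n)
  dup_sel <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  tie <- stats::runif(n_dup) < spec$tie_rate
  back <- ifelse(tie, 0L, sample.int(90L, n_dup, replace = TRUE))
  dup_date <- fda_date[dup_sel] - back
  first_start <- as.Date(sprintf("%04d-%02d-01",
                                 as.integer(substr(spec$quarters[1], 1, 4)),
                                 (as.integer(substr(spec$quarters[1], 6, 6)) - 1) * 3 + 1))
  dup_date[dup_date < first_start] <- first_start
  dup_fda_dt <- format(dup_date, "%Y%m%d")
  # version 1: always lower pid (paste0 guard: recycling on length 0)
  dup_pid <- if (n_dup > 0) paste0(caseid[dup_sel], "1") else character(0)

  demo <- data.frame(
    primaryid = c(primaryid, dup_pid),
    caseid = c(caseid, caseid[dup_sel]),
    fda_dt = c(fda_dt, dup_fda_dt),
    age = c(age_chr, age_chr[dup_sel]),
    age_cod = c(unit_chr, unit_chr[dup_sel]),
    sex = c(sex, sex[dup_sel]),
    occp_cod = c(occ, occ[dup_sel]),
    reporter_country = c(country, country[dup_sel]),
    stringsAsFactors = FALSE)

  rep_pid <- function(report_idx) primaryid[report_idx]
  drug_tab <- rbind(
    data.frame(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
               drugname = drug_name, prod_ai = drug_name,
               stringsAsFactors = FALSE),
    data.frame(primaryid = rep_pid(con_rows$report),
               drug_seq = as.character(con_seq), role_cod = "C",
               drugname = con_rows$drugname, prod_ai = con_rows$drugname,
               stringsAsFactors = FALSE))
  reac_tab <- data.frame(primaryid = rep_pid(pairs$report),
                         pt = ptb$pt[pairs$pt_idx], stringsAsFactors = FALSE)
  outc_tab <- data.frame(primaryid = rep_pid(outc_rows$report),
                         outc_cod = outc_rows$outc_cod,
                         stringsAsFactors = FALSE)
  rpsr_tab <- data.frame(primaryid = primaryid,
                         rpsr_cod = ifelse(occ %in% c("MD", "PH", "HP"),
                                           "HP", "CSM"),
                         stringsAsFactors = FALSE)
  ther_tab <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                         stringsAsFactors = FALSE)
  indi_tab <- data.frame(primaryid = primaryid, indi_drug_seq = "1",
                         indi_pt = indi_pt, stringsAsFactors = FALSE)

  # duplicate versions carry copies of their winner's child rows
  child_dup <- function(tab) {
    sel_pid <- primaryid[dup_sel]
    extra <- tab[tab$primaryid %in% sel_pid, , drop = FALSE]
    extra$primaryid <- dup_pid[match(extra$primaryid, sel_pid)]
    rbind(tab, extra)
  }
  drug_tab <- child_dup(drug_tab)
  reac_tab <- child_dup(reac_tab)
  outc_tab <- child_dup(outc_tab)
  rpsr_tab <- child_dup(rpsr_tab)
  ther_tab <- child_dup(ther_tab)
  indi_tab <- child_dup(indi_tab)

  # split into quarter objects by FDA_DT
  all_tabs <- list(demo = demo, drug = drug_tab, reac = reac_tab,
                   outc = outc_tab, rpsr = rpsr_tab, ther = ther_tab,
                   indi = indi_tab)
  pid_quarter <- setNames(c(q_lab, quarter_of(dup_fda_dt)),
                          c(primaryid, dup_pid))
  pid_quarter[pid_quarter < spec$quarters[1]] <- spec$quarters[1]
  quarters_out <- lapply(sort(unique(pid_quarter)), function(ql) {
    ids <- names(pid_quarter)[pid_quarter == ql]
    tabs <- lapply(all_tabs, function(tab) {
      out <- tab[tab$primaryid %in% ids, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    for (comp in setdiff(names(tabs), "demo")) {
      attr(tabs[[comp]], "orphan") <- rep(FALSE, nrow(tabs[[comp]]))
    }
    structure(list(quarter = ql, tables = tabs,
                   rejected = setNames(integer(length(tabs)), names(tabs)),
                   input = vapply(tabs, nrow, integer(1))),
              class = "faers_quarter")
  })

  pair_counts <- stats::aggregate(
    list(count = rep(1L, nrow(pairs))),
    by = list(drug = drug_name[pairs$report], pt = ptb$pt[pairs$pt_idx]),
    FUN = sum)
  pair_counts <- pair_counts[order(pair_counts$drug, pair_counts$pt), ,
                             drop = FALSE]
  rownames(pair_counts) <- NULL

  infection_pt <- ptb$pt[ptb$soc == "Infections and infestations"]
  has_inf <- tapply(ptb$pt[pairs$pt_idx] %in% infection_pt, pairs$report,
                    any)
  has_inf_v <- rep(FALSE, n)
  has_inf_v[as.integer(names(has_inf))] <- as.logical(has_inf)

  truth <- structure(list(
    unique_report_count = n,
    winners = data.frame(caseid = caseid, primaryid = primaryid,
                         stringsAsFactors = FALSE),
    reports = data.frame(
      primaryid = primaryid, caseid = caseid, drug = drug_name,
      fda_dt = fda_dt, sex = sex, age_years = ifelse(age_missing, NA,
                                                     age_years),
      occp_cod = occ, country = country, ad_indication = has_ad,
      has_infection_pt = has_inf_v, stringsAsFactors = FALSE),
    pairs = data.frame(primaryid = rep_pid(pairs$report),
                       drug = drug_name[pairs$report],
                       pt = ptb$pt[pairs$pt_idx],
                       soc = ptb$soc[pairs$pt_idx],
                       stringsAsFactors = FALSE),
    pair_counts = pair_counts),
    class = "ground_truth")

  list(quarters = quarters_out, truth = truth)
}

quarter_of <- function(yyyymmdd) {
  y <- substr(yyyymmdd, 1, 4)
  m <- as.integer(substr(yyyymmdd, 5, 6))
  paste0(y, "Q", (m - 1) %/% 3 + 1)
}

#' Closed-form expected contingency table under the generator model
#'
#' For a (drug, PT) pair, the expected cells of the drug-vs-rest 2x2 table
#' under the sampling model of [generate()] (no duplication, cohort
#' filters not applied): a report of drug g mentions PT j with probability
#' `mean_k(1 - (1 - p'_gj)^k)`, k uniform on 1..5, where `p'` is the
#' drug-tilted per-draw distribution.
#'
#' @param spec a [synthetic_spec()]
#' @param drug drug name in the spec's universe
#' @param pt preferred term in the spec's background
#' @return one-row data.frame `a`, `b`, `c`, `d` of expected counts
#' @export
expected_table <- function(spec, drug, pt) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drug <- norm_term(drug)
  pt <- norm_term(pt)
  d <- match(drug, spec$drugs$name)
  j <- match(pt, spec$pt_background$pt)
  if (is.na(d) || is.na(j)) {
    stop("unknown drug/PT pair: ", drug, " / ", pt)
  }
  probs <- tilted_pt_probs(spec)
  incl <- function(p) mean(1 - (1 - p)^(1:5))   # P(PT in report | k draws)
  q <- apply(probs, 2, function(col) vapply(col, incl, numeric(1)))
  n_eff <- spec$n_reports * spec$drugs$prevalence
  a <- n_eff[d] * q[j, d]
  b <- n_eff[d] * sum(q[, d]) - a
  cc <- sum(n_eff[-d] * q[j, -d])
  dd <- sum(n_eff[-d] * colSums(q[, -d, drop = FALSE])) - cc
  data.frame(a = a, b = b, c = cc, d = dd)
}
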