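# Shared fixture builders: everything is constructed in code at test time.

# minimal PT -> SOC map used by hand-built cases
mini_map <- function() {
  soc_map(
    pt = c("Herpes zoster", "Eczema herpeticum", "Sepsis", "Cellulitis",
           "Pneumonia", "Pyrexia", "Pruritus", "Headache"),
    soc = c(rep("Infections and infestations", 5),
            "General disorders and administration site conditions",
            "Skin and subcutaneous tissue disorders",
            "Nervous system disorders"))
}

packaged_soc_map <- function() {
  read_soc_map(system.file("extdata", "soc_minimap_synthetic.csv",
                           package = "faersignal"))
}

reference_signals <- function(drug = NULL) {
  df <- utils::read.csv(
    system.file("extdata", "jak1_infection_reference_signals.csv",
                package = "faersignal"),
    stringsAsFactors = FALSE)
  if (!is.null(drug)) df <- df[df$drug == drug, , drop = FALSE]
  df
}

# hand-built one-quarter dataset as raw "$"-delimited files; returns the
# file paths. Lines are passed verbatim so tests control every byte.
write_faers_files <- function(dir, demo, drug, reac, outc = NULL,
                              indi = NULL, label = "2024Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(
    demo = "primaryid$caseid$fda_dt$age$age_cod$sex$occp_cod$reporter_country",
    drug = "primaryid$drug_seq$role_cod$drugname$prod_ai",
    reac = "primaryid$pt",
    outc = "primaryid$outc_cod",
    rpsr = "primaryid$rpsr_cod",
    ther = "primaryid$dsg_drug_seq",
    indi = "primaryid$indi_drug_seq$indi_pt")
  # mandatory components get a benign row when the test does not care,
  # so empty-file warnings stay meaningful where they are asserted
  is_header <- function(line) {
    tolower(strsplit(line, "$", fixed = TRUE)[[1]][1]) == "primaryid"
  }
  first_row <- demo[if (is_header(demo[1])) 2 else 1]
  first_pid <- strsplit(first_row, "$", fixed = TRUE)[[1]][1]
  tables <- list(demo = demo, drug = drug, reac = reac,
                 outc = outc %||% paste0(first_pid, "$OT"),
                 indi = indi %||% paste0(first_pid, "$1$Unknown"))
  paths <- character(0)
  for (comp in names(tables)) {
    body <- tables[[comp]]
    has_header <- length(body) > 0 && is_header(body[1])
    lines <- if (has_header) body else c(defaults[[comp]], body)
    path <- file.path(dir, paste0(comp, ".txt"))
    writeLines(lines, path)
    paths[comp] <- path
  }
  paths
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a small fully-selected cohort: 3 reports on the target drug with the AD
# indication and one infection PT each, plus 2 comparator reports
demo_store <- function(dir) {
  paths <- write_faers_files(
    dir,
    demo = c("11$1001$20240115$45$YR$F$MD$US",
             "12$1002$20240210$30$YR$M$CN$US",
             "13$1003$20240301$70$YR$F$CN$CA",
             "21$2001$20240120$50$YR$M$MD$US",
             "22$2002$20240215$60$YR$F$OT$US"),
    drug = c("11$1$PS$ABROCITINIB$ABROCITINIB",
             "12$1$PS$CIBINQO$ABROCITINIB",
             "13$1$PS$ABROCITINIB$ABROCITINIB",
             "13$2$C$DUPILUMAB$DUPILUMAB",
             "21$1$PS$IBUPROFEN$IBUPROFEN",
             "22$1$PS$METHOTREXATE$METHOTREXATE"),
    reac = c("11$Herpes zoster", "11$Pyrexia", "12$Sepsis",
             "13$Herpes zoster", "21$Herpes zoster", "21$Headache",
             "22$Pruritus"),
    outc = c("11$HO", "12$DE", "12$HO"),
    indi = c("11$1$Dermatitis atopic", "12$1$Dermatitis atopic",
             "13$1$Dermatitis atopic", "21$1$Pain",
             "22$1$Rheumatoid arthritis"))
  deduplicate(list(read_quarter(paths, "2024Q1")))
}

abro_spec <- function() cohort_spec(c("ABROCITINIB", "CIBINQO"))

# small synthetic run shared by several tests (planted strong signal)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      planted <- data.frame(drug = "ABROCITINIB",
                            pt = c("ECZEMA HERPETICUM", "HERPES ZOSTER"),
                            rate_ratio = c(20, 6))
      spec <- synthetic_spec(n_reports = 8000,
                             quarters = quarter_seq("2023Q1", "2024Q4"),
                             planted_signals = planted,
                             indication_model = 1, seed = 77)
      cache <<- list(spec = spec, sim = generate(spec))
    }
    cache
  }
})
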