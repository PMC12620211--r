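#' FAERS quarterly component schema
#'
#' The seven core FAERS components and the columns the reader requires in
#' each: DEMO (demographics), DRUG (drug records and roles), REAC (adverse
#' event preferred terms), OUTC (outcomes), RPSR (report sources), THER
#' (therapy dates) and INDI (indications).
#'
#' @format Named list of character vectors (mandatory lowercase columns).
#' @export
faers_components <- list(
  demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
           "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  rpsr = c("primaryid", "rpsr_cod"),
  ther = c("primaryid", "dsg_drug_seq"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

# Historical FAERS column renames accepted out of the box; user-supplied
# aliases are merged over these (names = legacy column, value = canonical).
default_column_aliases <- c(gndr_cod = "sex")

read_faers_lines <- function(path) {
  # Real FAERS extracts contain stray non-UTF-8 (Latin-1) bytes; read raw
  # and convert with replacement so one bad byte never kills a quarter.
  con <- file(path, open = "rb")
  on.exit(close(con))
  raw <- readLines(con, warn = FALSE)
  iconv(raw, from = "latin1", to = "UTF-8", sub = "?")
}

parse_component <- function(path, component, aliases) {
  mandatory <- faers_components[[component]]
  lines <- read_faers_lines(path)
  if (length(lines) == 0L) {
    stop("FAERS file has no header line: ", path)
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  hit <- match(header, names(aliases))
  header[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols) > 0L) {
    stop("FAERS ", toupper(component), " file ", path,
         " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    warning("FAERS ", toupper(component), " file is empty after header: ", path)
    return(list(table = empty_df(mandatory), rejected = 0L, input = 0L))
  }
  fields <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty field is dropped by strsplit; tolerate one short
  ok_len <- nf == length(header) | nf == length(header) - 1L
  mat <- matrix("", nrow = sum(ok_len), ncol = length(header))
  if (any(ok_len)) {
    flat <- fields[ok_len]
    for (j in seq_along(header)) {
      mat[, j] <- vapply(flat, function(f) if (length(f) >= j) f[[j]] else "",
                         character(1))
    }
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df <- df[, mandatory, drop = FALSE]
  keep <- validate_component(df, component)
  list(table = df[keep, , drop = FALSE],
       rejected = sum(!ok_len) + sum(!keep),
       input = length(body))
}

# row-level validity of mandatory fields; invalid rows are dropped upstream
validate_component <- function(df, component) {
  ok <- nzchar(trimws(df$primaryid))
  switch(component,
    demo = ok & nzchar(trimws(df$caseid)) & valid_yyyymmdd(df$fda_dt),
    drug = {
      seq_ok <- suppressWarnings(as.integer(df$drug_seq))
      ok & !is.na(seq_ok) & seq_ok >= 1L &
        norm_term(df$role_cod) %in% c("PS", "SS", "C", "I")
    },
    reac = ok & nzchar(norm_term(df$pt)),
    outc = ok & nzchar(trimws(df$outc_cod)),
    indi = {
      seq_ok <- suppressWarnings(as.integer(df$indi_drug_seq))
      ok & !is.na(seq_ok) & seq_ok >= 1L
    },
    ok)
}

#' Read one FAERS-style quarter
#'
#' Parses the "$"-delimited ASCII files of a quarterly FAERS extract into a
#' typed quarter object. Column names are matched case-insensitively and
#' legacy names can be mapped through `aliases`. Records whose mandatory
#' fields do not parse (bad field count, missing primaryid, invalid FDA_DT,
#' unknown drug role, blank PT, ...) are dropped and counted in the
#' per-component rejection log. Child records whose PRIMARYID has no DEMO
#' parent in the same quarter are retained but flagged orphan; downstream
#' stages exclude them from all counting.
#'
#' @param paths named character vector of file paths; names must cover the
#'   components in [faers_components] (case-insensitive). RPSR and THER may
#'   be omitted.
#' @param quarter_label quarter identifier matching `YYYYQ[1-4]`, e.g.
#'   `"2019Q3"`.
#' @param aliases named character vector mapping legacy column names to
#'   canonical ones, merged over the built-in defaults.
#' @return An object of class `faers_quarter`: a list with `quarter`,
#'   `tables` (one data.frame per component, orphan flag as the `orphan`
#'   attribute on child tables), `rejected` and `input` per-component counts.
#' @export
read_quarter <- function(paths, quarter_label, aliases = NULL) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", quarter_label))
  names(paths) <- tolower(names(paths))
  required <- setdiff(names(faers_components), c("rpsr", "ther"))
  miss <- setdiff(required, names(paths))
  if (length(miss) > 0L) {
    stop("No path given for component(s): ", paste(toupper(miss), collapse = ", "))
  }
  gone <- !file.exists(paths)
  if (any(gone)) {
    stop("FAERS file does not exist: ", paste(paths[gone], collapse = ", "))
  }
  alias_map <- default_column_aliases
  if (!is.null(aliases)) alias_map[names(aliases)] <- aliases

  tables <- list()
  rejected <- integer(0)
  input <- integer(0)
  for (comp in names(faers_components)) {
    if (!comp %in% names(paths)) {
      tables[[comp]] <- empty_df(faers_components[[comp]])
      rejected[comp] <- 0L
      input[comp] <- 0L
      next
    }
    parsed <- parse_component(paths[[comp]], comp, alias_map)
    tables[[comp]] <- parsed$table
    rejected[comp] <- parsed$rejected
    input[comp] <- parsed$input
  }
  demo_ids <- tables$demo$primaryid
  for (comp in setdiff(names(tables), "demo")) {
    attr(tables[[comp]], "orphan") <- !(tables[[comp]]$primaryid %in% demo_ids)
  }
  structure(list(quarter = quarter_label, tables = tables,
                 rejected = rejected, input = input),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>", x$quarter, "\n")
  for (comp in names(x$tables)) {
    cat(sprintf("  %-4s %6d records (%d rejected)\n", toupper(comp),
                nrow(x$tables[[comp]]), x$rejected[[comp]]))
  }
  invisible(x)
}

#' Write one quarter back to FAERS-style ASCII files
#'
#' Emits one "$"-delimited file per component, one header line, no quoting
#' (the FAERS dialect has none). A literal "$" inside a field would corrupt
#' the record, so it is replaced by `dollar_sub` with a warning.
#'
#' @param quarter a `faers_quarter` object
#' @param directory output directory (created if needed)
#' @param dollar_sub single character substituted for embedded "$"
#' @return named character vector of written file paths
#' @export
write_quarter <- function(quarter, directory, dollar_sub = "/") {
  stopifnot(inherits(quarter, "faers_quarter"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("Cannot create output directory: ", directory)
  }
  paths <- character(0)
  for (comp in names(quarter$tables)) {
    df <- quarter$tables[[comp]]
    path <- file.path(directory,
                      paste0(toupper(comp), "_", quarter$quarter, ".txt"))
    cells <- as.matrix(df)
    bad <- grepl("$", cells, fixed = TRUE)
    if (any(bad)) {
      warning(sum(bad), " field(s) in ", toupper(comp),
              " contained the '$' delimiter; replaced by '", dollar_sub, "'")
      cells[bad] <- gsub("$", dollar_sub, cells[bad], fixed = TRUE)
    }
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df) > 0) apply(cells, 1L, paste, collapse = "$"))
    writeLines(lines, path, useBytes = FALSE)
    paths[comp] <- path
  }
  paths
}

#' Write a signal table to CSV
#'
#' One row per preferred term with the full-precision statistics plus
#' display columns in the conventional published layout: `ror_ci`
#' ("6.4 (4.3-9.53)"), `prr_chi2` ("6.36 (110.97)"), `ebgm_ebgm05`
#' ("6.06 (4.34)") and `ic_ic025` ("2.6 (2.03)"), numbers rounded to at
#' most two decimals with trailing zeros dropped.
#'
#' @param results a `signal_stats` data.frame (see [run_signal_scan()]);
#'   may be empty.
#' @param path output CSV path
#' @return `path`, invisibly
#' @seealso [read_signal_table()] for the lossless inverse on the
#'   full-precision columns.
#' @export
write_signal_table <- function(results, path) {
  num_cols <- c("n", "a", "b", "c", "d", "ror", "ror_lo", "ror_hi", "prr",
                "chi2", "ic", "ic_sd", "ic025", "ebgm", "ebgm05")
  flag_cols <- c("ror_pos", "prr_pos", "bcpnn_pos", "mgps_pos", "positive",
                 "corrected")
  if (nrow(results) == 0L) {
    out <- as.data.frame(setNames(
      rep(list(character(0)), 2 + length(num_cols) + length(flag_cols) + 4),
      c("pt", num_cols, "ror_ci", "prr_chi2", "ebgm_ebgm05", "ic_ic025",
        flag_cols)))
  } else {
    out <- results[, c("pt", num_cols, flag_cols)]
    out$ror_ci <- sprintf("%s (%s-%s)", fmt_est(results$ror),
                          fmt_est(results$ror_lo), fmt_est(results$ror_hi))
    out$prr_chi2 <- sprintf("%s (%s)", fmt_est(results$prr),
                            fmt_est(results$chi2))
    out$ebgm_ebgm05 <- sprintf("%s (%s)", fmt_est(results$ebgm),
                               fmt_est(results$ebgm05))
    out$ic_ic025 <- sprintf("%s (%s)", fmt_est(results$ic),
                            fmt_est(results$ic025))
    out <- out[, c("pt", num_cols, "ror_ci", "prr_chi2", "ebgm_ebgm05",
                   "ic_ic025", flag_cols)]
  }
  utils::write.csv(format_full_precision(out, num_cols), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_full_precision <- function(df, num_cols) {
  for (col in intersect(num_cols, names(df))) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  df
}

#' Read a signal table written by [write_signal_table()]
#'
#' @param path CSV path
#' @return data.frame with full-precision numeric columns restored
#' @export
read_signal_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  num_cols <- c("n", "a", "b", "c", "d", "ror", "ror_lo", "ror_hi", "prr",
                "chi2", "ic", "ic_sd", "ic025", "ebgm", "ebgm05")
  for (col in intersect(num_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(c("ror_pos", "prr_pos", "bcpnn_pos", "mgps_pos",
                          "positive", "corrected"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}
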