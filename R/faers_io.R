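#' The report-set container
#'
#' Deduplicated safety reports are kept in the normalized three-table form
#' that mirrors the source files: one row per report (`reports`: primaryid,
#' caseid, sex, age_years), one row per drug mention (`drugs`: primaryid,
#' drug, route, role), one row per event mention (`events`: primaryid, pt).
#' Mention tables refer only to report ids present in `reports`, and within
#' a report duplicate (drug, route) and duplicate PT rows are collapsed.
#'
#' @param reports,drugs,events data.frames with the columns above.
#' @return an object of class `report_set`.
#' @export
as_report_set <- function(reports, drugs, events) {
  reports <- as.data.table(reports)
  drugs <- as.data.table(drugs)
  events <- as.data.table(events)
  stopifnot(all(c("primaryid", "caseid", "sex", "age_years") %in% names(reports)),
            all(c("primaryid", "drug", "route") %in% names(drugs)),
            all(c("primaryid", "pt") %in% names(events)))
  if (!"role" %in% names(drugs)) drugs[, role := NA_character_]
  if (anyDuplicated(reports$primaryid)) stop("duplicate report primaryid")
  bad <- !reports$sex %in% c("male", "female", "unknown")
  if (any(bad)) stop("sex must be male/female/unknown")
  if (any(reports$age_years < 0, na.rm = TRUE)) stop("age_years must be >= 0 or NA")
  structure(list(reports = reports, drugs = drugs, events = events),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("report_set: %d reports, %d drug mentions (%d drugs), %d event mentions (%d PTs)\n",
              nrow(x$reports), nrow(x$drugs), uniqueN(x$drugs$drug),
              nrow(x$events), uniqueN(x$events$pt)))
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `report_set`.
#' @export
n_reports <- function(x) nrow(x$reports)

#' Read FAERS-style DEMO/DRUG/REAC ASCII tables
#'
#' Parses the quarterly-file dialect: `$`-delimited text with a header row.
#' Required columns (case-insensitive): DEMO needs primaryid, caseid, sex (or
#' gndr_cod), age, age_cod; DRUG needs primaryid, drugname, route; REAC needs
#' primaryid, pt. Rows with a missing/blank primaryid are skipped and counted
#' in the parse report attached as attribute `"parse_report"`.
#'
#' @param demo,drug,reac file paths.
#' @param sep field delimiter (default "$").
#' @return a list of class `raw_table_set` with data.tables `demo`, `drug`,
#'   `reac` and attribute `parse_report` (skipped-row counts per table).
#' @export
read_faers_tables <- function(demo, drug, reac, sep = "$") {
  read_one <- function(path, required, what) {
    if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
    dt <- fread(path, sep = sep, colClasses = "character", header = TRUE,
                quote = "", fill = TRUE, blank.lines.skip = TRUE)
    setnames(dt, tolower(names(dt)))
    miss <- setdiff(required, names(dt))
    if (length(miss)) {
      stop(sprintf("%s table %s is missing required column(s): %s",
                   what, path, paste(miss, collapse = ", ")))
    }
    n0 <- nrow(dt)
    dt <- dt[!is.na(primaryid) & primaryid != ""]
    list(table = dt, skipped = n0 - nrow(dt))
  }
  d <- read_one(demo, c("primaryid", "caseid"), "DEMO")
  if (!"sex" %in% names(d$table) && "gndr_cod" %in% names(d$table)) {
    setnames(d$table, "gndr_cod", "sex")
  }
  for (col in c("sex", "age", "age_cod")) {
    if (!col %in% names(d$table)) d$table[, (col) := NA_character_]
  }
  g <- read_one(drug, c("primaryid", "drugname"), "DRUG")
  if (!"route" %in% names(g$table)) g$table[, route := NA_character_]
  if (!"role_cod" %in% names(g$table)) g$table[, role_cod := NA_character_]
  r <- read_one(reac, c("primaryid", "pt"), "REAC")
  structure(list(demo = d$table, drug = g$table, reac = r$table),
            class = "raw_table_set",
            parse_report = c(demo_skipped = d$skipped, drug_skipped = g$skipped,
                             reac_skipped = r$skipped))
}

#' Convert a FAERS age value and unit code to years
#'
#' Unit codes follow the quarterly files: YR (years), MON (months), WK
#' (weeks), DY (days), HR (hours), DEC (decades). A missing unit is assumed
#' to be years (with a warning); unparseable or negative values become NA.
#'
#' @param age numeric or character age values.
#' @param unit character unit codes (may be NA).
#' @return numeric age in years (NA where unknown).
#' @export
standardize_age <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(unit)))
  unit[is.na(unit) | unit == ""] <- NA_character_
  if (any(!is.na(age) & is.na(unit))) {
    warning("age with missing unit code: unit assumed YR")
    unit[!is.na(age) & is.na(unit)] <- "YR"
  }
  fac <- c(YR = 1, MON = 1/12, WK = 1/52, DY = 1/365.25, HR = 1/8766, DEC = 10)
  out <- age * fac[unit]
  out[is.na(unit) & !is.na(age)] <- NA_real_  # unknown unit code
  if (any(out < 0, na.rm = TRUE)) {
    warning("negative age treated as missing")
    out[!is.na(out) & out < 0] <- NA_real_
  }
  unname(out)
}

#' Merge DEMO/DRUG/REAC and deduplicate case versions
#'
#' FAERS revises cases by reissuing them under the same caseid with a larger
#' primaryid; only the numerically greatest primaryid per caseid is kept.
#' Drug and event rows are attached by primaryid (orphan mention rows whose
#' primaryid has no demographic row are dropped and counted), and duplicate
#' (drug, route) / duplicate PT mentions within a report are collapsed.
#' Sex codes M/F map to male/female, anything else to unknown.
#'
#' @param tables a `raw_table_set` from [read_faers_tables()].
#' @return a `report_set`; attribute `"dedup_report"` holds counts of removed
#'   case versions and dropped orphan mention rows.
#' @export
merge_and_deduplicate <- function(tables) {
  stopifnot(inherits(tables, "raw_table_set"))
  demo <- copy(tables$demo)
  demo[, pid_num := suppressWarnings(as.numeric(primaryid))]
  keep <- demo[order(-pid_num), .SD[1L], by = caseid]
  n_versions_removed <- nrow(demo) - nrow(keep)
  sex <- toupper(trimws(ifelse(is.na(keep$sex), "", keep$sex)))
  reports <- data.table(
    primaryid = keep$primaryid,
    caseid = keep$caseid,
    sex = fifelse(sex == "M", "male", fifelse(sex == "F", "female", "unknown")),
    age_years = suppressWarnings(standardize_age(keep$age, keep$age_cod))
  )
  ids <- reports$primaryid
  drugs <- unique(tables$drug[primaryid %chin% ids,
                              .(primaryid, drug = trimws(drugname),
                                route = trimws(fifelse(is.na(route), "", route)),
                                role = role_cod)])
  drugs <- unique(drugs, by = c("primaryid", "drug", "route"))
  events <- unique(tables$reac[primaryid %chin% ids,
                               .(primaryid, pt = trimws(pt))])
  orphans <- (nrow(tables$drug) - nrow(tables$drug[primaryid %chin% ids])) +
             (nrow(tables$reac) - nrow(tables$reac[primaryid %chin% ids]))
  out <- as_report_set(reports, drugs, events)
  attr(out, "dedup_report") <- c(case_versions_removed = n_versions_removed,
                                 orphan_mentions_dropped = orphans)
  out
}

#' Restrict the analysis table to orally administered cases
#'
#' A report is retained when at least one of its drug mentions has a route in
#' the oral synonym set (case-insensitive). Retained reports keep all their
#' drug mentions, including non-oral ones. Set `mention_level = TRUE` to
#' instead drop the non-oral drug mentions themselves (and then any report
#' left with no mention).
#'
#' @param x a `report_set`.
#' @param oral_routes accepted route spellings (matched case-insensitively).
#' @param mention_level filter individual mentions instead of whole reports.
#' @export
filter_oral <- function(x, oral_routes = c("ORAL", "PO"), mention_level = FALSE) {
  stopifnot(inherits(x, "report_set"))
  oral <- toupper(oral_routes)
  is_oral <- toupper(x$drugs$route) %in% oral
  if (mention_level) {
    drugs <- x$drugs[is_oral]
    keep <- unique(drugs$primaryid)
  } else {
    keep <- unique(x$drugs$primaryid[is_oral])
    drugs <- x$drugs[primaryid %chin% keep]
  }
  as_report_set(x$reports[primaryid %chin% keep], drugs,
                x$events[primaryid %chin% keep])
}

#' Read a drug-name normalization map
#'
#' Two-column CSV (raw, generic). Matching is case-insensitive after
#' whitespace trimming. Conflicting duplicate raw names are an error.
#'
#' @param path CSV path.
#' @param unmapped_policy what [normalize_drug_names()] does with names absent
#'   from the map: `"keep_verbatim"` keeps them lower-cased, `"drop"` removes
#'   the mention.
#' @return a `name_map` list.
#' @export
read_name_map <- function(path, unmapped_policy = c("keep_verbatim", "drop")) {
  unmapped_policy <- match.arg(unmapped_policy)
  m <- fread(path, colClasses = "character", header = TRUE)
  if (ncol(m) < 2) stop("name map needs two columns: raw, generic")
  setnames(m, 1:2, c("raw", "generic"))
  m[, raw := tolower(trimws(raw))]
  m[, generic := trimws(generic)]
  dup <- m[, uniqueN(generic), by = raw][V1 > 1, raw]
  if (length(dup)) {
    stop(sprintf("conflicting name-map entries for: %s", paste(dup, collapse = ", ")))
  }
  m <- unique(m, by = "raw")
  structure(list(entries = m, unmapped_policy = unmapped_policy),
            class = "name_map")
}

#' Normalize drug names to generic forms
#'
#' Raw names are looked up case-insensitively in the map; mentions of the
#' same generic within one report collapse to a single mention. Unmapped
#' names follow the map's `unmapped_policy`. A normalization log (unmapped
#' names with counts) is attached as attribute `"unmapped"`.
#'
#' @param x a `report_set`.
#' @param map a `name_map` from [read_name_map()].
#' @export
normalize_drug_names <- function(x, map) {
  stopifnot(inherits(x, "report_set"), inherits(map, "name_map"))
  drugs <- copy(x$drugs)
  key <- tolower(trimws(drugs$drug))
  idx <- match(key, map$entries$raw)
  mapped <- map$entries$generic[idx]
  unmapped_tab <- sort(table(key[is.na(idx)]), decreasing = TRUE)
  if (map$unmapped_policy == "drop") {
    drugs <- drugs[!is.na(idx)]
    drugs[, drug := mapped[!is.na(idx)]]
  } else {
    drugs[, drug := fifelse(is.na(mapped), key, mapped)]
  }
  drugs <- unique(drugs, by = c("primaryid", "drug", "route"))
  out <- as_report_set(x$reports, drugs, x$events)
  attr(out, "unmapped") <- unmapped_tab
  out
}

#' Write the analysis table as TSV
#'
#' One row per report: primaryid, sex, age_years, semicolon-joined drugs,
#' semicolon-joined event PTs.
#'
#' @param x a `report_set`.
#' @param path output path.
#' @export
write_table_b <- function(x, path) {
  stopifnot(inherits(x, "report_set"))
  dj <- x$drugs[, .(drugs = paste(sort(unique(drug)), collapse = ";")), by = primaryid]
  ej <- x$events[, .(events = paste(sort(unique(pt)), collapse = ";")), by = primaryid]
  out <- merge(merge(x$reports, dj, by = "primaryid", all.x = TRUE),
               ej, by = "primaryid", all.x = TRUE)
  out[is.na(drugs), drugs := ""]
  out[is.na(events), events := ""]
  fwrite(out[, .(primaryid, sex, age_years, drugs, events)], path, sep = "\t")
  invisible(path)
}
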