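#' The gastrointestinal ulcer PT catalog shipped with the package
#'
#' The 21 MedDRA preferred terms for ulcer of the GI tract that pass the
#' 1000-report screen in the full FAERS database, with their FAERS report
#' counts and an anatomical site classification (see [default_site_map()]).
#' The full licensed 83-term standardized query is not distributed; supply
#' your own term file to `path` to extend the catalog.
#'
#' @param path optional TSV with columns `pt` (and optionally `site`,
#'   `reports_faers`) replacing the shipped catalog.
#' @return a data.table with columns pt, site, reports_faers.
#' @export
pt_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pt_catalog.tsv", package = "gisignal")
  }
  cat_ <- fread(path, sep = "\t", colClasses = list(character = "pt"))
  if (!"pt" %in% names(cat_)) stop("PT catalog needs a 'pt' column")
  if (anyDuplicated(tolower(cat_$pt))) stop("PT names must be unique (case-insensitive)")
  cat_[]
}

#' Default anatomical site map for the shipped PT catalog
#'
#' Upper GI runs from the oral cavity to the duodenum, lower GI from the
#' jejunum to the anus; terms whose wording carries no site are
#' `not_classified`. Assignments for site-free compound terms ("Peptic
#' ulcer", "Intestinal ulcer") follow that anatomical rule and can be
#' overridden via a user TSV.
#'
#' @param path optional TSV (pt, site) overriding the default.
#' @return named character vector: PT -> upper/lower/not_classified.
#' @export
default_site_map <- function(path = NULL) {
  cat_ <- pt_catalog(path)
  if (!"site" %in% names(cat_)) stop("site map source needs a 'site' column")
  bad <- setdiff(unique(cat_$site), c("upper", "lower", "not_classified"))
  if (length(bad)) stop(sprintf("unknown site label(s): %s", paste(bad, collapse = ", ")))
  setNames(cat_$site, cat_$pt)
}

#' Classify a PT by gastrointestinal site
#'
#' @param pt preferred term(s).
#' @param map named vector from [default_site_map()].
#' @return character vector of upper/lower/not_classified.
#' @export
classify_site <- function(pt, map = default_site_map()) {
  miss <- setdiff(pt, names(map))
  if (length(miss)) {
    stop(sprintf("PT(s) missing from site map: %s", paste(miss, collapse = ", ")))
  }
  unname(map[pt])
}

#' Count reports per event PT
#'
#' @param reports a `report_set`.
#' @param pts restrict to this PT set (default: all reported).
#' @return data.table (pt, n) sorted by decreasing count.
#' @export
event_report_counts <- function(reports, pts = NULL) {
  stopifnot(inherits(reports, "report_set"))
  emen <- unique(reports$events[, .(primaryid, pt)])
  if (!is.null(pts)) emen <- emen[pt %chin% pts]
  out <- emen[, .(n = .N), by = pt]
  setorder(out, -n, pt)
  out[]
}

#' Select the analyzed event set
#'
#' Keeps PTs whose report count meets the minimum (inclusive, default 1000),
#' sorted by count descending.
#'
#' @param event_counts data.table (pt, n) from [event_report_counts()], or a
#'   named numeric vector.
#' @param min_reports inclusive threshold.
#' @export
select_events <- function(event_counts, min_reports = 1000) {
  if (!is.data.frame(event_counts)) {
    event_counts <- data.table(pt = names(event_counts), n = as.numeric(event_counts))
  }
  if (nrow(event_counts) == 0) return(character(0))
  ec <- as.data.table(event_counts)[n >= min_reports]
  setorder(ec, -n, pt)
  ec$pt
}

#' Select the analyzed drug set
#'
#' A drug qualifies when its total report count is strictly greater than
#' `min_reports` and its smallest pairwise p-value is below `alpha`.
#'
#' @param signals output of [pairwise_signals()].
#' @param min_reports strict lower bound on per-drug report count (default 1000).
#' @param alpha significance level (default 0.05).
#' @export
select_drugs <- function(signals, min_reports = 1000, alpha = 0.05) {
  s <- as.data.table(signals)
  agg <- s[, .(n = n_reports[1L], p_min = min(p_value)), by = drug]
  sort(agg[n > min_reports & p_min < alpha, drug])
}
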