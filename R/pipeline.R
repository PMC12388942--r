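#' Demographic stratum analysis of ulcer reporting
#'
#' Reproduces the sex and age stratum tables: reports are cross-classified
#' by stratum membership and by whether they carry at least one of the
#' selected ulcer PTs. The age dichotomy is at 70 years; reports with
#' missing age (or unknown sex) form an "unknown" row that is excluded from
#' the 2x2. Each stratum table is computed in both index orientations,
#' because the printed convention in published stratum tables is not always
#' the row-label-first one.
#'
#' @param reports a `report_set`.
#' @param event_pts PT set defining an ulcer case (default: shipped catalog).
#' @param age_cut age dichotomy in years (default 70).
#' @return a data.table with one row per (stratum table, orientation):
#'   columns stratum, index_group, a, b, c, d, ror, ci_low, ci_high,
#'   p_value, plus the unknown-row counts as attribute `"unknown"`.
#' @export
demographic_report <- function(reports, event_pts = pt_catalog()$pt, age_cut = 70) {
  stopifnot(inherits(reports, "report_set"))
  ids <- reports$reports$primaryid
  case <- ids %in% unique(reports$events[pt %chin% event_pts, primaryid])
  sex <- reports$reports$sex
  age <- reports$reports$age_years

  strata <- list(
    sex = list(female = sex == "female", male = sex == "male",
               unknown = sex == "unknown"),
    age = list(under = !is.na(age) & age < age_cut,
               over = !is.na(age) & age >= age_cut,
               unknown = is.na(age))
  )
  pair_rows <- function(g1, name1, g2, name2, stratum) {
    rbindlist(lapply(list(c(name1, name2), c(name2, name1)), function(o) {
      idx <- if (o[1] == name1) g1 else g2
      cmp <- if (o[1] == name1) g2 else g1
      tab <- contingency_table(sum(idx & case), sum(idx & !case),
                               sum(cmp & case), sum(cmp & !case))
      s <- signal_stats(tab)
      data.table(stratum = stratum, index_group = o[1],
                 a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
                 p_value = s$p_value)
    }))
  }
  out <- rbind(
    pair_rows(strata$sex$female, "female", strata$sex$male, "male", "sex"),
    pair_rows(strata$age$under, sprintf("age<%g", age_cut),
              strata$age$over, sprintf("age>=%g", age_cut), "age")
  )
  attr(out, "unknown") <- data.table(
    stratum = c("sex", "age"),
    with_event = c(sum(strata$sex$unknown & case), sum(strata$age$unknown & case)),
    without_event = c(sum(strata$sex$unknown & !case), sum(strata$age$unknown & !case))
  )
  out[]
}

#' Stratum signal from four printed counts
#'
#' Convenience wrapper for reproducing a published stratum row from its four
#' contingency counts: index-group cases, index-group non-cases, comparator
#' cases, comparator non-cases. The ROR and Woolf interval are computed on
#' the raw counts (at these magnitudes the Haldane increment is
#' inconsequential); the Fisher p uses the exact log-space path.
#'
#' @param a,b,c,d the four counts, index group first.
#' @param correct apply the Haldane correction first (default FALSE).
#' @return a `signal_result`.
#' @export
stratum_signal <- function(a, b, c, d, correct = FALSE) {
  signal_stats(contingency_table(a, b, c, d), correct = correct)
}

#' Run the full signal-detection pipeline
#'
#' Executes the published analysis flow end to end on a directory of
#' FAERS-style files (or an in-memory `report_set`): merge + deduplicate,
#' optional oral-route restriction, optional drug-name normalization, event
#' and drug selection, pairwise signal statistics, volcano table,
#' demographic strata, lnROR matrix, correlation PCA, PC-vs-site t-test,
#' Ward clustering with elbow-selected k. Stage tables are written as TSV
#' under `out_dir` together with a JSON manifest of row counts per stage.
#'
#' @param input a `report_set`, or a named list/vector with paths `demo`,
#'   `drug`, `reac`.
#' @param out_dir output directory (created); NULL to skip writing.
#' @param name_map optional `name_map` for drug normalization.
#' @param pt_set PT catalog data.table (default shipped); its `site` column
#'   is the site map.
#' @param oral_only restrict to orally administered cases (default TRUE).
#' @param min_event_reports,min_drug_reports,alpha selection thresholds
#'   (defaults 1000 inclusive, 1000 strict, 0.05).
#' @param n_retain retained PCA components (default 3).
#' @param site_test_component which retained component is tested against
#'   injury site (default 3).
#' @param k_max largest cluster count considered by the elbow rule.
#' @return invisible list: `table_b`, `signals`, `volcano`, `demographics`,
#'   `events`, `drugs`, `lnror`, `pca`, `site_test`, `hclust`, `k`,
#'   `clusters`, `manifest`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         name_map = NULL,
                         pt_set = pt_catalog(),
                         oral_only = TRUE,
                         min_event_reports = 1000,
                         min_drug_reports = 1000,
                         alpha = 0.05,
                         n_retain = 3,
                         site_test_component = 3,
                         k_max = 10) {
  stage <- "ingest"
  manifest <- list()
  tryCatch({
    if (inherits(input, "report_set")) {
      rs <- input
      manifest$reports_in <- n_reports(rs)
    } else {
      raw <- read_faers_tables(input[["demo"]], input[["drug"]], input[["reac"]])
      manifest$parse_report <- as.list(attr(raw, "parse_report"))
      rs <- merge_and_deduplicate(raw)
      manifest$dedup_report <- as.list(attr(rs, "dedup_report"))
      manifest$reports_in <- n_reports(rs)
    }
    if (!is.null(name_map)) rs <- normalize_drug_names(rs, name_map)
    if (oral_only) {
      stage <- "oral filter"
      rs <- filter_oral(rs)
    }
    manifest$reports_analyzed <- n_reports(rs)
    if (n_reports(rs) == 0) stop("no reports left for analysis")

    stage <- "event selection"
    counts <- event_report_counts(rs, pts = pt_set$pt)
    events <- select_events(counts, min_reports = min_event_reports)
    if (length(events) < 3) {
      stop(sprintf("only %d event PT(s) pass the %d-report screen; need >= 3",
                   length(events), min_event_reports))
    }
    manifest$events_selected <- length(events)

    stage <- "signal statistics"
    signals <- pairwise_signals(rs, events = events)
    drugs <- select_drugs(signals, min_reports = min_drug_reports, alpha = alpha)
    if (length(drugs) < 2) stop("fewer than 2 drugs pass the selection rule")
    manifest$drugs_selected <- length(drugs)
    signals_sel <- as.data.table(signals)[drug %chin% drugs]
    volcano <- volcano_table(signals_sel)
    demo <- demographic_report(rs, event_pts = pt_set$pt)

    stage <- "PCA"
    lnror <- assemble_matrix(signals_sel, events = events, drugs = drugs)
    pca <- pca_correlation(lnror, n_retain = n_retain)
    sites <- classify_site(rownames(lnror), setNames(pt_set$site, pt_set$pt))
    comp <- min(site_test_component, pca$n_retain)
    site_test <- tryCatch(
      pc_site_ttest(pca$scores[, comp], sites),
      error = function(e) { warning(conditionMessage(e)); NULL })

    stage <- "clustering"
    hc <- ward_cluster(pca$loadings)
    k <- elbow_select_k(hc, k_max = k_max)
    clusters <- assign_clusters(hc, k)
    manifest$k_selected <- k

    res <- list(table_b = rs, signals = signals_sel, volcano = volcano,
                demographics = demo, events = events, drugs = drugs,
                lnror = lnror, pca = pca, site_test = site_test,
                hclust = hc, k = k, clusters = clusters, manifest = manifest)
    if (!is.null(out_dir)) write_bundle(res, out_dir)
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Write a pipeline result bundle as TSV + JSON manifest
#'
#' @param res the list returned by [run_pipeline()].
#' @param out_dir directory to create.
#' @export
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_b(res$table_b, file.path(out_dir, "table_b.tsv"))
  fwrite(res$signals, file.path(out_dir, "signals.tsv"), sep = "\t")
  fwrite(res$volcano, file.path(out_dir, "volcano.tsv"), sep = "\t")
  fwrite(res$demographics, file.path(out_dir, "demographics.tsv"), sep = "\t")
  ev <- data.table(pt = rownames(res$lnror))
  fwrite(cbind(ev, as.data.table(res$lnror)), file.path(out_dir, "lnror_matrix.tsv"),
         sep = "\t")
  pca <- res$pca
  fwrite(data.table(component = seq_along(pca$eigenvalues),
                    eigenvalue = pca$eigenvalues,
                    pct_variance = pca$pct_variance),
         file.path(out_dir, "pca_variance.tsv"), sep = "\t")
  fwrite(data.table(pt = rownames(pca$scores), as.data.table(pca$scores)),
         file.path(out_dir, "pca_scores.tsv"), sep = "\t")
  fwrite(data.table(drug = rownames(pca$loadings),
                    as.data.table(pca$loadings),
                    cluster = res$clusters[rownames(pca$loadings)]),
         file.path(out_dir, "pca_loadings.tsv"), sep = "\t")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
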