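#' Build a 2x2 contingency table from the analysis table
#'
#' Cross-classifies deduplicated reports by an index condition (typically
#' "mentions drug D", or a demographic stratum) and an event condition
#' (typically "reports at least one PT from a given set"). Cell `a` counts
#' reports satisfying both, `b` index-only, `c` event-only, `d` neither, so
#' `a + b + c + d` equals the number of reports.
#'
#' @param reports a `report_set` (see [as_report_set()]) or logical vectors.
#' @param index logical vector over reports, or a character vector of drug
#'   names (a report is index if it mentions any of them).
#' @param event logical vector over reports, or a character vector of PT
#'   names (a report is an event case if it reports any of them).
#' @return an object of class `contingency_table` with fields `a`,`b`,`c`,`d`,
#'   `corrected` (FALSE) and `correction` (0.5).
#' @export
build_contingency <- function(reports, index, event) {
  if (inherits(reports, "report_set")) {
    n <- nrow(reports$reports)
    ids <- reports$reports$primaryid
    if (is.character(index)) {
      hit <- unique(reports$drugs[drug %chin% index, primaryid])
      index <- ids %in% hit
    }
    if (is.character(event)) {
      hit <- unique(reports$events[pt %chin% event, primaryid])
      event <- ids %in% hit
    }
  } else {
    n <- length(index)
  }
  stopifnot(is.logical(index), is.logical(event), length(index) == length(event))
  a <- sum(index & event)
  b <- sum(index & !event)
  c_ <- sum(!index & event)
  d <- n - a - b - c_
  contingency_table(a, b, c_, d)
}

#' Construct a contingency table from four counts
#'
#' @param a,b,c,d non-negative counts: `a` = index group with event, `b` =
#'   index group without, `c` = comparator with, `d` = comparator without.
#' @param corrected whether a continuity correction has already been applied.
#' @param correction the correction increment (default 0.5).
#' @export
contingency_table <- function(a, b, c, d, corrected = FALSE, correction = 0.5) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop("contingency cells must be finite and non-negative")
  }
  if (!corrected && any(cells != floor(cells))) {
    stop("uncorrected contingency cells must be integers")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 corrected = corrected, correction = correction),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("index", "comparator"), c("event", "no event")))
  cat(sprintf("2x2 contingency table (%s)\n",
              if (x$corrected) sprintf("Haldane +%g", x$correction) else "raw counts"))
  print(m)
  invisible(x)
}

#' Apply the Haldane continuity correction
#'
#' Adds the correction increment (default 0.5) to every cell so that the
#' odds ratio and its log are finite even with zero cells. Correcting twice
#' is an error.
#'
#' @param table a `contingency_table`.
#' @export
haldane <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$corrected) stop("table is already Haldane-corrected")
  k <- table$correction
  contingency_table(table$a + k, table$b + k, table$c + k, table$d + k,
                    corrected = TRUE, correction = k)
}

#' Reporting odds ratio
#'
#' ROR = (a/b)/(c/d). Call [haldane()] first if any cell may be zero.
#'
#' @param table a `contingency_table`.
#' @return named list with `ror` and `ln_ror`.
#' @export
compute_ror <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  ror <- (table$a / table$b) / (table$c / table$d)
  list(ror = ror, ln_ror = log(ror))
}

#' Woolf (logit-scale) confidence interval for the ROR
#'
#' exp(lnROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table a `contingency_table` with strictly positive cells.
#' @param level confidence level (default 0.95).
#' @return c(ci_low, ci_high).
#' @export
woolf_ci <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    stop("woolf_ci requires all cells > 0; apply haldane() first")
  }
  z <- qnorm(1 - (1 - level) / 2)
  lr <- log((table$a / table$b) / (table$c / table$d))
  se <- sqrt(sum(1 / cells))
  exp(lr + c(-1, 1) * z * se)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided p: the sum, over the hypergeometric support
#' of cell `a` given fixed margins, of all point probabilities not exceeding
#' the observed one (with `1 + 1e-7` relative slack, the convention used by
#' most implementations). Probabilities are evaluated in log space via
#' log-gamma so the test is stable at database scale. When the support size
#' exceeds `max_support` a normal approximation to the log odds ratio
#' (Haldane-corrected Wald z) is used instead and flagged via the
#' `"approximate"` attribute.
#'
#' Fisher's test is computed on the raw integer counts; the Haldane
#' correction applies only to the ROR and its interval.
#'
#' @param table a `contingency_table` with uncorrected integer cells, or the
#'   count `a` when `b,c,d` are also given.
#' @param b,c,d optional counts when `table` is given as the scalar `a`.
#' @param max_support support-size threshold above which the normal
#'   approximation is used (default 1e6, which covers full FAERS scale).
#' @return the two-sided p-value, with attribute `approximate` (logical).
#' @export
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL,
                                   max_support = 1e6) {
  if (inherits(table, "contingency_table")) {
    if (table$corrected) stop("Fisher's exact test needs raw (uncorrected) counts")
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(cells != floor(cells)) || any(cells < 0)) {
    stop("Fisher's exact test requires non-negative integer cells")
  }
  m <- a + b          # index-row margin
  n2 <- c + d         # comparator-row margin
  k <- a + c          # event-column margin
  lo <- max(0, k - n2)
  hi <- min(k, m)
  if (hi - lo + 1 > max_support) {
    num <- (a + 0.5) * (d + 0.5)
    den <- (b + 0.5) * (c + 0.5)
    z <- log(num / den) / sqrt(1/(a+.5) + 1/(b+.5) + 1/(c+.5) + 1/(d+.5))
    p <- 2 * pnorm(-abs(z))
    return(structure(min(p, 1), approximate = TRUE))
  }
  support <- lo:hi
  logp <- lgamma(m + 1) - lgamma(support + 1) - lgamma(m - support + 1) +
    lgamma(n2 + 1) - lgamma(k - support + 1) - lgamma(n2 - k + support + 1) -
    (lgamma(m + n2 + 1) - lgamma(k + 1) - lgamma(m + n2 - k + 1))
  log_obs <- logp[support == a]
  keep <- logp <= log_obs + log1p(1e-7)
  sel <- logp[keep]
  mx <- max(sel)
  p <- exp(mx + log(sum(exp(sel - mx))))
  structure(min(p, 1), approximate = FALSE)
}

#' Capped -log10 p-value
#'
#' Underflowing p-values (below 1e-308, the double-precision limit at which
#' statistical software stops resolving them) are capped at 308 on the
#' -log10 scale; p = 0 maps to the cap.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param cap the cap (default 308).
#' @export
neglog10_cap <- function(p, cap = 308) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  pmin(-log10(p), cap)
}

#' Full signal statistics for one 2x2 table
#'
#' Combines the ROR on the Haldane-corrected table, the Woolf interval, the
#' two-sided Fisher exact p on the raw counts, and the capped -log10 p.
#'
#' @param table an uncorrected `contingency_table`.
#' @param level confidence level for the Woolf interval.
#' @param correct apply the Haldane correction before the ROR/CI (default TRUE).
#' @param max_support passed to [fisher_exact_two_sided()].
#' @return a `signal_result` list: `ror`, `ln_ror`, `ci_low`, `ci_high`,
#'   `p_value`, `neglog10p`, `approximate`, `table` (the corrected table).
#' @export
signal_stats <- function(table, level = 0.95, correct = TRUE, max_support = 1e6) {
  stopifnot(inherits(table, "contingency_table"), !table$corrected)
  p <- fisher_exact_two_sided(table, max_support = max_support)
  ct <- if (correct) haldane(table) else table
  est <- compute_ror(ct)
  ci <- woolf_ci(ct, level)
  structure(list(ror = est$ror, ln_ror = est$ln_ror,
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = as.numeric(p),
                 neglog10p = neglog10_cap(as.numeric(p)),
                 approximate = isTRUE(attr(p, "approximate")),
                 table = ct),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("ROR %.4g (95%% CI %.4g-%.4g), lnROR %.4g, p %.4g, -log10 p %.4g%s\n",
              x$ror, x$ci_low, x$ci_high, x$ln_ror, x$p_value, x$neglog10p,
              if (x$approximate) " [normal approx.]" else ""))
  invisible(x)
}

#' Signal statistics for every drug-event pair
#'
#' Builds the 2x2 table for each (drug, event PT) pair over the analysis
#' table in one pass and computes the full signal statistics. Pair counts are
#' obtained by joining drug mentions to event mentions on report id, so the
#' cost is linear in the number of mentions.
#'
#' @param reports a `report_set`.
#' @param drugs character vector of drugs to analyze (default: all mentioned).
#' @param events character vector of event PTs (default: all reported).
#' @param ... passed to [signal_stats()].
#' @return a `data.table` with one row per pair: drug, event, a, b, c, d,
#'   ror, ln_ror, ci_low, ci_high, p_value, neglog10p, n_reports (reports
#'   mentioning the drug).
#' @export
pairwise_signals <- function(reports, drugs = NULL, events = NULL, ...) {
  stopifnot(inherits(reports, "report_set"))
  n <- nrow(reports$reports)
  dmen <- unique(reports$drugs[, .(primaryid, drug)])
  emen <- unique(reports$events[, .(primaryid, pt)])
  if (is.null(drugs)) drugs <- sort(unique(dmen$drug))
  if (is.null(events)) events <- sort(unique(emen$pt))
  dmen <- dmen[drug %chin% drugs]
  emen <- emen[pt %chin% events]
  nd <- dmen[, .(n_d = .N), by = drug]
  ne <- emen[, .(n_e = .N), by = pt]
  both <- merge(dmen, emen, by = "primaryid", allow.cartesian = TRUE)[
    , .(a = .N), by = .(drug, pt)]
  grid <- CJ(drug = drugs, pt = events)
  grid <- merge(grid, both, by = c("drug", "pt"), all.x = TRUE)
  grid <- merge(grid, nd, by = "drug", all.x = TRUE)
  grid <- merge(grid, ne, by = "pt", all.x = TRUE)
  grid[is.na(a), a := 0L]
  grid[is.na(n_d), n_d := 0L]
  grid[is.na(n_e), n_e := 0L]
  res <- grid[, {
    tab <- contingency_table(a, n_d - a, n_e - a, n - n_d - n_e + a)
    s <- signal_stats(tab, ...)
    .(a = a, b = n_d - a, c = n_e - a, d = n - n_d - n_e + a,
      ror = s$ror, ln_ror = s$ln_ror, ci_low = s$ci_low, ci_high = s$ci_high,
      p_value = s$p_value, neglog10p = s$neglog10p, n_reports = n_d)
  }, by = .(drug, pt)]
  setnames(res, "pt", "event")
  res[]
}

#' Volcano table
#'
#' One row per drug-event pair with effect size (lnROR), significance
#' (capped -log10 p) and the labeling flag used on the volcano plot:
#' a pair is labeled when lnROR >= `ln_ror_min` and -log10 p >= `neglog10p_min`.
#' Rows are sorted by decreasing significance.
#'
#' @param signals output of [pairwise_signals()].
#' @param ln_ror_min effect-size labeling threshold (default 1).
#' @param neglog10p_min significance labeling threshold (default 1.3,
#'   i.e. p < 0.05).
#' @export
volcano_table <- function(signals, ln_ror_min = 1, neglog10p_min = 1.3) {
  v <- as.data.table(signals)[, .(drug, event, ln_ror, neglog10p, n_reports,
                                  labeled = ln_ror >= ln_ror_min &
                                            neglog10p >= neglog10p_min)]
  setorder(v, -neglog10p)
  v[]
}
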