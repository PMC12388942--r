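#' Canonical simulation scenarios
#'
#' Three fixed study designs used throughout the package's validation:
#' a null design for calibration, a diagonal-signal design for parameter
#' recovery, and a planted three-group design for end-to-end structure
#' recovery. Each returns a [sim_config()]; only the seed (and, where
#' stated, the report count) varies between runs so that results are
#' comparable across analyses.
#'
#' @name scenarios
NULL

#' @describeIn scenarios Null design: 30 drugs x 10 events, no injected
#'   signal (beta = 0), 50,000 reports, drug prevalence 0.1, event base
#'   logit -3.5 (about a 2.9% background reporting rate). The 300 drug-event
#'   pairs serve as null replicates for type-I error and CI coverage checks.
#' @param seed RNG seed.
#' @param n_reports number of reports.
#' @export
scenario_null <- function(seed = 1L, n_reports = 50000) {
  sim_config(n_reports,
             drugs = sprintf("drug%02d", 1:30),
             events = sprintf("event%02d", 1:10),
             drug_prevalence = 0.1, event_base_logit = -3.5,
             duplicate_rate = 0, nonoral_rate = 0, seed = seed)
}

#' @describeIn scenarios Parameter-recovery design: 12 drugs x 12 events
#'   with a diagonal injected signal (each event raised by exactly one
#'   drug), so the marginal reporting odds ratio of pair i equals
#'   exp(beta) exactly and estimation error is attributable to sampling
#'   alone. Default beta = ln 2, prevalence 0.25, base logit -3.5.
#' @param beta injected log odds ratio on the diagonal.
#' @export
scenario_recovery <- function(seed = 1L, n_reports = 50000, beta = log(2)) {
  sim_config(n_reports,
             drugs = sprintf("drug%02d", 1:12),
             events = sprintf("event%02d", 1:12),
             drug_prevalence = 0.25, event_base_logit = -3.5,
             beta = diag(beta, 12, 12),
             duplicate_rate = 0, nonoral_rate = 0, seed = seed)
}

#' @describeIn scenarios Single-pair design: one drug (prevalence 0.3), one
#'   event (base logit -3), injected beta = ln 3 by default.
#' @export
scenario_single_signal <- function(seed = 1L, n_reports = 200000, beta = log(3)) {
  sim_config(n_reports, drugs = "drugA", events = "eventA",
             drug_prevalence = 0.3, event_base_logit = -3,
             beta = matrix(beta, 1, 1),
             duplicate_rate = 0, nonoral_rate = 0, seed = seed)
}

#' @describeIn scenarios Planted-structure design: 12 drugs in three groups
#'   of four, 9 events in three groups of three; drugs of group g raise the
#'   events of group g by beta = 1.6 log-odds and no others, so the lnROR
#'   columns form three well-separated correlation blocks. 60,000 reports,
#'   prevalence 0.08, base logit -4, with case duplication (3%) and
#'   non-oral routes (5%) switched on so the whole ingest path is
#'   exercised. The ground-truth drug grouping is attached to the config as
#'   `$truth_groups`.
#' @export
scenario_planted_clusters <- function(seed = 1L, n_reports = 60000) {
  drugs <- sprintf("drug%02d", 1:12)
  events <- sprintf("event%02d", 1:9)
  groups <- rep(1:3, each = 4)
  beta <- matrix(0, 12, 9)
  for (g in 1:3) beta[groups == g, rep(1:3, each = 3) == g] <- 1.6
  cfg <- sim_config(n_reports, drugs = drugs, events = events,
                    drug_prevalence = 0.08, event_base_logit = -4,
                    beta = beta, duplicate_rate = 0.03, nonoral_rate = 0.05,
                    seed = seed)
  cfg$truth_groups <- setNames(groups, drugs)
  cfg$truth_sites <- setNames(rep(c("upper", "lower", "not_classified"), each = 3),
                              events)
  cfg
}

#' PT catalog for a simulation config
#'
#' Builds the catalog/site-map table that [run_pipeline()] expects from a
#' simulation config, so synthetic runs use the same interface as real
#' data. Sites default to the config's `truth_sites` when present, else
#' `not_classified`.
#'
#' @param config a `sim_config`.
#' @param sites optional named character vector PT -> site.
#' @export
sim_pt_set <- function(config, sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sites)) sites <- config$truth_sites
  if (is.null(sites)) sites <- setNames(rep("not_classified", length(config$events)),
                                        config$events)
  data.table(pt = config$events, site = unname(sites[config$events]))
}
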