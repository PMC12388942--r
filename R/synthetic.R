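#' Configure a synthetic spontaneous-report simulation
#'
#' The generator emulates the statistical structure the disproportionality
#' analysis assumes: each report carries an independent Bernoulli exposure
#' per drug, and each event PT occurs with probability
#' `plogis(base_logit_e + sum_d beta[d, e] * x_d)` given the report's drug
#' vector `x`. `beta[d, e]` is the injected log odds ratio: with a single
#' exposure and no other covariates the marginal reporting odds ratio of the
#' pair equals `exp(beta)` exactly, which is what the recovery tests use as
#' the ground truth. Demographics, duplicate case versions, and non-oral
#' routes are layered on top at the configured rates and do not feed back
#' into the event model.
#'
#' @param n_reports number of reports (cases) to simulate.
#' @param drugs character vector of drug names.
#' @param events character vector of event PT names.
#' @param drug_prevalence per-drug exposure probability, recycled to
#'   `length(drugs)`.
#' @param event_base_logit per-event baseline logit, recycled to
#'   `length(events)`.
#' @param beta drugs x events matrix of injected log odds ratios (default all
#'   zero). Overridden by `u`/`v` when given.
#' @param u,v optional low-rank factors (per-drug and per-event reals) with
#'   `beta = u %o% v`.
#' @param sex_probs probabilities for female/male/unknown. The default
#'   reflects the composition of large spontaneous-report databases, where
#'   female patients make up just over half of reports.
#' @param age_mix age mixture: fractions drawn from Uniform(20, 69),
#'   Uniform(70, 95), and missing.
#' @param duplicate_rate probability a case is emitted twice with an
#'   incremented primaryid (same caseid).
#' @param nonoral_rate probability an individual drug mention is assigned a
#'   non-oral route instead of ORAL.
#' @param seed integer RNG seed; the same config always generates the same
#'   report set.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reports,
                       drugs,
                       events,
                       drug_prevalence = 0.1,
                       event_base_logit = -4,
                       beta = NULL,
                       u = NULL, v = NULL,
                       sex_probs = c(female = 0.56, male = 0.37, unknown = 0.07),
                       age_mix = c(young = 0.6, old = 0.3, missing = 0.1),
                       duplicate_rate = 0.05,
                       nonoral_rate = 0.1,
                       seed = 1L) {
  D <- length(drugs); E <- length(events)
  stopifnot(n_reports >= 1, D >= 1, E >= 1,
            !anyDuplicated(drugs), !anyDuplicated(events))
  drug_prevalence <- rep_len(drug_prevalence, D)
  event_base_logit <- rep_len(event_base_logit, E)
  stopifnot(all(drug_prevalence > 0 & drug_prevalence < 1))
  if (!is.null(u) || !is.null(v)) {
    stopifnot(length(u) == D, length(v) == E)
    beta <- outer(u, v)
  }
  if (is.null(beta)) beta <- matrix(0, D, E)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(D, E))) {
    stop(sprintf("beta must be %d x %d (drugs x events)", D, E))
  }
  dimnames(beta) <- list(drugs, events)
  stopifnot(abs(sum(sex_probs) - 1) < 1e-8, abs(sum(age_mix) - 1) < 1e-8,
            duplicate_rate >= 0, duplicate_rate <= 1,
            nonoral_rate >= 0, nonoral_rate <= 1)
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 events = events, drug_prevalence = drug_prevalence,
                 event_base_logit = event_base_logit, beta = beta,
                 sex_probs = sex_probs, age_mix = age_mix,
                 duplicate_rate = duplicate_rate, nonoral_rate = nonoral_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Injected ground-truth log odds ratio for one drug-event pair
#'
#' @param config a `sim_config`.
#' @param drug,event names present in the config.
#' @export
truth_lnror <- function(config, drug, event) {
  stopifnot(inherits(config, "sim_config"))
  if (!drug %in% config$drugs) stop(sprintf("unknown drug: %s", drug))
  if (!event %in% config$events) stop(sprintf("unknown event: %s", event))
  config$beta[drug, event]
}

#' Generate a synthetic report set
#'
#' Draws the exposure matrix, events, demographics, routes and duplicate
#' case versions described in [sim_config()]. The returned `report_set` is
#' already deduplicated (one row per case, greatest primaryid); the
#' pre-deduplication raw tables, including the duplicate versions, are what
#' [write_faers_files()] emits. The config and a truth log (injected beta
#' per pair, number of duplicate versions emitted) are attached.
#'
#' @param config a `sim_config`.
#' @return a `report_set` with attributes `truth` (the config) and
#'   `truth_log` (list: beta matrix, n_duplicates).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  n <- config$n_reports
  D <- length(config$drugs); E <- length(config$events)

  x <- matrix(runif(n * D) < rep(config$drug_prevalence, each = n), n, D)
  logit <- matrix(rep(config$event_base_logit, each = n), n, E)
  logit <- logit + (x + 0) %*% config$beta
  y <- matrix(runif(n * E), n, E) < plogis(logit)

  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  agegrp <- sample(names(config$age_mix), n, TRUE, config$age_mix)
  age <- ifelse(agegrp == "young", runif(n, 20, 69),
         ifelse(agegrp == "old", runif(n, 70, 95), NA_real_))

  caseid <- sprintf("C%07d", seq_len(n))
  primaryid <- sprintf("%d1", seq_len(n))  # version 1 of each case

  wx <- which(x, arr.ind = TRUE)
  nonoral <- runif(nrow(wx)) < config$nonoral_rate
  drugs <- data.table(primaryid = primaryid[wx[, 1]],
                      drug = config$drugs[wx[, 2]],
                      route = fifelse(nonoral, "INTRAVENOUS", "ORAL"),
                      role = "PS")
  wy <- which(y, arr.ind = TRUE)
  events <- data.table(primaryid = primaryid[wy[, 1]],
                       pt = config$events[wy[, 2]])

  reports <- data.table(primaryid = primaryid, caseid = caseid,
                        sex = sex, age_years = age)
  dup <- runif(n) < config$duplicate_rate
  out <- as_report_set(reports, drugs, events)
  attr(out, "truth") <- config
  attr(out, "truth_log") <- list(beta = config$beta, n_duplicates = sum(dup),
                                 duplicated_case = dup)
  out
}

#' Write a synthetic report set as FAERS-style quarterly files
#'
#' Emits DEMO/DRUG/REAC in the `$`-delimited dialect read by
#' [read_faers_tables()]. Cases flagged as duplicated in the generator's
#' truth log are emitted twice: once under their version-1 primaryid and
#' once, identically, under the incremented version-2 primaryid, emulating
#' FAERS case revisions. Ages are written in mixed units (years or months)
#' to exercise unit standardization; the unit choice is deterministic (even
#' report index = months).
#'
#' @param x a `report_set` from [generate_reports()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_faers_files <- function(x, dir) {
  stopifnot(inherits(x, "report_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory: %s", dir))
  tl <- attr(x, "truth_log")
  dup <- if (is.null(tl)) rep(FALSE, nrow(x$reports)) else tl$duplicated_case

  reports <- copy(x$reports)
  even <- seq_len(nrow(reports)) %% 2 == 0
  reports[, age := fifelse(even, as.character(age_years * 12),
                           as.character(age_years))]
  reports[, age_cod := fifelse(even, "MON", "YR")]
  reports[is.na(age_years), `:=`(age = "", age_cod = "")]
  reports[, sexcode := fifelse(sex == "male", "M",
                       fifelse(sex == "female", "F", "UNK"))]

  bump_version <- function(pid) sub("1$", "2", pid)
  demo <- reports[, .(primaryid, caseid, sex = sexcode, age, age_cod)]
  demo2 <- demo[dup]
  demo2[, primaryid := bump_version(primaryid)]
  demo <- rbind(demo, demo2)

  dup_ids <- x$reports$primaryid[dup]
  drug <- x$drugs[, .(primaryid, drugname = drug, route, role_cod = role)]
  drug2 <- drug[primaryid %chin% dup_ids]
  drug2[, primaryid := bump_version(primaryid)]
  drug <- rbind(drug, drug2)
  reac <- x$events[, .(primaryid, pt)]
  reac2 <- reac[primaryid %chin% dup_ids]
  reac2[, primaryid := bump_version(primaryid)]
  reac <- rbind(reac, reac2)

  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"))
  fwrite(demo, paths["demo"], sep = "$", quote = FALSE)
  fwrite(drug, paths["drug"], sep = "$", quote = FALSE)
  fwrite(reac, paths["reac"], sep = "$", quote = FALSE)
  paths
}
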