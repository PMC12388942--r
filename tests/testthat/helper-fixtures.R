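# Shared fixtures and independent oracles. Fixtures are written to tempfiles
# at test time; nothing binary is stored in the repo.

# Write a toy DEMO/DRUG/REAC trio in the $-delimited dialect and return the
# three paths. `rows_*` are character vectors of pre-joined data lines.
write_faers_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                demo_rows, drug_rows, reac_rows) {
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$caseid$sex$age$age_cod", demo_rows), paths["demo"])
  writeLines(c("primaryid$drugname$route$role_cod", drug_rows), paths["drug"])
  writeLines(c("primaryid$pt", reac_rows), paths["reac"])
  paths
}

# Six-report toy used across modules: 3 reports mention drug D (2 of them
# with event E), 1 non-D report has E. Hand tally for the (D, E) pair:
# a = 2 (11, 21), b = 1 (31), c = 1 (41), d = 2 (51, 61).
toy_report_set <- function() {
  reports <- data.frame(
    primaryid = c("11", "21", "31", "41", "51", "61"),
    caseid = c("c1", "c2", "c3", "c4", "c5", "c6"),
    sex = c("female", "male", "female", "male", "unknown", "female"),
    age_years = c(35, 72, NA, 80, 55, 41)
  )
  drugs <- data.frame(
    primaryid = c("11", "21", "31", "41", "41", "61"),
    drug = c("D", "D", "D", "X", "Y", "X"),
    route = c("ORAL", "ORAL", "INTRAVENOUS", "ORAL", "TOPICAL", "ORAL"),
    role = "PS"
  )
  events <- data.frame(
    primaryid = c("11", "21", "41", "51"),
    pt = c("E", "E", "E", "F")
  )
  as_report_set(reports, drugs, events)
}

# Independent two-sided Fisher oracle: direct hypergeometric enumeration
# with choose() products (no log-space), minimum-likelihood rule.
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  s <- lo:hi
  probs <- choose(m1, s) * choose(m2, k - s) / choose(m1 + m2, k)
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}
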