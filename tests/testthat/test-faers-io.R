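test_that("well-formed fixture files parse identically and malformed rows are skipped", {
  paths <- write_faers_fixture(
    demo_rows = c("11$c1$F$35$YR", "21$c2$M$840$MON"),
    drug_rows = c("11$ASPIRIN.$ORAL$PS", "$LOSTDRUG$ORAL$SS"),
    reac_rows = c("11$Gastric ulcer", "21$Duodenal ulcer")
  )
  raw <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(raw$demo), 2)
  expect_equal(nrow(raw$drug), 1)  # blank primaryid dropped
  expect_equal(nrow(raw$reac), 2)
  expect_equal(unname(attr(raw, "parse_report")["drug_skipped"]), 1)
})

test_that("a missing required column is a hard error naming the column", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, "11$c1$F$35$YR", "11$A$ORAL$PS", "11$E")
  writeLines(c("primaryid$drugname_oops", "11$A"), paths["drug"])
  expect_error(read_faers_tables(paths["demo"], paths["drug"], paths["reac"]),
               "drugname")
  expect_error(read_faers_tables(file.path(dir, "nope.txt"), paths["drug"],
                                 paths["reac"]),
               "not found")
})

test_that("deduplication keeps the greatest primaryid per case and collapses repeated mentions", {
  paths <- write_faers_fixture(
    demo_rows = c("71$c7$F$35$YR", "72$c7$F$36$YR",   # two versions of case 7
                  "11$c1$M$50$YR", "21$c2$F$$", "31$c3$M$60$YR", "41$c4$F$70$YR"),
    drug_rows = c("72$A$ORAL$PS", "11$A$ORAL$PS", "11$A$ORAL$PS",
                  "21$B$ORAL$PS", "31$B$ORAL$PS", "41$A$ORAL$PS"),
    reac_rows = c("72$Gastric ulcer", "11$Gastric ulcer", "11$Gastric ulcer",
                  "21$Ulcer", "31$Ulcer", "41$Gastric ulcer")
  )
  raw <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"])
  rs <- merge_and_deduplicate(raw)
  expect_equal(n_reports(rs), 5)  # 6 demo cases, 1 duplicated
  expect_true("72" %in% rs$reports$primaryid)
  expect_false("71" %in% rs$reports$primaryid)
  # duplicated (drug, route) and PT mentions collapse to one
  expect_equal(nrow(rs$drugs[rs$drugs$primaryid == "11", ]), 1)
  expect_equal(nrow(rs$events[rs$events$primaryid == "11", ]), 1)
  expect_equal(rs$reports$age_years[rs$reports$primaryid == "72"], 36)
  # idempotence: deduplicating the deduplicated set changes nothing
  rt <- write_faers_files(rs, withr::local_tempdir())
  rs2 <- merge_and_deduplicate(read_faers_tables(rt["demo"], rt["drug"], rt["reac"]))
  expect_equal(n_reports(rs2), n_reports(rs))
  expect_setequal(rs2$reports$primaryid, rs$reports$primaryid)
})

test_that("oral filter is report-scoped, returns a subset, and leaves fields unchanged", {
  rs <- toy_report_set()
  oral <- filter_oral(rs)
  # 11, 21, 41, 61 have an oral mention; 31 is IV-only; 51 has no drugs
  expect_setequal(oral$reports$primaryid, c("11", "21", "41", "61"))
  # retained reports keep all their mentions, including non-oral ones
  expect_true("TOPICAL" %in% oral$drugs$route[oral$drugs$primaryid == "41"])
  rep41 <- rs$reports[rs$reports$primaryid == "41", ]
  expect_equal(oral$reports[oral$reports$primaryid == "41", ], rep41)
  # mention-level variant drops the topical mention itself
  oral2 <- filter_oral(rs, mention_level = TRUE)
  expect_false("TOPICAL" %in% oral2$drugs$route)
})

test_that("drug-name normalization maps synonyms, logs unmapped names, rejects conflicts", {
  dir <- withr::local_tempdir()
  map_path <- file.path(dir, "map.csv")
  writeLines(c("raw,generic",
               "aspirin.,acetylsalicylic acid",
               "asa,acetylsalicylic acid",
               "acetylsalicylic acid,acetylsalicylic acid"), map_path)
  nm <- read_name_map(map_path)
  rs <- as_report_set(
    data.frame(primaryid = "1", caseid = "c1", sex = "female", age_years = 40),
    data.frame(primaryid = c("1", "1", "1", "1"),
               drug = c("ASPIRIN.", "ASA", "acetylsalicylic acid", "BRANDX"),
               route = "ORAL", role = "PS"),
    data.frame(primaryid = character(0), pt = character(0))
  )
  out <- normalize_drug_names(rs, nm)
  # three synonyms collapse to one generic; unmapped kept lower-cased
  expect_setequal(out$drugs$drug, c("acetylsalicylic acid", "brandx"))
  expect_equal(sum(out$drugs$drug == "acetylsalicylic acid"), 1)
  expect_equal(as.integer(attr(out, "unmapped")["brandx"]), 1)
  # drop policy removes the unmapped mention
  nm_drop <- read_name_map(map_path, unmapped_policy = "drop")
  expect_false("brandx" %in% normalize_drug_names(rs, nm_drop)$drugs$drug)
  # conflicting entries are a hard error
  writeLines(c("raw,generic", "asa,acetylsalicylic acid", "ASA,aspirin"), map_path)
  expect_error(read_name_map(map_path), "conflicting")
})

test_that("age standardization converts every unit code and flags the odd cases", {
  expect_equal(standardize_age(840, "MON"), 70)
  expect_equal(standardize_age(7, "DEC"), 70)
  expect_equal(standardize_age(c(70, 364, 26, 8766), c("YR", "WK", "WK", "HR")),
               c(70, 7, 0.5, 1))
  expect_equal(standardize_age(365.25, "DY"), 1)
  expect_warning(out <- standardize_age(70, NA), "assumed YR")
  expect_equal(out, 70)
  expect_warning(out <- standardize_age(-5, "YR"), "negative")
  expect_true(is.na(out))
  expect_true(is.na(standardize_age("not a number", "YR")))
})

test_that("synthetic report sets round-trip losslessly through the quarterly-file dialect", {
  cfg <- sim_config(300, drugs = c("d1", "d2", "d3"), events = c("e1", "e2"),
                    drug_prevalence = 0.3, event_base_logit = -1,
                    duplicate_rate = 0, nonoral_rate = 0.2, seed = 5)
  rs <- generate_reports(cfg)
  paths <- write_faers_files(rs, withr::local_tempdir())
  back <- merge_and_deduplicate(
    read_faers_tables(paths["demo"], paths["drug"], paths["reac"]))
  o <- order(rs$reports$primaryid); b <- order(back$reports$primaryid)
  expect_equal(back$reports$primaryid[b], rs$reports$primaryid[o])
  expect_equal(back$reports$sex[b], rs$reports$sex[o])
  expect_equal(back$reports$age_years[b], rs$reports$age_years[o],
               tolerance = 1e-12)
  key <- function(x) sort(paste(x$primaryid, x$drug, x$route))
  expect_equal(key(back$drugs), key(rs$drugs))
  expect_equal(sort(paste(back$events$primaryid, back$events$pt)),
               sort(paste(rs$events$primaryid, rs$events$pt)))
})
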