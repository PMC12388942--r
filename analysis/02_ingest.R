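#!/usr/bin/env Rscript
# Stage 2: ingest the quarterly-style files into the analysis table.
#
# Merges DEMO/DRUG/REAC on report id, keeps only the latest version of each
# case, restricts to cases with at least one orally administered drug, and
# writes the per-report analysis table ("table B": one row per report with
# its demographics, drugs, and event PTs).

suppressMessages(library(gisignal))

raw <- read_faers_tables("results/data/DEMO.txt", "results/data/DRUG.txt",
                         "results/data/REAC.txt")
cat(sprintf("parsed: %d demo, %d drug, %d reac rows (skipped: %s)\n",
            nrow(raw$demo), nrow(raw$drug), nrow(raw$reac),
            paste(attr(raw, "parse_report"), collapse = "/")))

rs <- merge_and_deduplicate(raw)
dd <- attr(rs, "dedup_report")
cat(sprintf("after dedup: %d reports (%d case versions removed, %d superseded mentions dropped)\n",
            n_reports(rs), dd["case_versions_removed"], dd["orphan_mentions_dropped"]))

oral <- filter_oral(rs)
cat(sprintf("oral-route subset: %d reports (%d dropped)\n",
            n_reports(oral), n_reports(rs) - n_reports(oral)))

write_table_b(oral, "results/table_b.tsv")
cat("wrote results/table_b.tsv\n")
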