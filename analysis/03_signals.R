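#!/usr/bin/env Rscript
# Stage 3: disproportionality statistics.
#
# For every drug-event pair over the analysis table: 2x2 contingency counts,
# Haldane-corrected reporting odds ratio with Woolf 95% CI, two-sided Fisher
# exact p, capped -log10 p, and the volcano labeling rule (lnROR >= 1 and
# -log10 p >= 1.3). Also reproduces, from the published contingency counts,
# the sex and age stratum rows that are fully printed in the source tables.

suppressMessages(library(gisignal))

raw <- read_faers_tables("results/data/DEMO.txt", "results/data/DRUG.txt",
                         "results/data/REAC.txt")
oral <- filter_oral(merge_and_deduplicate(raw))
truth_sites <- read.delim("results/truth_sites.tsv")

events <- select_events(event_report_counts(oral, pts = truth_sites$pt))
cat(sprintf("%d event PTs pass the 1000-report screen\n", length(events)))

signals <- pairwise_signals(oral, events = events)
drugs <- select_drugs(signals)
cat(sprintf("%d drugs pass the selection rule (p < 0.05 and > 1000 reports)\n",
            length(drugs)))
signals <- signals[signals$drug %in% drugs, ]
data.table::fwrite(signals, "results/signals.tsv", sep = "\t")

v <- volcano_table(signals)
data.table::fwrite(v, "results/volcano.tsv", sep = "\t")
cat(sprintf("volcano: %d/%d pairs labeled (these carry the injected effects)\n",
            sum(v$labeled), nrow(v)))

# demographic strata of the synthetic cohort (no effect was injected, so the
# intervals should cover 1)
demo <- demographic_report(oral, event_pts = truth_sites$pt)
data.table::fwrite(demo, "results/demographics.tsv", sep = "\t")
fem <- demo[demo$stratum == "sex" & demo$index_group == "female", ]
cat(sprintf("synthetic sex stratum (female index): ROR %.3f [%.3f, %.3f]\n",
            fem$ror, fem$ci_low, fem$ci_high))

# reproduction of the published stratum rows from their printed counts
sex <- stratum_signal(89080, 28957601, 61978, 19077011)  # female index
age <- stratum_signal(84604, 27334589, 45035, 11271212)  # under-70 index
printed <- data.frame(
  stratum = c("sex (female index)", "age (under-70 index)"),
  ror = c(sex$ror, age$ror),
  ci_low = c(sex$ci_low, age$ci_low),
  ci_high = c(sex$ci_high, age$ci_high)
)
write.table(format(printed, digits = 6), "results/printed_strata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("printed sex stratum reproduces as ROR %.3f [%.3f, %.3f]\n",
            sex$ror, sex$ci_low, sex$ci_high))
cat(sprintf("printed age stratum reproduces as ROR %.3f [%.3f, %.3f]\n",
            age$ror, age$ci_low, age$ci_high))
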