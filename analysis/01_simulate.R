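#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# The full spontaneous-report extract behind the published analysis (tens of
# millions of reports) cannot be redistributed, so the workflow runs on a
# synthetic report set with known ground truth: 12 drugs in three planted
# groups whose members share an injected +1.6 log-odds effect on one of
# three event blocks, 60,000 reports, with case-version duplicates and
# non-oral routes switched on. Downstream stages must recover the three
# groups without being told them.

suppressMessages(library(gisignal))

cfg <- scenario_planted_clusters(seed = 20260930)
rs <- generate_reports(cfg)
paths <- write_faers_files(rs, "results/data")

tl <- attr(rs, "truth_log")
cat(sprintf("simulated %d reports (%d drugs, %d event PTs), %d duplicate case versions\n",
            n_reports(rs), length(cfg$drugs), length(cfg$events), tl$n_duplicates))
cat("planted drug groups:\n")
print(split(names(cfg$truth_groups), cfg$truth_groups))

# persist the ground truth for the later recovery check
truth <- data.frame(drug = names(cfg$truth_groups),
                    group = unname(cfg$truth_groups))
write.table(truth, "results/truth_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(pt = names(cfg$truth_sites),
                       site = unname(cfg$truth_sites)),
            "results/truth_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %s\n", paste(paths, collapse = ", ")))
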