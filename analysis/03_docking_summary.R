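#!/usr/bin/env Rscript
# Docking-table triage on the packaged per-target docking results: threshold
# filtering at -20 kcal/mol, best hit per target, and the cross-target
# shared-inhibitor report over the top-10 lists.
#
# Writes results/docking_summary.csv and results/shared_inhibitors.csv.

library(pocketrank)

dir.create("results", showWarnings = FALSE)

tabs <- do.call(rbind, lapply(paste0("table", 4:8), load_fixture))
targets <- unique(tabs$target)

summary <- do.call(rbind, lapply(targets, function(t) {
  sel <- tabs[tabs$target == t, ]
  best <- best_hit(sel, t)
  data.frame(target = t,
             n_records = nrow(sel),
             n_hits = nrow(filter_hits(sel)),
             best_molecule = best$molecule,
             best_score = best$score)
}))
print(summary)
write.csv(summary, "results/docking_summary.csv", row.names = FALSE)

ov <- cross_target_overlap(tabs, mode = "top_n", n = 10)
print(ov)
shared <- data.frame(
  molecule = ov$shared,
  targets = vapply(ov$molecule_targets[ov$shared], paste, character(1),
                   collapse = ";")
)
write.csv(shared, "results/shared_inhibitors.csv", row.names = FALSE)
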