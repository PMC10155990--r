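#!/usr/bin/env Rscript
# Build the demo dataset: per-eye stimulus schedules and a ground-truth
# neuron population for one synthetic mouse, plus the MD-perturbed
# population for its second imaging timepoint.

library(odplast)
dir.create("results", showWarnings = FALSE)

seed <- 20260926L
sch_c <- make_stimulus_schedule(600, eye = "contra", seed = seed)
sch_i <- make_stimulus_schedule(600, eye = "ipsi", seed = seed + 1L)
write_schedule_tsv(sch_c, "results/schedule_contra.tsv")
write_schedule_tsv(sch_i, "results/schedule_ipsi.tsv")

ev <- sch_c$events
cnt <- table(paste0(ev$orientation[!ev$is_blank], "deg_",
                    signif(ev$sf[!ev$is_blank], 2), "cpd"))
cat(sprintf("contra schedule: %d presentations (%d blanks); %d grating\n",
            nrow(ev), sum(ev$is_blank), sum(!ev$is_blank)))
cat(sprintf("per-condition presentation counts: %d-%d (48 conditions)\n",
            min(cnt), max(cnt)))

pop <- sample_population(150, seed = seed + 2L)
pop_md <- apply_md_transition(pop, seed = seed + 3L)
write.table(pop, "results/population_p28.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(pop_md, "results/population_p32md.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("P28 categories: ")
print(table(factor(pop$category, c("C", "B", "I", "NR"))))
cat("P32MD categories: ")
print(table(factor(pop_md$category, c("C", "B", "I", "NR"))))
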