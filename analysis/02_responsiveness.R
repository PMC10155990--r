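#!/usr/bin/env Rscript
# Simulate the P28 session for the demo mouse and run spike inference,
# reverse correlation, and the three-criterion responsiveness
# classification for every neuron and eye.

library(odplast)
dir.create("results", showWarnings = FALSE)

seed <- 20260926L
pop <- read.table("results/population_p28.tsv", header = TRUE, sep = "\t")
sch <- list(contra = make_stimulus_schedule(600, eye = "contra",
                                            seed = seed),
            ipsi = make_stimulus_schedule(600, eye = "ipsi",
                                          seed = seed + 1L))
ses <- simulate_session(pop, sch, seed = seed + 10L)
ana <- analyze_session(ses, sf_sig = TRUE)

st <- ana$stats
write.table(st, "results/responsiveness_p28.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (eye in c("contra", "ipsi")) {
  s <- st[st$eye == eye, ]
  cat(sprintf(
    "%s eye: %d/%d responsive (thresholds: SNR > %.2f, SR > %.1f%%)\n",
    eye, sum(s$responsive), nrow(s), s$snr_75[1], s$sr_75[1]))
}
cat(sprintf("ground-truth responsive fraction: %.2f\n",
            mean(pop$category != "NR")))

write.table(ana$tuning, "results/tuning_p28.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ana$od, "results/od_p28.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
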