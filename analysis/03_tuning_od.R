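#!/usr/bin/env Rscript
# Summarize tuning and ocular dominance for the demo P28 session: ODI
# histogram with identifiable monocular bins, per-eye dF/F CDFs, and
# binocular orientation matching.

library(odplast)
dir.create("results", showWarnings = FALSE)

od <- read.table("results/od_p28.tsv", header = TRUE, sep = "\t")
tun <- read.table("results/tuning_p28.tsv", header = TRUE, sep = "\t")

ms <- mouse_odi_summaries(od)
cat(sprintf("mean ODI %.3f, summed ODI %.3f over %d responsive neurons\n",
            ms$mean_odi, ms$summed_odi, ms$n_responsive))

h <- odi_distributions(od)
jsonlite::write_json(h, "results/odi_distributions_p28.json",
                     auto_unbox = TRUE, digits = NA)
cat("ODI histogram counts (ipsi-monocular ... contra-monocular):\n")
print(h$counts)

b <- od[od$category == "B" & !is.na(od$delta_ori), ]
cat(sprintf("binocular matching: n = %d, median delta-ori %.1f degrees\n",
            nrow(b), median(b$delta_ori)))
write.table(b[, c("id", "odi", "delta_ori")],
            "results/binocular_matching_p28.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("median preferred SF (contra) %.3f cpd; median ori FWHM %.0f deg\n",
            median(tun$pref_sf[tun$eye == "contra"], na.rm = TRUE),
            median(tun$ori_fwhm[tun$eye == "contra"], na.rm = TRUE)))
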