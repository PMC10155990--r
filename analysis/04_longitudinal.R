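#!/usr/bin/env Rscript
# Track one synthetic mouse through 4 days of contralateral-eye MD:
# simulate and analyze both timepoints, match ROIs, restrict to the
# stable-perimeter region, and tabulate OD-category transitions.

library(odplast)
dir.create("results", showWarnings = FALSE)

seed <- 77002L
sim <- simulate_mouse(n_neurons = 140, duration = 600, md = TRUE,
                      seed = seed)

pop <- sim$pop
masks <- population_masks(pop)
names(masks) <- pop$id
pairs <- match_rois(masks, masks)  # zero drift between sessions
cat(sprintf("matched %d/%d ROIs (median overlap %.2f)\n",
            nrow(pairs), nrow(pop), median(pairs$overlap_fraction)))

mk_tab <- function(ana) {
  st <- ana$stats[ana$stats$eye == "contra", ]
  tun <- ana$tuning
  resp_any <- tapply(ana$stats$responsive, ana$stats$id, any)
  pref <- function(id, col) {
    v <- tun[tun$id == id & tun$eye == "contra", col]
    if (length(v)) v[1] else NA_real_
  }
  data.frame(id = as.character(st$id),
             responsive = as.logical(resp_any[as.character(st$id)]),
             pref_ori = vapply(st$id, pref, numeric(1), "pref_ori"),
             pref_sf = vapply(st$id, pref, numeric(1), "pref_sf"),
             cx = pop$cx[match(st$id, pop$id)],
             cy = pop$cy[match(st$id, pop$id)])
}
t1 <- mk_tab(sim$analysis_t1)
t2 <- mk_tab(sim$analysis_t2)
reg <- tryCatch(stable_perimeter_region(pairs, t1, t2),
                error = function(e) NULL)
if (is.null(reg)) {
  cat("too few stable anchors; analyzing the full field\n")
  analyzed1 <- t1$id; analyzed2 <- t2$id
} else {
  cat(sprintf("stable perimeter: %d anchors, %d/%d neurons analyzed\n",
              nrow(reg$anchors), length(reg$analyzed_t1), nrow(t1)))
  jsonlite::write_json(list(hull = reg$hull,
                            anchors = reg$anchors$id_t1),
                       "results/stable_region.json", auto_unbox = TRUE,
                       digits = NA)
  analyzed1 <- reg$analyzed_t1; analyzed2 <- reg$analyzed_t2
}

cat1 <- setNames(sim$analysis_t1$od$category,
                 as.character(sim$analysis_t1$od$id))
cat2 <- setNames(sim$analysis_t2$od$category,
                 as.character(sim$analysis_t2$od$id))
tt <- transition_table(cat1, cat2, pairs, analyzed1, analyzed2)
cat("category transitions (rows P28, columns P32MD):\n")
print(tt$counts)
write.table(as.data.frame.matrix(tt$counts), "results/transitions.tsv",
            sep = "\t", quote = FALSE)
jsonlite::write_json(list(counts = tt$counts, n = tt$n),
                     "results/transitions.json", digits = NA)

odi1 <- mean(sim$analysis_t1$od$odi[cat1 %in% c("C", "B", "I")], na.rm = TRUE)
odi2 <- mean(sim$analysis_t2$od$odi[cat2 %in% c("C", "B", "I")], na.rm = TRUE)
cat(sprintf("tracked-cohort mean ODI: %.2f at P28 -> %.2f at P32MD\n",
            odi1, odi2))

st1 <- sim$analysis_t1$stats[sim$analysis_t1$stats$eye == "contra", ]
st2 <- sim$analysis_t2$stats[sim$analysis_t2$stats$eye == "contra", ]
st1$responsive <- as.logical(tapply(sim$analysis_t1$stats$responsive,
                                    sim$analysis_t1$stats$id,
                                    any)[as.character(st1$id)])
st2$responsive <- as.logical(tapply(sim$analysis_t2$stats$responsive,
                                    sim$analysis_t2$stats$id,
                                    any)[as.character(st2$id)])
em <- exchanged_mask_metrics(st1, st2, pairs)
write.table(em, "results/exchanged_mask_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
agg <- aggregate(snr_ratio ~ cohort, em[is.finite(em$snr_ratio), ], median)
cat("median SNR ratio (t2/t1) by cohort:\n")
print(agg)
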