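#!/usr/bin/env Rscript
# Compare low- vs high-burden model performance: best-of-two selection,
# subgrouping by which schema won, paired Wilcoxon signed-rank tests within
# each subgroup, cohort F1 summary. Writes comparison.json and, when
# ggplot2 is available, a per-person F1 dot-range plot.

library(ppgv)

ev <- read.csv("results/evaluation.csv")
ids <- unique(ev$participant_id)
pairs <- data.frame(
  participant_id = ids,
  f1_low = ev$f1[match(paste(ids, "low_burden"),
                       paste(ev$participant_id, ev$schema))],
  f1_high = ev$f1[match(paste(ids, "high_burden"),
                        paste(ev$participant_id, ev$schema))])
cm <- subgroup_and_test(pairs)

jsonlite::write_json(
  list(subgroup_sizes = cm$subgroup_sizes, tests = cm$tests,
       best_f1_summary = cm$best_f1_summary, caveat = cm$caveat),
  "results/comparison.json", auto_unbox = TRUE, digits = NA, na = "null")

sz <- cm$subgroup_sizes
message(sprintf("low better: %d (%.1f%%), high better: %d (%.1f%%), tie: %d, incomparable: %d",
                sz$low_better, 100 * sz$low_better / nrow(pairs),
                sz$high_better, 100 * sz$high_better / nrow(pairs),
                sz$tie, sz$incomparable))
for (sg in names(cm$tests)) {
  t <- cm$tests[[sg]]
  message(sprintf("%s (n=%d): median low %.3f vs high %.3f, Z=%.2f, p=%.2g",
                  sg, t$n, t$median_low, t$median_high, t$z, t$p))
}
s <- cm$best_f1_summary
message(sprintf("best F1: mean %.2f%%, median %.2f%%, SD %.2f%% (n=%d defined)",
                100 * s$mean, 100 * s$median, 100 * s$sd, s$n))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- cm$pairs[!is.na(cm$pairs$best_f1), ]
  long$med <- apply(long[, c("f1_low", "f1_high")], 1, median, na.rm = TRUE)
  long$lo <- pmin(long$f1_low, long$f1_high, na.rm = TRUE)
  long$hi <- pmax(long$f1_low, long$f1_high, na.rm = TRUE)
  long$participant_id <- reorder(long$participant_id, long$med)
  p <- ggplot(long, aes(x = med, y = participant_id)) +
    geom_linerange(aes(xmin = lo, xmax = hi), colour = "grey60") +
    geom_point(size = 1.2) +
    geom_vline(xintercept = median(long$med), linetype = "dashed") +
    labs(x = "within-person F1 (median and range across schemas)",
         y = NULL) +
    theme_minimal(base_size = 9)
  ggsave("results/f1_by_person.pdf", p, width = 5, height = 7)
}
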