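#!/usr/bin/env Rscript
# Vulnerability profiles: per-individual normalized percent importance
# (gain-based, with mean-|SHAP| alongside) from each participant's best
# model, aggregated to feature categories; cohort heterogeneity per
# best-model subgroup; optional stacked-bar figure for a subsample.

library(ppgv)

fits <- readRDS("results/fits.rds")
ev <- read.csv("results/evaluation.csv")
ids <- unique(ev$participant_id)
pairs <- data.frame(
  participant_id = ids,
  f1_low = ev$f1[match(paste(ids, "low_burden"),
                       paste(ev$participant_id, ev$schema))],
  f1_high = ev$f1[match(paste(ids, "high_burden"),
                        paste(ev$participant_id, ev$schema))])
cm <- subgroup_and_test(pairs)

profiles <- list(); shap <- list()
for (i in seq_len(nrow(cm$pairs))) {
  row <- cm$pairs[i, ]
  if (row$best_schema == "incomparable") next
  schema <- if (row$best_schema == "tie") "low_burden" else row$best_schema
  ft <- fits[[paste(row$participant_id, schema, sep = ".")]]
  profiles[[row$participant_id]] <- gain_profile(ft)
  shap[[row$participant_id]] <- shap_profile(ft)
}

rows <- list()
for (id in names(profiles)) {
  for (method in c("gain", "shap")) {
    p <- if (method == "gain") profiles[[id]] else shap[[id]]
    rows[[paste(id, method)]] <- data.frame(
      participant_id = id, best_schema = p$best_schema, method = method,
      category = names(p$per_category_pct),
      pct = as.numeric(p$per_category_pct))
  }
}
write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
          "results/profiles.csv", row.names = FALSE)

het_rows <- list()
for (sg in c("low_better", "high_better")) {
  ids_sg <- intersect(cm$pairs$participant_id[cm$pairs$subgroup == sg],
                      names(profiles))
  if (!length(ids_sg)) next
  het <- cohort_heterogeneity(profiles[ids_sg])
  message(sprintf("%s (n=%d): top categories %s; duplicate rankings: %d",
                  sg, length(ids_sg), paste(het$top5, collapse = ", "),
                  nrow(het$duplicate_rankings)))
  t <- het$table; t$subgroup <- sg
  het_rows[[sg]] <- t
}
write.csv(do.call(rbind, c(het_rows, make.row.names = FALSE)),
          "results/heterogeneity.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  set.seed(1)  # plot subsample only; analysis outputs are unaffected
  show <- sample(names(profiles), min(12, length(profiles)))
  df <- do.call(rbind, lapply(show, function(id) {
    p <- profiles[[id]]
    data.frame(participant_id = id, category = names(p$per_category_pct),
               pct = as.numeric(p$per_category_pct))
  }))
  g <- ggplot(df, aes(x = participant_id, y = pct, fill = category)) +
    geom_col() +
    labs(y = "% of total feature importance", x = NULL, fill = NULL) +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  ggsave("results/vulnerability_profiles.pdf", g, width = 8, height = 4.5)
}
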