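#!/usr/bin/env Rscript
# Cross-validated model selection on the training cohort: every relative
# feature alone and in pairs per segmentation method (29 candidates),
# 5-fold x 50-repeat stratified CV, corrected resampled t-test CIs, and the
# Youden / natural-scale threshold of the single-feature whole-slab rWIR
# model.

library(osteodce)

train <- read_cohort_csv("results/cohort_train.csv")
grid <- candidate_model_grid()
cv_results <- lapply(seq_along(grid), function(i) {
  cross_validate(train, grid[[i]], seed = 500 + i)
})

tab <- do.call(rbind, lapply(cv_results, function(r) {
  data.frame(method = r$spec$method,
             features = paste(r$spec$features, collapse = "+"),
             auc = r$means[["auc"]],
             auc_lo = r$cis$auc[1], auc_hi = r$cis$auc[2],
             accuracy = r$means[["accuracy"]])
}))
tab <- tab[order(-tab$auc), ]
write.csv(tab, "results/model_selection.csv", row.names = FALSE)
cat("top five candidates by mean cross-validated AUC:\n")
print(head(tab, 5), digits = 3, row.names = FALSE)

best <- select_model(cv_results)
cat(sprintf("\nselected model: %s\n", format(best)))

rwir <- finalize_model(train, model_spec("whole_slab", "r_wir"))
cv_rwir <- cv_results[[which(tab$method == "whole_slab" &
                               tab$features == "r_wir")[1]]]
thr <- rwir$natural_threshold
cat(sprintf("whole-slab rWIR model: probability threshold %.3f (Youden J %.2f)\n",
            rwir$prob_threshold, rwir$youden_j))
cat(sprintf("natural-scale threshold: rWIR < %.2f predicts poor response\n",
            thr$threshold))
cat(sprintf("i.e. a WIR decrease of less than %.0f%% over therapy\n",
            ratio_to_percent_decrease(thr$threshold)))

model_json <- list(
  method = "whole_slab", features = "r_wir",
  intercept = rwir$intercept, slopes = unname(rwir$slopes),
  norm_mean = unname(rwir$normalizer$mean), norm_sd = unname(rwir$normalizer$sd),
  prob_threshold = rwir$prob_threshold,
  rwir_threshold = thr$threshold, direction = thr$direction
)
jsonlite::write_json(model_json, "results/final_model.json",
                     auto_unbox = TRUE, digits = NA)
cat("frozen model written to results/final_model.json\n")
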