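#!/usr/bin/env Rscript
# Descriptive statistics of the training cohort: good-vs-poor comparison of
# every relative feature (Kruskal-Wallis) and an interobserver-agreement
# demonstration on synthetic second-observer ratings (the generator yields
# one measurement per patient, so observer B is emulated by adding
# independent measurement noise; the ICC here characterizes that synthetic
# noise level, not published interobserver variability).

library(osteodce)

train <- read_cohort_csv("results/cohort_train.csv")
feats <- c("r_wir_ws", "r_mre_ws", "r_auc_ws", "delta_tte_ws",
           "r_wir_fa", "r_mre_fa", "r_auc_fa", "delta_tte_fa", "r_volume")

rows <- lapply(feats, function(f) {
  kw <- kruskal_wallis(split(train[[f]], train$response))
  # synthetic observer B: 10% multiplicative measurement noise on the
  # log scale (signed-log scale for the TTE difference)
  x <- train[[f]]
  noise <- withr::with_seed(900 + match(f, feats), rnorm(length(x), sd = 0.1))
  b <- if (startsWith(f, "delta_tte")) signed_exp(signed_log(x) + noise)
       else exp(log(x) + noise)
  icc <- icc_absolute_agreement(x, b)
  data.frame(feature = f,
             median_good = median(x[train$response == "good"]),
             median_poor = median(x[train$response == "poor"]),
             kw_H = kw$H, kw_p = kw$p,
             icc_synthetic = icc$icc,
             icc_lo = icc$ci_lo, icc_hi = icc$ci_hi)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/cohort_stats.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
cat("\nall features separate the response classes (small Kruskal-Wallis p),\n")
cat("with good responders showing larger relative decreases, as constructed\n")
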