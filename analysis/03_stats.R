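#!/usr/bin/env Rscript
# Step 3: statistical layer over the per-trial metrics.
#
# Repeated-measures ANOVAs (per-subject cell means; df = (k-1, (k-1)(m-1)))
# for response time, object-fixation count, head path and fixation ratio
# across complexity, start position, orientation difference, sameness and the
# 6-block learning factor; binomial mixed model (logit link, subject random
# intercept) for accuracy. Normalized response time per block element is
# reported per complexity level.

library(activegaze)

metrics <- read.csv("results/trial_metrics.csv")
stats <- run_stats(metrics)

jsonlite::write_json(lapply(stats, function(x) { attr(x, "model") <- NULL; x }),
                     "results/stats.json", auto_unbox = TRUE, digits = NA,
                     dataframe = "rows")

for (dv in names(stats)) {
  cat("\n==", dv, "==\n")
  tab <- stats[[dv]]
  for (i in seq_len(nrow(tab))) {
    df_str <- if (is.na(tab$df_den[i])) sprintf("df=%s", tab$df_num[i])
              else sprintf("df=(%d,%d)", tab$df_num[i], tab$df_den[i])
    cat(sprintf("  %-22s stat=%8.3f %-12s p=%.4f%s %s\n", tab$effect[i],
                tab$statistic[i], df_str, tab$p_value[i],
                ifelse(isTRUE(tab$significant[i]), " *", ""),
                ifelse(nzchar(tab$note[i]), paste0("[", tab$note[i], "]"), "")))
  }
}

cat("\nNormalized response time (s per block element):\n")
blocks <- c(C_e = 7, C_m = 10, C_h = 18)
for (cx in names(blocks)) {
  rt <- mean(metrics$response_time_s[metrics$complexity == cx])
  cat(sprintf("  %s: mean RT %.2f s / %d blocks = %.2f s\n", cx, rt, blocks[[cx]],
              normalized_response_time(rt, blocks[[cx]])))
}
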