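#!/usr/bin/env Rscript
# Stage 3: extended analysis on the full cohort with the dense metric.
#
# The dense product covers every residence, so no birth is excluded; the
# structured weekly model is fit to all 10,000 births and the identified
# susceptible window is reported, together with a per-week plot of
# posterior medians and 95% credible intervals.

library(critwin)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/extended_fit"

res <- run_pipeline(generator_config(n_births = 10000, seed = seed),
                    out_dir = out, metrics = "dense", models = 1,
                    mcmc = mcmc_config(profile = "test", seed = seed + 101L))

s <- res$summaries[["dense.weekly_structured"]]
w <- res$windows[["dense.weekly_structured"]]
message("average 95% interval width: ", round(attr(s, "avg_width"), 4))
if (nrow(w)) {
  message("identified windows: ",
          paste(sprintf("weeks %d-%d (sign %+d)", w$start_week, w$end_week,
                        w$sign), collapse = "; "))
} else message("no significant window identified")

dir.create(file.path(out, "figures"), showWarnings = FALSE)
pdf(file.path(out, "figures", "weekly_effects.pdf"), width = 7, height = 4.5)
plot_windows(s, main = "Weekly ozone effects, dense metric (full cohort)")
dev.off()
message("outputs written under ", out)
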