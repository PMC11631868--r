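#!/usr/bin/env Rscript
# Stage 5: behavioral statistics.
#
# One-way ANOVA across the four dose groups for every open-field and
# tail-flick measure, and the one-sample chance test (IR vs 0.5) per
# group for the novel-object task.

suppressPackageStartupMessages(library(phmrikit))

inp <- "results/synth"
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_table(file.path(inp, "behavior_table.csv"),
                  required = c("subject", "group", "measure", "value"),
                  numeric = "value")
res <- behavior_stats(tab)
write_table(res$anova, file.path(out, "anova.csv"))
write_table(res$ir_chance, file.path(out, "ir_vs_chance.csv"))

for (i in seq_len(nrow(res$anova)))
  cat(sprintf("%-12s F(%d, %d) = %6.2f, p = %.4g\n",
              res$anova$measure[i], res$anova$df1[i], res$anova$df2[i],
              res$anova$F[i], res$anova$p[i]))
cat("IR vs chance (0.5):\n")
for (i in seq_len(nrow(res$ir_chance)))
  cat(sprintf("  %-8s mean IR %.2f, t(%d) = %5.2f, p = %.3g\n",
              res$ir_chance$group[i], res$ir_chance$mean_ir[i],
              res$ir_chance$df[i], res$ir_chance$t[i], res$ir_chance$p[i]))

# post-hoc on distance if the omnibus fires
d <- tab[tab$measure == "distance", ]
ph <- dose_anova_lsd(d$value, d$group)
if (!is.null(ph$pairwise)) {
  write_table(ph$pairwise, file.path(out, "distance_lsd.csv"))
  sig <- ph$pairwise[ph$pairwise$p < 0.05, ]
  cat(sprintf("distance post-hoc: %d/%d pairs significant\n",
              nrow(sig), nrow(ph$pairwise)))
}

write_manifest(file.path(out, "manifest.json"), run_config(), 20260101L,
               extra = list(stage = "behavior"))
cat("stage 5 complete; stats under", out, "\n")
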