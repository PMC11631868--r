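#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emulates a four-dose awake-rat session: 250 BOLD acquisitions (TR 6 s)
# per subject on a 24 x 24 x 8 atlas grid with an inverse dose-response
# deactivation planted in one region, block-structured resting-state
# series per subject, a lipid panel with a 50-fold plasma effect and
# CNS decreases, and an open-field/NOR/tail-flick behavior table.

suppressPackageStartupMessages(library(phmrikit))

seed <- 20260101L
out <- "results/synth"
dir.create(file.path(out, "bold"), recursive = TRUE, showWarnings = FALSE)

## atlas ----------------------------------------------------------------------
atlas <- synth_atlas(dim = c(24, 24, 8), n_regions = 6)
write_nifti(atlas$labels, file.path(out, "atlas_labels.nii.gz"))
write_table(atlas$regions, file.path(out, "atlas_regions.csv"))

## BOLD: inverse dose-response deactivation in region 2, mild positive
## response in region 5 -------------------------------------------------------
design <- bold_design(seed = seed)           # groups n = 4/4/6/5
effects <- list(
  region_effect_spec(2, c(`3mg` = -3, `10mg` = -2.5, `30mg` = -1.5),
                     responder_fraction = 0.6),
  region_effect_spec(5, c(`3mg` = 1.6, `10mg` = 1.4, `30mg` = 1.2),
                     responder_fraction = 0.4))
sim <- generate_bold(design, atlas, effects, noise_sd = 0.5)
for (s in sim$subjects)
  write_nifti(s, file.path(out, "bold", paste0(s$subject, ".nii.gz")))
write_table(sim$truth, file.path(out, "bold_truth.csv"))
write_table(design$groups, file.path(out, "bold_groups.csv"))
cat(sprintf("BOLD: %d subjects, %d planted effects\n",
            length(sim$subjects), length(effects)))

## resting state: two 8-node blocks per subject; the 30 mg/kg group gets a
## global correlation increase ------------------------------------------------
rest_groups <- list(vehicle = list(within = 0.5, between = 0.05, n = 6),
                    `30mg` = list(within = 0.75, between = 0.35, n = 6))
i <- 0L
for (g in names(rest_groups)) {
  gp <- rest_groups[[g]]
  for (s in seq_len(gp$n)) {
    i <- i + 1L
    spec <- network_spec(16, rep(1:2, each = 8), gp$within, gp$between,
                         series_length = 150, seed = seed + i)
    rs <- generate_restingstate(spec)
    df <- data.frame(node = rownames(rs$series), block = rs$blocks,
                     rs$series, check.names = FALSE)
    write_table(df, file.path(out, sprintf("rest_%s_s%02d.csv", g, s)))
  }
}
cat(sprintf("resting state: %d subjects in %d groups\n",
            i, length(rest_groups)))

## lipid panel: plasma surge, CNS-wide AEA decrease, moderate 2-AG
## increase, one undetectable analyte ----------------------------------------
cns <- c("HYP", "CER", "STR", "THAL", "CTX", "HIPP")
specs <- c(
  list(lipid_effect_spec("PEA", "plasma", c(vehicle = 1, `30mg` = 50),
                         cv = 0.3)),
  lapply(cns, function(cp) lipid_effect_spec("PEA", cp,
        c(vehicle = 2, `30mg` = 5), cv = 0.4)),
  lapply(cns, function(cp) lipid_effect_spec("AEA", cp,
        c(vehicle = 4, `30mg` = 1.6), cv = 0.25)),
  lapply(cns, function(cp) lipid_effect_spec("2-AG", cp,
        c(vehicle = 10, `30mg` = 13), cv = 0.15)),
  list(lipid_effect_spec("ghost", "STR", c(vehicle = 1, `30mg` = 1),
                         cv = 0.2, p_below_detection = 1)))
lip <- generate_lipid_table(specs, n_per_group = 5, seed = seed + 100L)
write_table(lip$table, file.path(out, "lipid_table.csv"))
write_table(lip$truth, file.path(out, "lipid_truth.csv"))
cat(sprintf("lipids: %d records, %d analyte x compartment cells\n",
            nrow(lip$table), nrow(lip$truth)))

## behavior -------------------------------------------------------------------
beh <- generate_behavior_table(n_per_group = 6, seed = seed + 200L)
write_table(beh$table, file.path(out, "behavior_table.csv"))
write_table(beh$truth, file.path(out, "behavior_truth.csv"))

write_manifest(file.path(out, "manifest.json"), run_config(), seed,
               extra = list(stage = "simulate"))
cat("stage 1 complete; inputs under", out, "\n")
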