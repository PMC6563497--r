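#!/usr/bin/env Rscript
# Inter-rater reliability on the simulated operators' lesion masks: Dice
# overlap per patient, ICC(3,1) over extracted lesion volumes, and the
# conservativeness contrast (rater 2 is configured to erode more).

# run from the repository root: Rscript analysis/07_reliability.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "07_reliability")
dir.create(out, showWarnings = FALSE)

res <- get_run()
rc <- res$reliability

write.table(rc$per_patient, file.path(out, "rater_agreement.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

say("Dice overlap: %.2f +/- %.2f over %d patients",
    rc$mean_dice, rc$sd_dice, nrow(rc$per_patient))
say("lesion-volume ICC(3,1) = %.2f (F = %.1f, p = %.2g)",
    rc$icc$icc, rc$icc$f, rc$icc$p)
say("conservativeness: mean volume difference %.2f cm3 (t = %.1f, p = %.2g) -> %s",
    rc$conservativeness$mean_diff, rc$conservativeness$t,
    rc$conservativeness$p, rc$conservativeness$direction)
say("wrote %s", out)
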