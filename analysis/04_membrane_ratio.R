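#!/usr/bin/env Rscript
# Sperm plasma membrane breakdown: the volume of membrane signal touching
# the axoneme, divided by the axoneme volume, in 20 control scenes
# (membrane tube 15% filled, i.e. mostly cleared) vs 20 knockdown-like
# scenes (70% filled, clearance blocked). Compared with the two-tailed
# pooled t test, as in the original assay.
#
# Finds: the knockdown condition retains several times more membrane per
# unit axoneme, with an overwhelming group difference.

suppressPackageStartupMessages(library(pmequant))
dir.create("results", showWarnings = FALSE)
seed <- 1L

ratio_scene <- function(s, fill) {
  p <- scene3d_params(seed = s, shape = c(32, 96, 96), n_puncta = 0,
                      membrane_fill_fraction = fill)
  sc <- make_axoneme_volume_3d(p)
  membrane_axoneme_ratio(
    label_and_filter(get_channel(sc$stack, "membrane") > 1600, p$spacing),
    get_channel(sc$stack, "axoneme") > 1600, p$spacing)$ratio
}
ctl <- vapply(seq_len(20), function(i) ratio_scene(seed + 820L + i, 0.15), 0)
kd <- vapply(seq_len(20), function(i) ratio_scene(seed + 920L + i, 0.70), 0)

tt <- t_test_unpaired(ctl, kd)
cat(sprintf("membrane/axoneme ratio: control %.3f vs knockdown %.3f, t = %.2f, p = %.3g\n",
            mean(ctl), mean(kd), tt$t, tt$p))
utils::write.csv(data.frame(group = rep(c("control", "knockdown"), each = 20),
                            ratio = c(ctl, kd)),
                 "results/membrane_ratio.csv", row.names = FALSE)
cat("wrote results/membrane_ratio.csv\n")
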