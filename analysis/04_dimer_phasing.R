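#!/usr/bin/env Rscript
# Stage 4: dimeric motif spacing and helical phasing.
#
# Takes the forward-forward dimer spacing series, fits the DNA
# torsional-elasticity phasing model by multi-start nonlinear least
# squares, and reports the fitted helical repeat together with the
# per-spacing phase and helix-face projection.

suppressMessages(library(snapspec))

probes <- read_probe_table("results/probes.tsv")
norm <- read.delim("results/normalized_intensities.tsv")
probes$intensity <- norm$normalized[match(probes$probe_id, norm$probe_id)]
dim_ff <- probes[probes$probe_class == "dimer_spacing" &
                   probes$orientation == "FF", ]
dim_ff <- dim_ff[order(dim_ff$spacing), ]

fit <- fit_phasing(dim_ff$spacing, dim_ff$intensity)
print(fit)

pred <- fit$predicted
pred$helix_angle <- helix_projection(pred$spacing)
write.table(as.data.frame(pred), "results/phasing_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
p <- fit$params
report <- data.frame(parameter = c("h_r", "K_min", "s_min", "C_app",
                                   "sigma_bp", "residual_sum", "converged"),
                     value = c(p$h_r, p$K_min, p$s_min, p$C_app,
                               sigma_bp(p), fit$residual_sum,
                               as.numeric(fit$converged)))
write.table(report, "results/phasing_fit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(lapply(split(report$value, report$parameter), identity),
                     "results/phasing_fit.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("\nFitted helical periodicity: %.2f bp per oscillation\n", p$h_r))
cat("Spacings in phase with the binding optimum sit on the same helical face;\n")
cat("half-period spacings fall on the opposite face (see helix_angle column).\n")
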