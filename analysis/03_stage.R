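#!/usr/bin/env Rscript
# Stage every cell on the differentiation axis: asinh-transform the raw
# CD71/Ter119 intensities, project onto the curve family, bin into
# DS1-DS6, compare recovered positions against the generator's ground
# truth, and demonstrate axis alignment by cell-size fluctuations.

suppressPackageStartupMessages(library(burststage))
truth <- read.csv("results/ground_truth.csv", stringsAsFactors = FALSE)

staged <- stage_cells(truth[, c("cell_id", "cd71", "ter119")])
write.csv(staged, "results/staged_cells.csv", row.names = FALSE)

rho <- cor(truth$true_position, staged$position, method = "spearman")
cat(sprintf("staged %d cells; Spearman(true, recovered position) = %.3f\n",
            nrow(staged), rho))
print(table(staged$stage))

# align a copy of this dataset whose axis is displaced by +0.08, as when
# matching a FACS-sorted dataset to the time-lapse axis
ref <- data.frame(position = truth$true_position, size = truth$cell_size)
qry <- data.frame(position = pmin(pmax(truth$true_position + 0.08, 0), 1),
                  size = truth$cell_size)
al <- align_axes(ref, qry)
cat(sprintf("axis alignment recovered shift %.3f (profile correlation %.2f)\n",
            al$shift, al$correlation))
cat("wrote results/staged_cells.csv\n")
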