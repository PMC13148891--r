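#!/usr/bin/env Rscript
# Step 3: batch standardization. Uses the quantified sgRNA titers to adjust
# the input volume of preps 2 and 3 so each delivers the same number of
# sgRNA copies as 1 uL of prep 1 — the copy-matched normalization strategy.
# The same adjustment applies unchanged to RLU/uL metrics from the lytic
# HiBiT assay.

suppressMessages(library(evlptiter))

titers <- read.csv("results/titers.csv")
test <- titers[titers$role == "test", ]

metrics <- data.frame(prep = test$prep, kind = "sgRNA_copies_per_ul",
                      value = test$copies_per_ul_prep, dilution = 1)
adj <- adjust_doses(metrics, reference = metrics$prep[1], ref_volume = 1,
                    max_volume = 20)
print(adj)

doses <- adj$doses
doses$volume_ul_pipettable <- round(doses$volume_ul, 2)
write.csv(doses, "results/doses.csv", row.names = FALSE)

amounts <- delivered_amount(adj)
cat(sprintf("\nDelivered sgRNA copies per dose: %s\n",
            paste(format(amounts$delivered, digits = 4), collapse = ", ")))
cat("Equal across uncapped preps by construction.\n")
cat("Wrote results/doses.csv\n")
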