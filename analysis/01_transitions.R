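#!/usr/bin/env Rscript
# MRM transition design for the DMED/d4-DMED labeled FAHFA panel.
#
# Builds the light/heavy transition table for all 72 panel isomers across
# the three product channels (loss of FA; FA + dimethylamine; FA +
# dimethylamine + water, the 63/67 Da screening channel) and checks the
# OAHSA worked example against its unit-resolution instrument channels.

library(cilFAHFA)

dir.create("results", showWarnings = FALSE)

tr <- panel_transitions(fahfa_panel(), nominal = TRUE)
write_transition_table(tr, "results/transitions.tsv")

oahsa <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE), 9)
ex <- build_transitions(oahsa, tags = "DMED")
cat(sprintf("transition table: %d rows over %d species -> results/transitions.tsv\n",
            nrow(tr), nrow(fahfa_panel())))
cat(sprintf("OAHSA example: precursor %.4f; products %s\n",
            ex$precursor_mz[1],
            paste(sprintf("%.4f (%s)", ex$product_mz, ex$channel_kind),
                  collapse = ", ")))
cat(sprintf("printed channels 635.5 > 353.5 / 308.5 match within 0.3 Da: %s\n",
            all(matches_printed_channel(ex$precursor_mz[1], 635.5),
                matches_printed_channel(
                  ex$product_mz[ex$channel_kind == "LOSS_FA"], 353.5),
                matches_printed_channel(
                  ex$product_mz[ex$channel_kind == "LOSS_FA_45"], 308.5))))
light <- label_tag("DMED"); heavy <- label_tag("d4-DMED")
cat(sprintf("combined neutral losses: %.4f (light, nominal %d) / %.4f (heavy, nominal %d)\n",
            light$combined_neutral_loss, round(light$combined_neutral_loss),
            heavy$combined_neutral_loss, round(heavy$combined_neutral_loss)))
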