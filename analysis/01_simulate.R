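#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a six-tissue normal reference
# panel, a paired colon-to-liver tumor cohort (primaries mixed 15% toward
# the target tissue, metastases 45%), 20 hallmark-sized gene sets of
# which 3 carry a planted shift (alpha = 0.9), written as a file bundle
# that the later drivers consume.

library(tdratio)

cfg <- simulation_config(seed = 1206)
bundle <- write_fixture_bundle(cfg, "scratch/fixture", n_sets = 20,
                               n_planted = 3, alpha_planted = 0.9)
truth <- yaml::read_yaml(bundle$ground_truth)
message("wrote fixture bundle under scratch/fixture/")
message("cohort: ", truth$ot, " -> ", truth$tt,
        "; alpha primary/met = ", truth$alpha_primary, "/", truth$alpha_met)
message("planted pathways: ", paste(unlist(truth$planted_pathways), collapse = ", "))
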