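#!/usr/bin/env Rscript
# Lipari-Szabo model-free closed loop on synthetic backbone 15N relaxation:
# rigid beta-sheet-like residues versus a flexible 517-522-like segment.
# Fits S2 and tau_e per residue with a shared overall correlation time and
# writes the recovered parameters next to the truth.

suppressMessages(library(ringflipr))
dir.create("results", showWarnings = FALSE)

motion <- data.frame(
  residue = sprintf("R%03d", c(505, 508, 512, 518, 519, 520, 524, 528)),
  s2 = c(0.88, 0.90, 0.86, 0.55, 0.50, 0.58, 0.84, 0.87),
  tau_e_ps = c(20, 30, 25, 200, 300, 250, 40, 30))
rs <- make_relaxation_set(motion, tau_c_ns = 5, fields = 600,
                          noise = 0.02, seed = 21)
utils::write.csv(rs, "results/relaxation_synthetic.csv", row.names = FALSE)

mf <- fit_modelfree(rs)
out <- merge(motion, mf, by = "residue", suffixes = c("_true", "_fit"))
utils::write.csv(out, "results/modelfree_fit.csv", row.names = FALSE)
message(sprintf("shared tau_c: %.2f ns (truth 5.00)", attr(mf, "tau_c_ns")))
message(sprintf("max |S2 error|: %.3f", max(abs(out$s2_true - out$s2_fit))))
flex <- out$s2_true < 0.6
message(sprintf(
  "flexible segment mean S2: %.2f fitted vs %.2f true; rigid: %.2f vs %.2f",
  mean(out$s2_fit[flex]), mean(out$s2_true[flex]),
  mean(out$s2_fit[!flex]), mean(out$s2_true[!flex])))
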