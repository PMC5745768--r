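#!/usr/bin/env Rscript
# Strain simulation: one noise-free template exemplar per category (running
# angles 25/35/45/55 degrees, plus a crossing two-bundle CFL2), swept over
# the 6 x 3 pose grid.  Writes results/exemplar_strain_tables.csv and
# results/sign_patterns.csv.

library(cflsim)

message("strain sweep: template exemplars at 25/35/45/55 deg + CFL2(30/60), ",
        "pose grid PF30..DF20 x EV20/neutral/INV20")
dir.create("results", showWarnings = FALSE)

tpl <- make_template_ankle()
tables <- lapply(c(CFL20 = 25, CFL30 = 35, CFL40 = 45, CFL50 = 55),
                 function(th) sweep_grid(ankle_model(make_cfl_at_angle(tpl, th))))
tables$CFL2 <- sweep_grid(ankle_model(make_two_bundle_cfl(tpl, 30, 60)))

out <- write_strain_table(tables, "results/exemplar_strain_tables.csv")
message("per-category strain table (neutral frontal, % strain):")
for (i in seq_len(nrow(out))) {
  message(sprintf("  %-12s %6.1f %6.1f %6.1f %6.1f %6.1f %6.1f", out$row[i],
                  out$PF30[i], out$PF20[i], out$PF10[i], out$N0[i],
                  out$DF10[i], out$DF20[i]))
}

pats <- t(vapply(tables, function(t) unlist(sign_pattern(t)), c(sagittal = "", frontal = "")))
write.csv(data.frame(category = rownames(pats), pats, row.names = NULL),
          "results/sign_patterns.csv", row.names = FALSE)
message("sagittal behaviour by running angle:")
for (i in seq_len(nrow(pats))) {
  message("  ", rownames(pats)[i], ": ", pats[i, "sagittal"])
}
if (pats["CFL20", "sagittal"] != pats["CFL50", "sagittal"]) {
  message("low-angle ligaments contract in plantarflexion and stretch in ",
          "dorsiflexion; high-angle ligaments show the reverse -- the ",
          "functional transition lies between 25 and 55 degrees")
}
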