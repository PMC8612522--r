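#!/usr/bin/env Rscript
# Simulate the study's synthetic raw data with known ground truth:
# birthdating section images (TIFF + truth CSV), a progenitor count matrix
# (MatrixMarket), and flow-cytometry event tables (CSV). Everything
# downstream (02-06) consumes these files or regenerates deterministically
# from the same seeds.

suppressMessages(library(tempocode))
seed <- 20260926L
out <- "results/data"
dir.create(file.path(out, "sections"), recursive = TRUE,
           showWarnings = FALSE)

program <- temporal_program()
print(program)

## Section images: EdU pulses e9.5-e12.5, collected at e13.5, for the
## intermediate (Zfhx3) and late (Nfib) temporal TFs, 2 sections each.
k <- 0L
manifest <- list()
for (tf in c("Zfhx3", "Nfib")) for (pulse in c(9.5, 10.5, 11.5, 12.5)) {
  for (rep in 1:2) {
    k <- k + 1L
    s <- derive_seed(seed, k)
    sec <- generate_section(section_spec(edu_pulse_day = pulse,
                                         tf_channel = tf), program, seed = s)
    stem <- sprintf("section_%s_e%.1f_rep%d", tf, pulse, rep)
    write_section(sec, file.path(out, "sections",
                                 paste0(stem, ".tiff")), seed = s)
    write.csv(sec$truth, file.path(out, "sections",
                                   paste0(stem, "_truth.csv")),
              row.names = FALSE)
    manifest[[k]] <- data.frame(file = paste0(stem, ".tiff"), tf = tf,
                                edu_pulse_day = pulse, rep = rep, seed = s)
  }
}
write.csv(do.call(rbind, manifest),
          file.path(out, "sections", "manifest.csv"), row.names = FALSE)
message(k, " sections written")

## Progenitor count matrix with 15 planted temporal genes in 9/10 domains
cm <- generate_counts(counts_spec(), seed = derive_seed(seed, 900L))
write_counts(cm, file.path(out, "counts"))
write.csv(cm$planted, file.path(out, "counts", "planted_truth.csv"),
          row.names = FALSE)
message("counts: ", nrow(cm$counts), " genes x ", ncol(cm$counts),
        " cells; ", nrow(cm$planted), " planted temporal genes")

## Flow samples: three replicates each for an early marker in young
## cultures (low positive fraction) and late cultures (high fraction)
for (cond in c("young", "old")) {
  f <- if (cond == "young") 0.15 else 0.6
  for (rep in 1:3) {
    ev <- generate_flow_events(
      flow_spec(marker_positive_fraction_neurons = f),
      seed = derive_seed(seed, 950L + 10L * (cond == "old") + rep))
    write.csv(ev, file.path(out, sprintf("flow_%s_rep%d.csv", cond, rep)),
              row.names = FALSE)
  }
}
message("flow event tables written under ", out)
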