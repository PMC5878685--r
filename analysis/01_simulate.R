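#!/usr/bin/env Rscript
# Build the toy mating-type references and simulate the sonicated,
# end-blunted libraries; export references, a small SAM sample and the
# strand-specific 5'-count profiles.

source(file.path("analysis", "00_settings.R"))
out <- res_dir("simulate")

for (variant in c("M_donorless", "P_donorless", "nick_free", "h90_M")) {
  g <- build_mat_region(variant, flank_len = SETTINGS$flank_len)
  write_genome(g, file.path(out, variant))
  cat(sprintf("%-12s %6d bp, nick at %s\n", variant, g$length,
              if (nrow(g$nick_sites)) g$nick_sites$pos else "none"))
}

run <- m_library()
g <- run$genome
nick <- g$nick_sites$pos
cat(sprintf("\nM library: %d reads from %d molecules (%.0f%% imprinted)\n",
            nrow(run$reads), SETTINGS$n_molecules,
            100 * SETTINGS$imprint_fraction))
cat(sprintf("Watson 5' count at the nick (%d): %d  (background mean %.1f)\n",
            nick, run$profile$watson[nick],
            mean(run$profile$watson[-nick])))

write_profile(run$profile, file.path(out, "M_donorless"))
# small coordinate-sorted SAM sample for interoperability checks / display
sam_sample <- run$reads[sample.int(nrow(run$reads), 5000), ]
write_sam(sam_sample, g, file.path(out, "M_donorless.sample.sam"))

cat("\nwrote", length(list.files(out)), "files to", out, "\n")
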