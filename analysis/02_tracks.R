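#!/usr/bin/env Rscript
# Binned RPKM tracks and the IP/WCE enrichment ratio: an IP-style library
# concentrated around the nick against a whole-cell-extract library.

source(file.path("analysis", "00_settings.R"))
out <- res_dir("tracks")

run <- m_library()
g <- run$genome
nick <- g$nick_sites$pos

# IP pulls down fragments near the nick-bound complex; WCE is the input
ip_reads <- filter_reads_to_region(run$reads, nick - 300, nick + 300)
wce <- m_library(seed = SETTINGS$seed_wce)$reads

bin <- 1000L
ip_track <- rpkm_track(ip_reads, g, bin)
wce_track <- rpkm_track(wce, g, bin)
ratio <- enrichment_track(ip_track, wce_track)

write_track_bedgraph(ip_track, file.path(out, "ip.rpkm.bedgraph"), g$length)
write_track_bedgraph(wce_track, file.path(out, "wce.rpkm.bedgraph"), g$length)
write_track_bedgraph(ratio, file.path(out, "ip_over_wce.bedgraph"), g$length)

peak_bin <- which.max(ratio$values)
cat(sprintf("IP library: %d reads (%.1f%% of the extract)\n", nrow(ip_reads),
            100 * nrow(ip_reads) / nrow(run$reads)))
cat(sprintf("max IP/WCE ratio %.1f in bin %d (%d-%d); nick at %d\n",
            ratio$values[peak_bin], peak_bin, (peak_bin - 1) * bin + 1,
            peak_bin * bin, nick))
stopifnot(nick > (peak_bin - 1) * bin, nick <= peak_bin * bin)
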