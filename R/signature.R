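# Genome-wide 5'-count screen and the nick caller.
#
# The sonication signature of a confined, persistent single-strand break is
# (i) a single-nucleotide 5'-count spike at the nick on the nicked strand and
# (ii) a short zone (roughly the weakened window, ~17-23 nt in practice) of
# preferential mechanical breakage on the opposite strand, detectable as a
# significant multi-nucleotide window facing the spike. Symmetric artifacts
# (collapsed repeats, mitochondrial homology) inflate BOTH strands alike,
# because every double-strand fragment carries one 5' end per strand; a nick
# concentrates its excess on one exact position of one strand, so the
# own/opposite count ratio separates the two classes at any sequencing depth.

#' Genome-wide screen for 5'-count-enriched positions and regions
#'
#' Positions on each strand with upper-tail p below `alpha / N` (Bonferroni
#' over the `N` scored positions of that strand) are reported, merged into
#' regions when closer than `merge_dist`, and each region is classified
#' `"symmetric"` (comparably enriched on both strands, the repeat-artifact
#' class) or `"strand_exclusive"` (own-strand summed count at least
#' `spike_ratio`-fold the opposite strand's over the region span).
#'
#' @param profile An unnormalized [compute_five_prime_counts()] profile.
#' @param model_w,model_c [fit_null()] models for the Watson and Crick
#'   strands (genome-wide fits).
#' @param alpha Family-wise error target before Bonferroni (default 0.05).
#' @param merge_dist Enriched positions closer than this are merged into one
#'   region (default 50 nt).
#' @param spike_ratio Own/opposite summed-count ratio (pseudocount 1) above
#'   which a region is strand-exclusive (default 5).
#' @return List of class `"genome_screen"` with elements `watson` and
#'   `crick`, each a list of `positions` (enriched coordinates) and `regions`
#'   (`data.frame`: `start`, `end`, `n_enriched`, `peak_pos`, `peak_count`,
#'   `own_sum`, `opp_sum`, `status`), plus `alpha` and `n_tests`.
#' @export
genome_screen <- function(profile, model_w, model_c, alpha = 0.05,
                          merge_dist = 50L, spike_ratio = 5) {
  if (profile$normalized) {
    stop("screen requires raw integer counts; the null models were fitted on raw counts")
  }
  n_tests <- profile$length
  thr <- -log10(alpha / n_tests)
  out <- list()
  for (s in c("watson", "crick")) {
    model <- if (s == "watson") model_w else model_c
    own <- profile[[s]]
    opp <- profile[[if (s == "watson") "crick" else "watson"]]
    nlp <- neglog10_pvalue_window(own, 1L, model)
    pos <- which(nlp > thr)
    if (length(pos) > 0) {
      merged <- IRanges::reduce(IRanges::IRanges(pos, pos),
                                min.gapwidth = merge_dist + 1L)
      rs <- BiocGenerics::start(merged)
      re <- BiocGenerics::end(merged)
      regions <- data.frame(start = rs, end = re,
                            n_enriched = IRanges::countOverlaps(
                              merged, IRanges::IRanges(pos, pos)))
      regions$peak_pos <- vapply(seq_len(nrow(regions)), function(i) {
        span <- rs[i]:re[i]
        span[which.max(own[span])]
      }, integer(1))
      regions$peak_count <- own[regions$peak_pos]
      regions$own_sum <- vapply(seq_len(nrow(regions)), function(i) {
        sum(own[rs[i]:re[i]])
      }, numeric(1))
      regions$opp_sum <- vapply(seq_len(nrow(regions)), function(i) {
        sum(opp[rs[i]:re[i]])
      }, numeric(1))
      regions$status <- ifelse(
        (regions$own_sum + 1) / (regions$opp_sum + 1) >= spike_ratio,
        "strand_exclusive", "symmetric")
    } else {
      regions <- data.frame(start = integer(), end = integer(),
                            n_enriched = integer(), peak_pos = integer(),
                            peak_count = numeric(), own_sum = numeric(),
                            opp_sum = numeric(), status = character())
    }
    out[[s]] <- list(positions = pos, regions = regions)
  }
  structure(c(out, list(alpha = alpha, n_tests = n_tests)),
            class = "genome_screen")
}

#' @export
print.genome_screen <- function(x, ...) {
  for (s in c("watson", "crick")) {
    r <- x[[s]]$regions
    cat(sprintf("%s: %d enriched position(s) in %d region(s) (%d strand-exclusive)\n",
                s, length(x[[s]]$positions), nrow(r),
                sum(r$status == "strand_exclusive")))
  }
  invisible(x)
}

#' Call persistent nicks from the sonication signature
#'
#' Candidate nicks are genome-screen-enriched positions whose own-strand
#' count dominates the opposite strand at that exact position
#' (`spike_ratio`-fold, pseudocount 1); candidates within `merge_dist` keep
#' only the highest-count position. Each candidate anchor is then confirmed
#' on the opposite strand: null models are re-fitted locally
#' (`fit_halfwidth` around the anchor, the analysis-region convention for
#' focused significance), the opposite strand is scanned (`+/- flank`,
#' sizes 1..`max_size`), and a nick is called when the best opposite window
#' has size in `[min_size, max_size]`, p below `alpha` Bonferroni-corrected
#' over the scan grid, and faces the anchor (overlaps the anchor +/- its own
#' size). The `min_size` floor rejects mirror anchors sitting inside the
#' weakened zone, whose "opposite" optimum is the size-1 spike itself.
#'
#' @param profile An unnormalized [compute_five_prime_counts()] profile.
#' @param models Optional list with elements `watson` and `crick`
#'   (genome-wide [fit_null()] models); fitted on the fly when `NULL`.
#' @param alpha Significance level for both the screen and the opposite-
#'   window gate (default 0.05, Bonferroni-corrected internally).
#' @param spike_ratio Own/opposite count dominance required of a spike
#'   (default 5).
#' @param min_size,max_size Accepted size range of the opposite-strand best
#'   window (defaults 2 and 40).
#' @param flank Half-width of the opposite-strand scan region (default
#'   1000 nt).
#' @param fit_halfwidth Half-width of the local null-fit region around the
#'   anchor (default 5000 nt, i.e. a 10-kb region).
#' @param merge_dist Candidate spikes closer than this collapse to the
#'   highest-count one (default 50 nt).
#' @return A `data.frame` of class `"nick_calls"`, one row per call, sorted
#'   by decreasing spike significance: `chrom`, `pos`, `nicked_strand`,
#'   `spike_count`, `single_p` (local-fit single-position p-value),
#'   `spike_neglog10p`, `opp_window_start`, `opp_window_size`,
#'   `opp_window_sum`, `opp_window_neglog10p`, `opp_offset`, `asymmetric`.
#' @examples
#' g <- build_mat_region("M_donorless", flank_len = 1000)
#' reads <- simulate_library(g, sonication_params(20000, seed = 5))
#' calls <- call_nicks(compute_five_prime_counts(reads, g))
#' calls$pos == g$nick_sites$pos
#' @export
call_nicks <- function(profile, models = NULL, alpha = 0.05, spike_ratio = 5,
                       min_size = 2L, max_size = 40L, flank = 1000L,
                       fit_halfwidth = 5000L, merge_dist = 50L) {
  if (is.null(models)) {
    models <- list(watson = fit_null(profile, "watson"),
                   crick = fit_null(profile, "crick"))
  }
  screen <- genome_screen(profile, models$watson, models$crick, alpha = alpha,
                          merge_dist = merge_dist, spike_ratio = spike_ratio)
  empty <- data.frame(chrom = character(), pos = integer(),
                      nicked_strand = character(), spike_count = numeric(),
                      single_p = numeric(), spike_neglog10p = numeric(),
                      opp_window_start = integer(), opp_window_size = integer(),
                      opp_window_sum = numeric(),
                      opp_window_neglog10p = numeric(),
                      opp_offset = integer(), asymmetric = logical())
  calls <- empty
  L <- profile$length
  for (s in c("watson", "crick")) {
    opp <- if (s == "watson") "crick" else "watson"
    pos <- screen[[s]]$positions
    if (length(pos) == 0) next
    dominant <- (profile[[s]][pos] + 1) / (profile[[opp]][pos] + 1) >= spike_ratio
    pos <- pos[dominant]
    if (length(pos) == 0) next
    # collapse candidate runs to their highest-count position
    grp <- cumsum(c(TRUE, diff(pos) > merge_dist))
    pos <- vapply(split(pos, grp), function(p) {
      p[which.max(profile[[s]][p])]
    }, integer(1))
    for (a in pos) {
      fit_reg <- c(max(1L, a - fit_halfwidth), min(L, a + fit_halfwidth - 1L))
      local_own <- fit_null(profile, s, fit_reg)
      local_opp <- fit_null(profile, opp, fit_reg)
      scan_reg <- c(max(1L, a - flank), min(L, a + flank))
      sc <- window_scan(profile, opp, local_opp, region = scan_reg,
                        max_size = max_size)
      best <- best_window(sc, anchor = a)
      n_cells <- sum(!is.na(sc$neglog10p))
      gate_thr <- -log10(alpha / n_cells)
      faces <- abs(best$offset_to_anchor) <= best$size
      if (best$size >= min_size && best$size <= max_size &&
          best$neglog10p > gate_thr && faces) {
        spike_nlp <- neglog10_pvalue_window(profile[[s]][a], 1L, local_own)
        calls <- rbind(calls, data.frame(
          chrom = profile$chrom, pos = a,
          nicked_strand = if (s == "watson") "+" else "-",
          spike_count = profile[[s]][a],
          single_p = pvalue_single(profile[[s]][a], local_own),
          spike_neglog10p = spike_nlp,
          opp_window_start = best$start, opp_window_size = best$size,
          opp_window_sum = best$sum, opp_window_neglog10p = best$neglog10p,
          opp_offset = best$offset_to_anchor, asymmetric = TRUE))
      }
    }
  }
  calls <- calls[order(-calls$spike_neglog10p), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("nick_calls", "data.frame")
  attr(calls, "screen") <- screen
  calls
}

#' Export nick calls as BED and TSV
#'
#' Writes `<prefix>.calls.bed` (one thick mark per spike, strand-aware) and
#' `<prefix>.calls.tsv` (all columns).
#'
#' @param calls A [call_nicks()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_nick_calls <- function(calls, prefix) {
  tsv <- paste0(prefix, ".calls.tsv")
  utils::write.table(as.data.frame(calls), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- tsv
  if (nrow(calls) > 0) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, calls$pos),
                                 strand = calls$nicked_strand,
                                 name = sprintf("nick_%d", seq_len(nrow(calls))),
                                 score = pmin(calls$spike_neglog10p, 1000))
    bed <- paste0(prefix, ".calls.bed")
    rtracklayer::export.bed(gr, bed)
    files <- c(files, bed)
  }
  invisible(files)
}
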