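# Binned RPKM and IP/WCE enrichment tracks.

#' Binned RPKM track from aligned reads
#'
#' Each read is assigned to the bin containing its biological 5' end
#' (consistent with the 5'-count convention); bin values are
#' `count * 1e9 / (library_size * bin_size)`, i.e. reads per kilobase per
#' million mapped reads.
#'
#' @param reads Read table (`chrom`, `start`, `end`, `strand`, `mapq`).
#' @param genome A [genome()] object.
#' @param bin_size Bin width, nt (>= 10; default 1000).
#' @return An object of class `"binned_track"`: list with `chrom`,
#'   `bin_size`, `values` (length `ceiling(length / bin_size)`) and `kind`
#'   (`"rpkm"`).
#' @export
rpkm_track <- function(reads, genome, bin_size = 1000L) {
  if (bin_size < 10) stop("bin_size must be >= 10")
  if (nrow(reads) == 0) stop("empty library")
  bin_size <- as.integer(bin_size)
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end)
  nbins <- as.integer(ceiling(genome$length / bin_size))
  counts <- tabulate((p5 - 1L) %/% bin_size + 1L, nbins = nbins)
  structure(list(chrom = genome$name, bin_size = bin_size,
                 values = counts * 1e9 / (as.numeric(nrow(reads)) * bin_size),
                 kind = "rpkm"),
            class = "binned_track")
}

#' IP over whole-cell-extract enrichment track
#'
#' Element-wise `(ip + pseudocount) / (wce + pseudocount)` of two RPKM
#' tracks on the same chromosome and binning. The pseudocount keeps bins
#' with an empty whole-cell-extract finite.
#'
#' @param ip,wce [rpkm_track()] tracks.
#' @param pseudocount Added to both numerator and denominator (default 0.5).
#' @return A `"binned_track"` with `kind = "enrichment_ratio"`.
#' @export
enrichment_track <- function(ip, wce, pseudocount = 0.5) {
  if (!identical(ip$chrom, wce$chrom) || ip$bin_size != wce$bin_size ||
      length(ip$values) != length(wce$values)) {
    stop("IP and WCE tracks must share chromosome and binning")
  }
  structure(list(chrom = ip$chrom, bin_size = ip$bin_size,
                 values = (ip$values + pseudocount) / (wce$values + pseudocount),
                 kind = "enrichment_ratio"),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d bins of %d nt (%s)\n",
              x$chrom, length(x$values), x$bin_size, x$kind))
  invisible(x)
}

#' Export a binned track as bedGraph
#'
#' @param track A [rpkm_track()] or [enrichment_track()] track.
#' @param path Output bedGraph path.
#' @param chrom_length Optional chromosome length used to clip the last bin.
#' @return Invisibly, `path`.
#' @export
write_track_bedgraph <- function(track, path, chrom_length = NULL) {
  n <- length(track$values)
  starts <- (seq_len(n) - 1L) * track$bin_size + 1L
  ends <- seq_len(n) * track$bin_size
  if (!is.null(chrom_length)) ends[n] <- min(ends[n], chrom_length)
  gr <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(starts, ends),
                               score = track$values)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}
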