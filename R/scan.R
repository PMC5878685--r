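# Multi-scale sliding-window significance scan.
#
# For every window size w = 1..max_size and every start position in a region,
# the w-window 5'-count sum (cumulative-sum arithmetic, exact in integers) is
# scored by its -log10 upper-tail p-value under the fitted null. The
# resulting (size x start) surface localizes both a single-nucleotide spike
# (optimum at w = 1) and a diffuse breakage zone (optimum at the zone width).
# Windows are registered by their start coordinate.

#' Sliding-window significance scan over a region
#'
#' @param profile An unnormalized [compute_five_prime_counts()] profile.
#' @param strand `"watson"` or `"crick"`.
#' @param model A [fit_null()] model for that strand.
#' @param region `c(start, end)` (1-based, closed) to scan; default the
#'   whole chromosome. Must be at least `max_size` long.
#' @param max_size Largest window size scanned (default 40).
#' @param step Start step (default 1).
#' @return An object of class `"scan_result"`: list with `chrom`, `strand`,
#'   `region`, `sizes`, `starts`, `sums` and `neglog10p` (matrices, one row
#'   per size, one column per start; entries where the window would overrun
#'   the region are `NA`) and `model`.
#' @examples
#' g <- build_mat_region("M_donorless", flank_len = 1000)
#' prof <- compute_five_prime_counts(
#'   simulate_library(g, sonication_params(20000, seed = 11)), g)
#' m <- fit_null(prof, "watson")
#' sc <- window_scan(prof, "watson", m,
#'                   region = g$nick_sites$pos + c(-500, 500), max_size = 10)
#' best_window(sc)
#' @export
window_scan <- function(profile, strand = c("watson", "crick"), model,
                        region = NULL, max_size = 40L, step = 1L) {
  strand <- match.arg(strand)
  stopifnot(inherits(model, "null_model"))
  if (profile$normalized) stop("scan requires raw integer counts")
  if (is.null(region)) region <- c(1L, profile$length)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > profile$length) {
    stop("scan region outside chromosome")
  }
  if (max_size < 1L) stop("max_size must be >= 1")
  n <- region[2] - region[1] + 1L
  if (n < max_size) stop("scan region shorter than max_size")
  counts <- profile[[strand]][region[1]:region[2]]
  cs <- c(0, cumsum(counts))
  starts <- seq.int(region[1], region[2], by = step)
  i <- starts - region[1] + 1L
  sizes <- seq_len(max_size)
  sums <- matrix(NA_real_, nrow = max_size, ncol = length(starts),
                 dimnames = list(size = sizes, start = starts))
  nlp <- sums
  for (w in sizes) {
    ok <- i + w - 1L <= n
    s <- cs[i[ok] + w] - cs[i[ok]]
    sums[w, ok] <- s
    nlp[w, ok] <- neglog10_pvalue_window(s, w, model)
  }
  structure(list(chrom = profile$chrom, strand = strand, region = region,
                 sizes = sizes, starts = starts, sums = sums,
                 neglog10p = nlp, model = model),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s %s strand, region %d-%d, sizes 1-%d, max -log10(p) = %.2f\n",
              x$chrom, x$strand, x$region[1], x$region[2], max(x$sizes),
              max(x$neglog10p, na.rm = TRUE)))
  invisible(x)
}

#' Extract the k most significant windows of a scan
#'
#' Cells are ranked by decreasing `-log10(p)`; ties are broken by smaller
#' size, then smaller start, making the order deterministic.
#'
#' @param result A [window_scan()] result.
#' @param k Number of windows to return (capped at the number of scored
#'   cells).
#' @param anchor Optional anchor position; when given, `offset_to_anchor` is
#'   the signed distance from the window to the anchor (0 when the window
#'   covers it, negative when the window lies left of it).
#' @return A `data.frame` of window hits: `strand`, `size`, `start`, `sum`,
#'   `neglog10p` and `offset_to_anchor`.
#' @export
top_k <- function(result, k, anchor = NULL) {
  stopifnot(inherits(result, "scan_result"), k >= 1)
  idx <- which(!is.na(result$neglog10p))
  nlp <- result$neglog10p[idx]
  size <- result$sizes[(idx - 1L) %% nrow(result$neglog10p) + 1L]
  start <- result$starts[(idx - 1L) %/% nrow(result$neglog10p) + 1L]
  o <- order(-nlp, size, start)
  o <- o[seq_len(min(k, length(o)))]
  hits <- data.frame(strand = result$strand, size = size[o], start = start[o],
                     sum = result$sums[idx][o], neglog10p = nlp[o])
  hits$offset_to_anchor <- if (is.null(anchor)) {
    NA_integer_
  } else {
    end <- hits$start + hits$size - 1L
    ifelse(anchor < hits$start, hits$start - anchor,
           ifelse(anchor > end, end - anchor, 0L))
  }
  class(hits) <- c("window_hits", "data.frame")
  hits
}

#' Most significant window of a scan
#'
#' Equivalent to `top_k(result, 1, anchor)`.
#'
#' @inheritParams top_k
#' @return A one-row window-hit `data.frame`.
#' @export
best_window <- function(result, anchor = NULL) {
  top_k(result, 1L, anchor)
}

#' Export a scan result as a long-format TSV
#'
#' Columns: `chrom`, `strand`, `size`, `start`, `sum`, `neglog10p`; one row
#' per scored window.
#'
#' @param result A [window_scan()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(result, path) {
  idx <- which(!is.na(result$neglog10p))
  df <- data.frame(
    chrom = result$chrom, strand = result$strand,
    size = result$sizes[(idx - 1L) %% nrow(result$neglog10p) + 1L],
    start = result$starts[(idx - 1L) %/% nrow(result$neglog10p) + 1L],
    sum = result$sums[idx], neglog10p = result$neglog10p[idx])
  df <- df[order(df$size, df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
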