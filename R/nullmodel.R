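# Overdispersed count null model for per-position 5' counts.
#
# Per-position 5' counts over a reference region are modelled as i.i.d.
# negative binomial (size r, success probability p; mean mu = r(1-p)/p),
# fitted by maximum likelihood with moment-matching initialization via
# MASS::fitdistr, zeros included. When the sample variance does not exceed
# the sample mean the Poisson limit is used instead. Significance is the
# upper tail P(X >= x); window sums of w positions use the additivity of the
# negative binomial, NB(w*r, p) (Poisson: w*lambda), which assumes
# independence of neighbouring positions. Tail probabilities are evaluated
# in log space so deeply significant counts keep finite, ordered -log10
# p-values instead of underflowing to zero.

#' Construct a null model directly
#'
#' Builds a `"null_model"` from known parameters, e.g. for simulation
#' studies or tests; [fit_null()] estimates one from data.
#'
#' @param mu Mean count per position (> 0).
#' @param size Negative-binomial size parameter r; `Inf` gives the Poisson
#'   limit.
#' @param strand,fit_region,n_positions_fit Optional provenance fields.
#' @return A `"null_model"` object.
#' @export
null_model <- function(mu, size = Inf, strand = NA_character_,
                       fit_region = c(NA_integer_, NA_integer_),
                       n_positions_fit = NA_integer_) {
  stopifnot(mu > 0, size > 0)
  structure(list(family = if (is.finite(size)) "negative_binomial" else "poisson",
                 size = size,
                 prob = if (is.finite(size)) size / (size + mu) else NA_real_,
                 mu = mu, strand = strand, fit_region = fit_region,
                 n_positions_fit = n_positions_fit, note = NULL),
            class = "null_model")
}

#' Fit the count null model to a 5'-count profile
#'
#' @param profile An unnormalized [compute_five_prime_counts()] profile.
#' @param strand `"watson"` or `"crick"`: which strand's counts to fit.
#' @param region Optional `c(start, end)` (1-based, closed) restricting the
#'   fit; default the whole chromosome. Must span at least 1000 positions.
#' @return An object of class `"null_model"`: list with `family`
#'   (`"negative_binomial"` or `"poisson"`), `size` (r; `Inf` for Poisson),
#'   `prob` (p; `NA` for Poisson), `mu` (mean), `strand`, `fit_region`,
#'   `n_positions_fit` and `note` (fitting diagnostics, e.g. the Poisson
#'   fallback).
#' @examples
#' g <- build_mat_region("nick_free", flank_len = 1000)
#' prof <- compute_five_prime_counts(
#'   simulate_library(g, sonication_params(5000, seed = 3)), g)
#' fit_null(prof, "watson")
#' @export
fit_null <- function(profile, strand = c("watson", "crick"), region = NULL) {
  strand <- match.arg(strand)
  if (profile$normalized) {
    stop("null model must be fitted on raw integer counts, not a normalized profile")
  }
  if (is.null(region)) region <- c(1L, profile$length)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > profile$length || region[1] > region[2]) {
    stop("fit region outside profile")
  }
  counts <- profile[[strand]][region[1]:region[2]]
  if (length(counts) < 1000L) stop("fit region must contain >= 1000 positions")
  if (all(counts == 0)) stop("all counts in the fit region are zero")
  m <- mean(counts)
  v <- stats::var(counts)
  note <- NULL
  if (v <= m) {
    family <- "poisson"
    size <- Inf
    prob <- NA_real_
    note <- "sample variance <= sample mean; Poisson limit used"
    if (v == 0) note <- paste(note, "(zero-variance input)")
  } else {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(counts, "negative binomial")),
      error = function(e) NULL)
    if (is.null(fit)) {
      # method-of-moments fallback; keeps the model usable on inputs where
      # the likelihood optimization fails to converge
      size <- m^2 / (v - m)
      note <- "ML fit failed; method-of-moments estimates used"
    } else {
      size <- unname(fit$estimate["size"])
      m <- unname(fit$estimate["mu"])
    }
    family <- "negative_binomial"
    prob <- size / (size + m)
  }
  structure(list(family = family, size = size, prob = prob, mu = m,
                 strand = strand, fit_region = region,
                 n_positions_fit = length(counts), note = note),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> %s, mu = %.4g", x$family, x$mu))
  if (x$family == "negative_binomial") {
    cat(sprintf(", size = %.4g, prob = %.4g", x$size, x$prob))
  }
  cat(sprintf(" [%s strand, %d-%d, n = %d]\n", x$strand,
              x$fit_region[1], x$fit_region[2], x$n_positions_fit))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# log upper-tail probability log P(S >= x) for a sum of `w` positions.
# R's pnbinom/ppois log.p underflow to -Inf in very deep tails (the
# incomplete-beta/gamma series underflows before the log is taken); those
# entries are recomputed exactly by log-sum-exp over the pmf, which the
# saddle-point density evaluates accurately at any depth.
.log_tail <- function(x, w, model) {
  x <- pmax(x, 0)
  pois <- model$family == "poisson"
  lp <- suppressWarnings(
    if (pois) {
      stats::ppois(x - 1, lambda = w * model$mu, lower.tail = FALSE,
                   log.p = TRUE)
    } else {
      stats::pnbinom(x - 1, size = w * model$size, prob = model$prob,
                     lower.tail = FALSE, log.p = TRUE)
    })
  bad <- which(!is.finite(lp) & x > 0)
  for (i in bad) {
    ld_prev <- -Inf
    total <- -Inf
    k <- x[i]
    repeat {
      ks <- seq(k, k + 4095)
      ld <- if (pois) {
        stats::dpois(ks, lambda = w * model$mu, log = TRUE)
      } else {
        stats::dnbinom(ks, size = w * model$size, prob = model$prob,
                       log = TRUE)
      }
      m <- max(ld, total)
      total <- m + log(exp(total - m) + sum(exp(ld - m)))
      if (ld[length(ld)] < total - 40) break
      k <- k + 4096
    }
    lp[i] <- total
  }
  lp
}

#' Upper-tail p-value of a single-position count
#'
#' Returns `P(X >= count)` under the fitted null; `P(X >= 0) = 1`.
#' Vectorized over `count`.
#'
#' @param count Non-negative integer count(s).
#' @param model A [fit_null()] model.
#' @return p-value(s) in (0, 1].
#' @export
pvalue_single <- function(count, model) {
  exp(.log_tail(count, 1, model))
}

#' Upper-tail p-value of a window count sum
#'
#' `P(S >= window_sum)` where `S` sums `window_size` i.i.d. positions under
#' the null: `NB(window_size * r, p)` by negative-binomial additivity
#' (Poisson: `window_size * lambda`). `window_size = 1` reduces exactly to
#' [pvalue_single()]. Vectorized over `window_sum`.
#'
#' @param window_sum Non-negative integer window sum(s).
#' @param window_size Number of positions in the window (>= 1).
#' @param model A [fit_null()] model.
#' @return p-value(s) in (0, 1].
#' @export
pvalue_window <- function(window_sum, window_size, model) {
  if (window_size < 1) stop("window_size must be >= 1")
  exp(.log_tail(window_sum, window_size, model))
}

#' -log10 upper-tail p-value of a window count sum
#'
#' Log-space version of [pvalue_window()] for significance far beyond
#' double-precision underflow.
#'
#' @inheritParams pvalue_window
#' @return `-log10 P(S >= window_sum)`, finite and `>= 0`.
#' @export
neglog10_pvalue_window <- function(window_sum, window_size, model) {
  if (window_size < 1) stop("window_size must be >= 1")
  -.log_tail(window_sum, window_size, model) / log(10)
}

#' Serialize / restore a null model as JSON
#'
#' @param model A [fit_null()] model.
#' @param path Output (input) JSON path.
#' @return `write_null_model` invisibly returns `path`; `read_null_model`
#'   returns the restored `"null_model"` object.
#' @export
write_null_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$size <- as.numeric(x$size)        # "Inf" round-trips as string
  x$fit_region <- as.integer(x$fit_region)
  if (is.null(x$note)) x["note"] <- list(NULL)
  structure(x, class = "null_model")
}
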