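#' Bin transfer efficiencies into a histogram
#'
#' Bins are half-open `[l, u)` from 0 to 1 with the last bin closed, so
#' E = 1 falls in the final bin. Per-bin membership (model ids) is recorded
#' for downstream selection.
#'
#' @param records Data frame with columns `model_id` and `E_DA` (all in
#'   \[0, 1\]), e.g. from [efficiency_records()].
#' @param bin_width Bin width; `1 / bin_width` must be an integer.
#' @return An object of class `efficiency_histogram`: `bin_width`,
#'   `breaks`, `mids`, `counts`, `probabilities`, `member_ids` (list of
#'   character vectors per bin), `n`. An empty input gives an all-zero
#'   histogram with attribute `empty = TRUE`.
#' @export
histogram_efficiencies <- function(records, bin_width = 0.05) {
  m <- check_bin_count(bin_width)
  if (is.numeric(records)) {
    records <- data.frame(model_id = as.character(seq_along(records)), E_DA = records)
  }
  stopifnot(all(c("model_id", "E_DA") %in% names(records)))
  e <- records$E_DA
  if (length(e) && (any(e < 0) || any(e > 1))) stop("E_DA values must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (length(e) == 0L) {
    out <- structure(
      list(bin_width = bin_width, breaks = breaks, mids = breaks[-1] - bin_width / 2,
           counts = integer(m), probabilities = rep(0, m),
           member_ids = rep(list(character(0)), m), n = 0L),
      class = "efficiency_histogram"
    )
    attr(out, "empty") <- TRUE
    return(out)
  }
  idx <- bin_index(e, bin_width, m)
  counts <- tabulate(idx, m)
  member_ids <- split(records$model_id, factor(idx, levels = seq_len(m)))
  structure(
    list(bin_width = bin_width, breaks = breaks, mids = breaks[-1] - bin_width / 2,
         counts = counts, probabilities = counts / sum(counts),
         member_ids = unname(member_ids), n = length(e)),
    class = "efficiency_histogram"
  )
}

bin_index <- function(e, bin_width, m) pmin(floor(e / bin_width), m - 1L) + 1L

#' @export
print.efficiency_histogram <- function(x, ...) {
  cat(sprintf("<efficiency_histogram> %d bins of width %g, n = %d, mean = %.3f\n",
              length(x$counts), x$bin_width, x$n,
              if (x$n) sum(x$mids * x$probabilities) else NA))
  invisible(x)
}

#' Histogram mean efficiency (probability-weighted bin centers)
#' @param hist An `efficiency_histogram` or [target_distribution()].
#' @return Scalar mean.
#' @export
histogram_mean <- function(hist) sum(hist$mids * hist$probabilities)

#' Kullback-Leibler divergence between two efficiency histograms
#'
#' Computes `sum over bins with p_j > 0 of p_j * log(p_j / q_j)` in natural
#' log units (nats). With `regularize = "reference"` (default) the q
#' histogram receives pseudo-counts of total weight m/2 (m bins, Jeffreys
#' magnitude) distributed proportionally to the reference probabilities p
#' before normalization — a Dirichlet prior centered on the reference — so
#' identical histograms give exactly 0 at any sample size and empty q bins
#' never produce infinities. `"none"` evaluates the bare formula and returns
#' `Inf` when some bin has `p_j > 0 = q_j`.
#'
#' @param p,q `efficiency_histogram` objects with identical binning; `p` is
#'   the reference (full-collection) histogram.
#' @param regularize `"reference"` or `"none"`.
#' @return Non-negative scalar (possibly `Inf` in strict mode).
#' @export
kld <- function(p, q, regularize = c("reference", "none")) {
  regularize <- match.arg(regularize)
  stopifnot(inherits(p, "efficiency_histogram"), inherits(q, "efficiency_histogram"))
  if (!isTRUE(all.equal(p$bin_width, q$bin_width)) ||
      length(p$counts) != length(q$counts)) {
    stop("histograms have mismatched binning")
  }
  pj <- p$probabilities
  if (regularize == "reference") {
    beta <- length(p$counts) / 2
    qj <- (q$counts + beta * pj) / (sum(q$counts) + beta)
  } else {
    qj <- q$probabilities
  }
  kld_core(pj, qj)
}

kld_core <- function(pj, qj) {
  nz <- pj > 0
  if (any(qj[nz] == 0)) return(Inf)
  v <- sum(pj[nz] * log(pj[nz] / qj[nz]))
  if (v < 0 && v > -1e-9) v <- 0   # fp rounding; KLD is non-negative
  v
}

#' Estimate the minimum representative subset size by KLD convergence
#'
#' For each subset size `x` on the grid `size_step, 2 * size_step, ...,
#' N - size_step` (plus `N` itself when `include_full`), repeatedly draws
#' `x` models uniformly without replacement, histograms their efficiencies,
#' and computes the KLD of the subset histogram from the full-collection
#' histogram. Repetitions grow from `repetition_floor` until the standard
#' error of the mean KLD falls below `sd_tolerance` times the mean, or
#' `repetition_cap` is reached (such points are flagged non-converged).
#'
#' @param records Data frame with `model_id`, `E_DA` (the full collection).
#' @param bin_width Histogram bin width (default 0.05).
#' @param size_step Subset size grid step (default 10).
#' @param sd_tolerance Stopping rule: sd of the mean / mean (default 0.01).
#' @param repetition_floor,repetition_cap Bounds on repetitions per size.
#' @param seed RNG seed for the subset draws.
#' @param regularize Zero-bin handling passed to [kld()].
#' @param include_full Append x = N (KLD exactly 0) to the grid.
#' @return An object of class `kld_curve`: data frame with columns `x`,
#'   `mean_kld`, `sd_kld` (sd of the mean), `k`, `converged`.
#' @export
estimate_min_subset <- function(records, bin_width = 0.05, size_step = 10L,
                                sd_tolerance = 0.01, repetition_floor = 10L,
                                repetition_cap = 10000L, seed = 1L,
                                regularize = c("reference", "none"),
                                include_full = TRUE) {
  regularize <- match.arg(regularize)
  m <- check_bin_count(bin_width)
  n <- nrow(records)
  if (n < 2L * size_step) stop("collection must contain at least 2 * size_step models")
  idx_full <- bin_index(records$E_DA, bin_width, m)
  counts_full <- tabulate(idx_full, m)
  pj <- counts_full / sum(counts_full)
  beta <- m / 2
  sizes <- seq(size_step, n - size_step, by = size_step)
  if (include_full) sizes <- c(sizes, n)
  one_kld <- function(x) {
    counts <- tabulate(idx_full[sample.int(n, x)], m)
    qj <- if (regularize == "reference") {
      (counts + beta * pj) / (x + beta)
    } else {
      counts / sum(counts)
    }
    kld_core(pj, qj)
  }
  with_rng(seed, {
    rows <- lapply(sizes, function(x) {
      vals <- vapply(seq_len(repetition_floor), function(r) one_kld(x), numeric(1))
      repeat {
        k <- length(vals)
        mu <- mean(vals)
        sem <- stats::sd(vals) / sqrt(k)
        converged <- mu < 1e-12 || sem <= sd_tolerance * mu
        if (converged || k >= repetition_cap) break
        batch <- min(k, repetition_cap - k)
        vals <- c(vals, vapply(seq_len(batch), function(r) one_kld(x), numeric(1)))
      }
      data.frame(x = x, mean_kld = mu, sd_kld = sem, k = k, converged = converged)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("kld_curve", "data.frame")
    out
  })
}

#' Smallest subset size whose smoothed mean KLD drops below a threshold
#'
#' Applies antitonic (decreasing isotonic) regression to the mean KLD curve
#' and returns the first size at which the smoothed curve is at or below
#' `threshold`.
#'
#' @param curve A `kld_curve` from [estimate_min_subset()].
#' @param threshold KLD level in nats (default 0.01).
#' @return Integer subset size, or `NA` if the curve never reaches it.
#' @export
min_subset_size <- function(curve, threshold = 0.01) {
  sm <- smooth_decreasing(curve$mean_kld)
  i <- which(sm <= threshold)
  if (length(i) == 0L) return(NA_integer_)
  as.integer(curve$x[i[1L]])
}

# antitonic fit via isotonic regression on the reversed series
smooth_decreasing <- function(y) rev(stats::isoreg(rev(y))$yf)

#' Write a KLD curve as TSV
#' @param curve A `kld_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kld_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
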