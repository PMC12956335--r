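#' Photon-burst simulation configuration
#'
#' @param burst_sizes Empirical burst-size distribution: data frame with
#'   columns `size` (photon counts, >= 1) and `freq` (relative frequencies,
#'   normalized internally), or a path to such a TSV, or a bare integer
#'   vector of sizes (taken equiprobable).
#' @param gamma Detection-correction factor applied as
#'   `E_app = n_A / (n_A + gamma * n_D)`.
#' @param direct_excitation Probability in \[0, 1) that a photon not produced
#'   by energy transfer is still detected as an acceptor photon.
#' @param n_bursts Number of bursts to simulate.
#' @param exchange_mode `"fast"` (fresh structure draw per photon),
#'   `"static"` (one structure per burst) or `"trajectory"` (consecutive
#'   frames of a time-ordered series within each burst).
#' @param seed RNG seed.
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(burst_sizes, gamma = 1, direct_excitation = 0,
                         n_bursts = 10000L,
                         exchange_mode = c("fast", "static", "trajectory"),
                         seed = 1L) {
  exchange_mode <- match.arg(exchange_mode)
  if (is.character(burst_sizes)) {
    burst_sizes <- utils::read.table(burst_sizes, header = TRUE, sep = "\t")
  }
  if (is.numeric(burst_sizes)) {
    burst_sizes <- data.frame(size = burst_sizes, freq = 1)
  }
  stopifnot(all(c("size", "freq") %in% names(burst_sizes)),
            nrow(burst_sizes) >= 1L)
  if (any(burst_sizes$size < 1)) stop("burst sizes must be >= 1")
  if (any(burst_sizes$freq < 0) || sum(burst_sizes$freq) <= 0) {
    stop("burst-size frequencies must be non-negative and not all zero")
  }
  stopifnot(gamma > 0, direct_excitation >= 0, direct_excitation < 1,
            n_bursts >= 1)
  structure(
    list(burst_sizes = data.frame(size = as.integer(burst_sizes$size),
                                  freq = burst_sizes$freq / sum(burst_sizes$freq)),
         gamma = gamma, direct_excitation = direct_excitation,
         n_bursts = as.integer(n_bursts), exchange_mode = exchange_mode,
         seed = seed),
    class = "burst_config"
  )
}

#' Simulate shot-noise-broadened photon bursts
#'
#' For each burst a size n is drawn from the empirical burst-size table.
#' Each photon reports acceptor with probability
#' `E_s + (1 - E_s) * direct_excitation`, where the structure s providing
#' `E_s` is drawn per photon (`fast` exchange: the molecule averages over the
#' collection within a burst), per burst (`static`: one conformation per
#' transit), or follows consecutive frames of a time-ordered efficiency
#' series (`trajectory`). The apparent burst efficiency is the
#' gamma-corrected ratio `n_A / (n_A + gamma * n_D)`.
#'
#' @param records Data frame with `model_id`, `E_DA` (per-structure
#'   efficiencies). For `trajectory` mode the row order is the time order.
#' @param config A [burst_config()].
#' @param weights Optional `selection_weights`; multiplicities set the
#'   structure sampling probabilities (default: uniform over records).
#' @return An object of class `fret_distribution`: `e_app` (per-burst
#'   apparent efficiencies), `histogram` (at `bin_width`), `mean`, `sd`.
#' @param bin_width Bin width of the output histogram.
#' @export
simulate_bursts <- function(records, config, weights = NULL, bin_width = 0.05) {
  stopifnot(inherits(config, "burst_config"))
  stopifnot(all(c("model_id", "E_DA") %in% names(records)))
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "selection_weights"))
    if (config$exchange_mode == "trajectory") {
      stop("trajectory mode samples frames in time order; ",
           "selection weights are not applicable")
    }
    e <- records$E_DA[match(weights$table$model_id, records$model_id)]
    if (anyNA(e)) stop("weights refer to model_ids without efficiency records")
    w <- weights$table$multiplicity
    keep <- w > 0
    e <- e[keep]
    w <- w[keep]
  } else {
    e <- records$E_DA
    w <- rep(1, length(e))
  }
  if (length(e) == 0L || sum(w) <= 0) stop("no structure with positive weight")
  w <- w / sum(w)
  de <- config$direct_excitation
  pa <- e + (1 - e) * de   # per-structure acceptor-photon probability
  with_rng(config$seed, {
    sizes <- config$burst_sizes$size[
      sample.int(nrow(config$burst_sizes), config$n_bursts, replace = TRUE,
                 prob = config$burst_sizes$freq)
    ]
    n_acc <- switch(
      config$exchange_mode,
      # marginal acceptor probability is the weight-average of pa and photons
      # are independent, so the acceptor count is exactly binomial
      fast = stats::rbinom(config$n_bursts, sizes, sum(w * pa)),
      static = {
        s <- sample.int(length(e), config$n_bursts, replace = TRUE, prob = w)
        stats::rbinom(config$n_bursts, sizes, pa[s])
      },
      trajectory = {
        nf <- length(pa)
        if (nf < 2L) stop("trajectory mode needs a time-ordered series of frames")
        vapply(seq_len(config$n_bursts), function(b) {
          n <- sizes[b]
          start <- sample.int(nf, 1L)
          frames <- ((start - 1L + seq_len(n) - 1L) %% nf) + 1L  # wrap
          sum(stats::runif(n) < pa[frames])
        }, numeric(1))
      }
    )
    e_app <- n_acc / (n_acc + config$gamma * (sizes - n_acc))
    structure(
      list(e_app = e_app,
           histogram = histogram_efficiencies(
             data.frame(model_id = as.character(seq_along(e_app)), E_DA = e_app),
             bin_width
           ),
           mean = mean(e_app), sd = stats::sd(e_app)),
      class = "fret_distribution"
    )
  })
}

#' @export
print.fret_distribution <- function(x, ...) {
  cat(sprintf("<fret_distribution> %d bursts: E_app = %.3f +/- %.3f\n",
              length(x$e_app), x$mean, x$sd))
  invisible(x)
}

#' Write a burst histogram as TSV
#' @param dist A `fret_distribution`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fret_distribution <- function(dist, path) {
  h <- dist$histogram
  utils::write.table(
    data.frame(bin_center = h$mids, count = h$counts, probability = h$probabilities),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
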