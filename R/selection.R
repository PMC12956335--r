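#' Experimental target efficiency distribution
#'
#' Binned smFRET probabilities on the same binning contract as
#' [histogram_efficiencies()]: bins of `bin_width` from 0 to 1, last bin
#' closed.
#'
#' @param probabilities Numeric vector of per-bin probabilities (length
#'   `1 / bin_width`); normalized to sum to 1.
#' @param bin_width Bin width; must divide 1 evenly.
#' @return An object of class `target_distribution` with fields `bin_width`,
#'   `mids`, `probabilities`.
#' @export
target_distribution <- function(probabilities, bin_width = 0.05) {
  m <- check_bin_count(bin_width)
  stopifnot(length(probabilities) == m, all(probabilities >= 0),
            sum(probabilities) > 0)
  structure(
    list(bin_width = bin_width,
         mids = seq(0, 1, by = bin_width)[-1] - bin_width / 2,
         probabilities = probabilities / sum(probabilities)),
    class = "target_distribution"
  )
}

#' Read / write a target distribution as a two-column TSV
#'
#' Plain-text table with header columns `bin_center` and `probability`.
#'
#' @param path File path.
#' @return `read_target_distribution()` returns a [target_distribution()].
#' @export
read_target_distribution <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("bin_center", "probability") %in% names(tab)))
  tab <- tab[order(tab$bin_center), ]
  bw <- stats::median(diff(tab$bin_center))
  m <- check_bin_count(bw)
  probs <- rep(0, m)
  idx <- bin_index(tab$bin_center, bw, m)
  probs[idx] <- tab$probability
  target_distribution(probs, bw)
}

#' @rdname read_target_distribution
#' @param target A [target_distribution()].
#' @export
write_target_distribution <- function(target, path) {
  utils::write.table(
    data.frame(bin_center = target$mids, probability = target$probabilities),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Filter a collection on kissing-loop integrity and eRMSD
#'
#' Retains exactly the models classified `preserved` by [classify_kl()] whose
#' eRMSD to the reference is at most `ref$ermsd_max` (inclusive threshold).
#'
#' @param collection A [structure_collection()].
#' @param ref A [kl_reference()].
#' @param annotations Optional precomputed table from [annotate_collection()];
#'   computed on the fly when `NULL`.
#' @return The filtered [structure_collection()] (possibly empty, with a
#'   message) with attribute `audit`: per-model data frame `model_id`,
#'   `kl_status`, `ermsd`, `retained`.
#' @export
filter_collection <- function(collection, ref, annotations = NULL) {
  stopifnot(inherits(collection, "structure_collection"), inherits(ref, "kl_reference"))
  if (is.null(annotations)) annotations <- annotate_collection(collection, ref)
  stopifnot(setequal(annotations$model_id, model_ids(collection)))
  ann <- annotations[match(model_ids(collection), annotations$model_id), ]
  retained <- ann$kl_status == "preserved" & !is.na(ann$ermsd) &
    ann$ermsd <= ref$ermsd_max
  audit <- data.frame(model_id = ann$model_id, kl_status = ann$kl_status,
                      ermsd = ann$ermsd, retained = retained)
  if (!any(retained)) message("filter_collection: no model retained")
  out <- structure_collection(collection$models[retained])
  attr(out, "audit") <- audit
  out
}

new_selection_weights <- function(table, mode) {
  stopifnot(all(table$multiplicity >= 0), !anyDuplicated(table$model_id))
  structure(
    list(table = table, n_total = sum(table$multiplicity), mode = mode),
    class = "selection_weights"
  )
}

#' @export
print.selection_weights <- function(x, ...) {
  cat(sprintf("<selection_weights> mode %s: %d unique models, n_total = %d\n",
              x$mode, sum(x$table$multiplicity > 0), x$n_total))
  invisible(x)
}

#' Unweighted selection: every structure exactly once
#'
#' Preserves the collection's own efficiency distribution: per-bin
#' frequencies equal `|B_i| / N`.
#'
#' @param hist A non-empty `efficiency_histogram`.
#' @return A `selection_weights` object (multiplicity 1 per member).
#' @export
unweighted_selection <- function(hist) {
  stopifnot(inherits(hist, "efficiency_histogram"))
  if (hist$n == 0L) stop("cannot select from an empty histogram")
  ids <- unlist(hist$member_ids, use.names = FALSE)
  new_selection_weights(
    data.frame(model_id = ids, multiplicity = 1L),
    mode = "unweighted"
  )
}

# largest-remainder apportionment of n_total into quotas proportional to p;
# ties broken toward lower bin index
apportion_largest_remainder <- function(p, n_total) {
  raw <- p * n_total
  base <- floor(raw)
  rem <- n_total - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Weighted selection against an experimental target distribution
#'
#' Target probabilities restricted to the populated bins (`|B_i| > 0`) are
#' renormalized and converted to integer per-bin quotas by largest-remainder
#' apportionment of `n_total`. Within each bin: when the quota does not
#' exceed the bin population, that many distinct members are drawn without
#' replacement; otherwise every member receives the integer part
#' `floor(quota / |B_i|)` and the remainder goes to members drawn without
#' replacement from a random permutation of the bin.
#'
#' @param hist `efficiency_histogram` of the (filtered) collection.
#' @param target A [target_distribution()] on the same binning.
#' @param n_total Total selection size (default: the collection size N).
#' @param seed RNG seed for the within-bin draws.
#' @return A `selection_weights` object with attributes `quota` (per-bin
#'   quota table) and `discarded_mass` (target probability lost to
#'   unpopulated bins before renormalization).
#' @export
weighted_selection <- function(hist, target, n_total = NULL, seed = NULL) {
  stopifnot(inherits(hist, "efficiency_histogram"),
            inherits(target, "target_distribution"))
  if (!isTRUE(all.equal(hist$bin_width, target$bin_width))) {
    stop("histogram and target have mismatched binning")
  }
  if (hist$n == 0L) stop("cannot select from an empty histogram")
  if (is.null(n_total)) n_total <- hist$n
  stopifnot(n_total >= 1)
  populated <- hist$counts > 0
  covered <- sum(target$probabilities[populated])
  if (covered == 0) {
    stop("no overlap: every target-populated bin is empty in the collection; ",
         "reweighting cannot generate conformations the collection lacks")
  }
  p <- ifelse(populated, target$probabilities, 0) / covered
  quota <- apportion_largest_remainder(p, n_total)
  rows <- list()
  with_rng(seed, {
    for (b in which(quota > 0L)) {
      ids <- hist$member_ids[[b]]
      nb <- length(ids)
      q <- quota[b]
      if (q <= nb) {
        pick <- ids[sample.int(nb, q)]
        mult <- stats::setNames(rep(1L, q), pick)
      } else {
        mult <- stats::setNames(rep(q %/% nb, nb), ids)
        extra <- q %% nb
        if (extra > 0L) {
          bump <- ids[sample.int(nb, extra)]
          mult[bump] <- mult[bump] + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(model_id = names(mult),
                                              multiplicity = as.integer(mult),
                                              bin = b)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    out <- new_selection_weights(tab[c("model_id", "multiplicity")], "weighted")
    attr(out, "quota") <- data.frame(bin = seq_along(quota),
                                     bin_center = hist$mids,
                                     target_p = target$probabilities,
                                     renormalized_p = p,
                                     population = hist$counts,
                                     quota = quota)
    attr(out, "bin_of") <- tab$bin
    attr(out, "discarded_mass") <- 1 - covered
    out
  })
}

#' Per-structure contribution report
#'
#' @param weights A `selection_weights` object.
#' @return Data frame `model_id`, `multiplicity`, `percent`
#'   (multiplicity / n_total * 100), sorted by decreasing contribution, with
#'   attribute `unique_count` (number of models with multiplicity > 0).
#' @export
report_contributions <- function(weights) {
  stopifnot(inherits(weights, "selection_weights"))
  if (nrow(weights$table) == 0L) stop("empty selection")
  tab <- weights$table
  tab$percent <- 100 * tab$multiplicity / weights$n_total
  tab <- tab[order(-tab$multiplicity, tab$model_id), ]
  rownames(tab) <- NULL
  attr(tab, "unique_count") <- sum(tab$multiplicity > 0)
  tab
}

# efficiency histogram implied by a selection (multiplicities applied)
selection_histogram <- function(weights, records, bin_width = 0.05) {
  e <- records$E_DA[match(weights$table$model_id, records$model_id)]
  expanded <- rep(e, weights$table$multiplicity)
  histogram_efficiencies(
    data.frame(model_id = rep(weights$table$model_id, weights$table$multiplicity),
               E_DA = expanded),
    bin_width
  )
}
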