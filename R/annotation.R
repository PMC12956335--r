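#' Kissing-loop validation contract
#'
#' Bundles the reference structure and the rules a model must satisfy to
#' count as a preserved kissing loop: a set of residue pairs required to be
#' canonical Watson-Crick, one variable pair exempt from the canonical
#' requirement but required to stay spatially proximal, the residue region
#' over which eRMSD to the reference is computed, and the eRMSD threshold.
#'
#' @param reference_model A [structure_model()] of the reference motif
#'   (e.g. the kissing-loop region of a cryo-EM structure).
#' @param required_pairs Two-column matrix (or list of length-2 vectors) of
#'   residue numbers that must be canonical WC.
#' @param variable_pair Length-2 residue-number vector exempt from the
#'   canonical requirement; may be `NULL`.
#' @param region Residue numbers over which eRMSD is computed; must contain
#'   all residues of `required_pairs`.
#' @param ermsd_max eRMSD selection threshold (default 0.8).
#' @param proximity_max C1'-C1' distance (A) within which the variable pair
#'   counts as spatially proximal (default 12).
#' @param chain Chain id the residue numbers refer to (default "A").
#' @return An object of class `kl_reference`.
#' @export
kl_reference <- function(reference_model, required_pairs, variable_pair = NULL,
                         region = NULL, ermsd_max = 0.8, proximity_max = 12,
                         chain = "A") {
  stopifnot(inherits(reference_model, "structure_model"))
  if (is.list(required_pairs)) required_pairs <- do.call(rbind, required_pairs)
  required_pairs <- matrix(as.integer(required_pairs), ncol = 2)
  if (!is.null(variable_pair)) {
    variable_pair <- as.integer(variable_pair)
    stopifnot(length(variable_pair) == 2)
    if (any(apply(required_pairs, 1, function(p) setequal(p, variable_pair)))) {
      stop("variable_pair must not be one of the required_pairs")
    }
  }
  if (is.null(region)) region <- sort(unique(as.integer(required_pairs)))
  region <- sort(unique(as.integer(region)))
  if (!all(required_pairs %in% region)) {
    stop("region must contain all residues of required_pairs")
  }
  structure(
    list(reference_model = reference_model, required_pairs = required_pairs,
         variable_pair = variable_pair, region = region,
         ermsd_max = ermsd_max, proximity_max = proximity_max, chain = chain),
    class = "kl_reference"
  )
}

#' Kissing-loop reference for the synthetic two-stem construct
#'
#' Convenience constructor: uses an unperturbed (spread = 0) model as the
#' reference, the first duplex block as the eRMSD region, its base pairs as
#' the required pairs, with one of them optionally designated variable.
#'
#' @param spec A [fixture_spec()]; its stem/linker dimensions define the
#'   region (the spread is forced to 0 for the reference model).
#' @param variable_index Index (1-based) of the stem pair to designate as the
#'   variable pair, or 0 for none.
#' @inheritParams kl_reference
#' @return A [kl_reference()].
#' @export
toy_kl_reference <- function(spec, variable_index = 1L, ermsd_max = 0.8) {
  ref_spec <- fixture_spec(1L, spec$linker_length_nt, spec$stem_length_bp,
                           seed = spec$seed, spread = 0, stem_seq = spec$stem_seq)
  coll <- generate_toy_construct(ref_spec)
  cons <- attr(coll, "construct")
  pairs <- cons$stem1_pairs
  varp <- NULL
  if (variable_index > 0) {
    varp <- pairs[variable_index, ]
    pairs <- pairs[-variable_index, , drop = FALSE]
  }
  kl_reference(coll$models[[1]], pairs, varp,
               region = cons$stem1_resnos, ermsd_max = ermsd_max)
}

# residue table: one row per residue with the atoms needed for pair geometry
residue_split <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, sep = "|")
  split(a, factor(key, levels = unique(key)))
}

base_letter <- function(resname) {
  r <- toupper(trimws(resname))
  map <- c(A = "A", ADE = "A", RA = "A", DA = "A",
           G = "G", GUA = "G", RG = "G", DG = "G",
           C = "C", CYT = "C", RC = "C", DC = "C",
           U = "U", URA = "U", URI = "U", RU = "U", T = "U", DT = "U")
  unname(map[r])
}

# canonical WC edge heavy-atom pairs, listed as (purine atom, pyrimidine atom)
wc_edge_atoms <- function(pur, pyr) {
  if (pur == "A" && pyr == "U") list(c("N1", "N3"), c("N6", "O4"))
  else if (pur == "G" && pyr == "C") list(c("N1", "N3"), c("O6", "N4"))
  else NULL
}

residue_geometry <- function(res) {
  need <- c("C2", "C4", "C6")
  if (!all(need %in% res$atom)) return(NULL)
  pick <- function(nm) as.numeric(res[match(nm, res$atom), c("x", "y", "z")])
  ring <- rbind(pick("C2"), pick("C4"), pick("C6"))
  center <- colMeans(ring)
  v1 <- ring[1, ] - center
  v2 <- ring[2, ] - center
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  n <- n / sqrt(sum(n^2))
  base <- base_letter(res$resname[1])
  glyco_name <- if (isTRUE(base %in% c("A", "G"))) "N9" else "N1"
  list(center = center, normal = n, base = base,
       atoms = res, chain = res$chain[1], resno = res$resno[1],
       glyco = if (glyco_name %in% res$atom) pick(glyco_name) else NULL,
       c1p = if ("C1'" %in% res$atom) pick("C1'") else NULL)
}

# cis test: the two C1' atoms lie on the same side of the axis through the
# glycosidic nitrogens (standard cis WC/WC criterion)
is_cis <- function(ga, gb) {
  if (is.null(ga$glyco) || is.null(gb$glyco) ||
      is.null(ga$c1p) || is.null(gb$c1p)) return(NA)
  axis <- gb$glyco - ga$glyco
  perp <- function(p, o) {
    v <- p - o
    v - axis * sum(v * axis) / sum(axis^2)
  }
  sum(perp(ga$c1p, ga$glyco) * perp(gb$c1p, gb$glyco)) > 0
}

#' Annotate base pairs geometrically
#'
#' Emits every residue pair whose base centroids are within interaction
#' range, classified as `canonical_WC` when (i) the bases are complementary
#' (A-U or G-C), (ii) both canonical edge hydrogen-bond heavy-atom distances
#' fall within `hbond_range`, (iii) the inter-base-plane angle is at most
#' `max_plane_angle` degrees, and (iv) the faces are oriented cis; otherwise
#' `noncanonical`. Residues missing the base atoms needed for the geometry
#' are skipped with a warning.
#'
#' @param model A [structure_model()].
#' @param hbond_range Length-2 numeric, allowed heavy-atom H-bond distance
#'   interval in Angstrom (default `c(2.4, 3.6)`).
#' @param max_plane_angle Maximum inter-base-plane angle in degrees (35).
#' @param contact_range Base-centroid distance (A) below which a pair is
#'   examined and emitted (default 7).
#' @return Data frame with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `base_a`, `base_b`, `category`, `d1`, `d2`, `plane_angle`; ordered so
#'   `(chain_a, res_a) < (chain_b, res_b)`.
#' @export
annotate_base_pairs <- function(model, hbond_range = c(2.4, 3.6),
                                max_plane_angle = 35, contact_range = 7) {
  stopifnot(inherits(model, "structure_model"))
  geos <- lapply(residue_split(model), residue_geometry)
  skipped <- vapply(geos, is.null, logical(1))
  if (any(skipped)) {
    warning(sprintf("model %s: %d residue(s) skipped (missing base atoms)",
                    model$model_id, sum(skipped)))
    geos <- geos[!skipped]
  }
  n <- length(geos)
  out <- list()
  if (n >= 2) {
    centers <- t(vapply(geos, function(g) g$center, numeric(3)))
    dmat <- as.matrix(stats::dist(centers))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (dmat[i, j] > contact_range) next
        out[[length(out) + 1L]] <- classify_pair(
          geos[[i]], geos[[j]], hbond_range, max_plane_angle
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      chain_a = character(0), res_a = integer(0), chain_b = character(0),
      res_b = integer(0), base_a = character(0), base_b = character(0),
      category = character(0), d1 = numeric(0), d2 = numeric(0),
      plane_angle = numeric(0)
    ))
  }
  do.call(rbind, out)
}

classify_pair <- function(ga, gb, hbond_range, max_plane_angle) {
  # order so that (chain, resno) of a < b
  if (ga$chain > gb$chain || (ga$chain == gb$chain && ga$resno > gb$resno)) {
    tmp <- ga; ga <- gb; gb <- tmp
  }
  d1 <- d2 <- NA_real_
  cosang <- abs(sum(ga$normal * gb$normal))
  angle <- acos(pmin(1, cosang)) * 180 / pi
  category <- "noncanonical"
  comp <- !is.na(ga$base) && !is.na(gb$base) &&
    ((ga$base %in% c("A", "G") && gb$base == wc_partner(ga$base)) ||
     (gb$base %in% c("A", "G") && ga$base == wc_partner(gb$base)))
  if (comp) {
    if (ga$base %in% c("A", "G")) { pur <- ga; pyr <- gb } else { pur <- gb; pyr <- ga }
    edges <- wc_edge_atoms(pur$base, pyr$base)
    dist_of <- function(ed) {
      pa <- pur$atoms[match(ed[1], pur$atoms$atom), c("x", "y", "z")]
      pb <- pyr$atoms[match(ed[2], pyr$atoms$atom), c("x", "y", "z")]
      if (anyNA(pa) || anyNA(pb)) return(NA_real_)
      sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))
    }
    d1 <- dist_of(edges[[1]])
    d2 <- dist_of(edges[[2]])
    cis <- is_cis(ga, gb)
    if (!anyNA(c(d1, d2)) &&
        d1 >= hbond_range[1] && d1 <= hbond_range[2] &&
        d2 >= hbond_range[1] && d2 <= hbond_range[2] &&
        angle <= max_plane_angle && isTRUE(cis)) {
      category <- "canonical_WC"
    }
  }
  data.frame(
    chain_a = ga$chain, res_a = ga$resno, chain_b = gb$chain, res_b = gb$resno,
    base_a = ga$base, base_b = gb$base, category = category,
    d1 = d1, d2 = d2, plane_angle = angle
  )
}

#' Classify kissing-loop integrity of one model
#'
#' A model is `preserved` iff every required pair of the reference contract
#' is annotated canonical WC and the variable pair's residues are spatially
#' proximal (C1'-C1' distance at most `ref$proximity_max`); any deviation,
#' including missing residues, gives `altered`.
#'
#' @param pairs Annotation table from [annotate_base_pairs()] for `model`.
#' @param ref A [kl_reference()].
#' @param model The [structure_model()] the annotation came from.
#' @return `"preserved"` or `"altered"`, with attribute `reason` when altered.
#' @export
classify_kl <- function(pairs, ref, model) {
  stopifnot(inherits(ref, "kl_reference"), inherits(model, "structure_model"))
  canon <- pairs[pairs$category == "canonical_WC" & pairs$chain_a == ref$chain &
                   pairs$chain_b == ref$chain, , drop = FALSE]
  have <- paste(pmin(canon$res_a, canon$res_b), pmax(canon$res_a, canon$res_b))
  for (k in seq_len(nrow(ref$required_pairs))) {
    p <- ref$required_pairs[k, ]
    key <- paste(min(p), max(p))
    if (!key %in% have) {
      return(structure("altered",
                       reason = sprintf("required pair %d-%d not canonical WC",
                                        p[1], p[2])))
    }
  }
  if (!is.null(ref$variable_pair)) {
    a <- find_atom(model, ref$chain, ref$variable_pair[1], "C1'")
    b <- find_atom(model, ref$chain, ref$variable_pair[2], "C1'")
    if (is.null(a) || is.null(b)) {
      return(structure("altered", reason = "variable pair residue(s) missing"))
    }
    if (sqrt(sum((a - b)^2)) > ref$proximity_max) {
      return(structure("altered", reason = "variable pair not proximal"))
    }
  }
  "preserved"
}

# --- eRMSD ----------------------------------------------------------------

# per-base orthonormal frame from the six-membered ring atoms C2/C4/C6
base_frames <- function(model, region, chain) {
  geos <- lapply(residue_split(model), residue_geometry)
  geos <- Filter(Negate(is.null), geos)
  geos <- Filter(function(g) g$chain == chain && g$resno %in% region, geos)
  resnos <- vapply(geos, function(g) g$resno, integer(1))
  geos <- geos[order(resnos)]
  lapply(geos, function(g) {
    pick <- function(nm) as.numeric(g$atoms[match(nm, g$atoms$atom), c("x", "y", "z")])
    x <- pick("C2") - g$center
    x <- x / sqrt(sum(x^2))
    v <- pick("C4") - g$center
    z <- c(x[2] * v[3] - x[3] * v[2],
           x[3] * v[1] - x[1] * v[3],
           x[1] * v[2] - x[2] * v[1])
    z <- z / sqrt(sum(z^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    list(resno = g$resno, center = g$center, R = rbind(x, y, z))
  })
}

# 4-component G-vectors over all ordered base pairs; lateral scale 5 A,
# normal scale 3 A, cutoff 2.4 scaled units, gamma = pi / cutoff
gvectors <- function(frames, cutoff = 2.4, scale = c(5, 5, 3)) {
  n <- length(frames)
  gamma <- pi / cutoff
  G <- array(0, c(n, n, 4))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      r <- frames[[j]]$R %*% (frames[[k]]$center - frames[[j]]$center)
      rt <- as.numeric(r) / scale
      rho <- sqrt(sum(rt^2))
      if (rho < cutoff) {
        G[j, k, ] <- c(sin(gamma * rho) * rt / rho, 1 + cos(gamma * rho)) / gamma
      }
    }
  }
  G
}

#' Compute the eRMSD between a model and the reference over a residue region
#'
#' Base-centric structural distance: each base gets an orthonormal frame from
#' its C2/C4/C6 ring atoms; inter-base displacements are anisotropically
#' scaled (5 A laterally, 3 A along the base normal) and mapped to
#' 4-component G-vectors with cutoff 2.4 scaled units; the result is the
#' root-mean-square G-vector difference over all ordered base pairs,
#' normalized by the number of residues.
#'
#' @param model A [structure_model()].
#' @param ref A [kl_reference()]; its `region` and `reference_model` are used.
#' @return Non-negative scalar; 0 for identical (or rigidly transformed)
#'   structures.
#' @export
compute_ermsd <- function(model, ref) {
  stopifnot(inherits(model, "structure_model"), inherits(ref, "kl_reference"))
  fa <- base_frames(model, ref$region, ref$chain)
  fb <- base_frames(ref$reference_model, ref$region, ref$chain)
  ra <- vapply(fa, function(f) f$resno, integer(1))
  rb <- vapply(fb, function(f) f$resno, integer(1))
  if (!identical(ra, rb)) {
    stop("residue mismatch between model and reference region: model has {",
         paste(ra, collapse = ","), "}, reference has {",
         paste(rb, collapse = ","), "}")
  }
  n <- length(fa)
  if (n < 2) stop("eRMSD region must contain at least two resolvable residues")
  ga <- gvectors(fa)
  gb <- gvectors(fb)
  sqrt(sum((ga - gb)^2) / n)
}

#' Annotate a whole collection and classify kissing-loop integrity
#'
#' @param collection A [structure_collection()].
#' @param ref A [kl_reference()].
#' @return Data frame (one row per model): `model_id`, `kl_status`, `ermsd`,
#'   `n_canonical`; attribute `pairs` holds the per-model annotation tables.
#' @export
annotate_collection <- function(collection, ref) {
  stopifnot(inherits(collection, "structure_collection"))
  rows <- vector("list", length(collection))
  pair_tables <- vector("list", length(collection))
  for (i in seq_along(collection$models)) {
    m <- collection$models[[i]]
    pairs <- annotate_base_pairs(m)
    status <- classify_kl(pairs, ref, m)
    erm <- tryCatch(compute_ermsd(m, ref), error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      model_id = m$model_id, kl_status = as.character(status), ermsd = erm,
      n_canonical = sum(pairs$category == "canonical_WC")
    )
    pair_tables[[i]] <- pairs
  }
  out <- do.call(rbind, rows)
  names(pair_tables) <- out$model_id
  attr(out, "pairs") <- pair_tables
  out
}
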