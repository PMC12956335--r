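#' Dye parameters for accessible-contact-volume calculation
#'
#' @param attachment `list(chain, resno, atom)` naming the attachment atom.
#' @param linker_length Dye linker length in Angstrom (maximum path length
#'   from the attachment atom through free space).
#' @param linker_width Linker tube width in Angstrom; obstacles are dilated
#'   by half this width during pathfinding.
#' @param dye_radii One or three dye sphere radii in Angstrom; with three
#'   radii the accessible sets are unioned with equal weight.
#' @param cv_thickness Contact-shell depth from the biomolecular surface (A):
#'   accessible points whose distance to the nearest atom surface is at most
#'   this are labeled `contact`.
#' @param cv_fraction Fraction of total dye weight carried by the contact
#'   shell, in \[0, 1\] (experimentally from anisotropy).
#' @param forster_radius Forster radius R0 in Angstrom.
#' @param quantum_yield Donor fluorescence quantum yield (default 0.46).
#' @return An object of class `dye_parameters`.
#' @export
dye_parameters <- function(attachment, linker_length = 20, linker_width = 4.5,
                           dye_radii = 3.5, cv_thickness = 6, cv_fraction = 0,
                           forster_radius = 54, quantum_yield = 0.46) {
  stopifnot(linker_length > 0, linker_width >= 0,
            all(dye_radii > 0), length(dye_radii) %in% c(1L, 3L),
            cv_fraction >= 0, cv_fraction <= 1, forster_radius > 0)
  stopifnot(is.list(attachment), all(c("chain", "resno", "atom") %in% names(attachment)))
  structure(
    list(attachment = attachment, linker_length = linker_length,
         linker_width = linker_width, dye_radii = dye_radii,
         cv_thickness = cv_thickness, cv_fraction = cv_fraction,
         forster_radius = forster_radius, quantum_yield = quantum_yield),
    class = "dye_parameters"
  )
}

# van der Waals radii by element, inferred from the first letter of the atom
# name; heavy atoms only
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)

atom_vdw <- function(atom_names) {
  el <- substr(gsub("[^A-Za-z].*$", "", atom_names), 1, 1)
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Compute the accessible contact volume of one dye on one structure
#'
#' A cubic grid centered on the attachment atom (half-width
#' `linker_length + max(dye_radii)`) is screened in three steps: grid points
#' where the dye sphere overlaps any biomolecular heavy atom are excluded;
#' the remaining points must be reachable from the attachment atom along a
#' shortest grid path (Dijkstra, Euclidean edge lengths, neighborhood of
#' `nbr_radius` grid steps) of length at most `linker_length`, where for
#' pathfinding obstacles are additionally dilated by `linker_width / 2`;
#' finally, points within `cv_thickness` of any atom surface are labeled
#' `contact` and the rest `free`, with the contact shell carrying
#' `cv_fraction` of the total weight and the free volume the remainder.
#'
#' @param model A [structure_model()].
#' @param dye A [dye_parameters()].
#' @param grid_spacing Grid spacing in Angstrom (default 1.0).
#' @param nbr_radius Neighborhood radius of the path graph in grid steps
#'   (default 3; 1 gives the classical 26-neighbor graph, at the price of a
#'   sizable metric distortion of the accessible region).
#' @return An object of class `acv`: `points` data frame (`x`, `y`, `z`,
#'   `weight`, `label`), `mean_position`, `grid_origin`, `grid_spacing`,
#'   `attachment_xyz`, `model_id`.
#' @export
compute_acv <- function(model, dye, grid_spacing = 1.0, nbr_radius = 3L) {
  stopifnot(inherits(model, "structure_model"), inherits(dye, "dye_parameters"),
            grid_spacing > 0)
  att <- dye$attachment
  apos <- find_atom(model, att$chain, att$resno, att$atom)
  if (is.null(apos)) {
    stop(sprintf("attachment atom %s/%s/%s not found in model %s",
                 att$chain, att$resno, att$atom, model$model_id))
  }
  halfw <- dye$linker_length + max(dye$dye_radii)
  nhalf <- ceiling(halfw / grid_spacing)
  ax <- apos[1] + grid_spacing * seq(-nhalf, nhalf)
  ay <- apos[2] + grid_spacing * seq(-nhalf, nhalf)
  az <- apos[3] + grid_spacing * seq(-nhalf, nhalf)
  nd <- length(ax)
  px <- rep(ax, times = nd * nd)
  py <- rep(rep(ay, each = nd), times = nd)
  pz <- rep(az, each = nd * nd)

  # signed distance from every grid point to the nearest atom surface
  a <- model$atoms
  is_att <- a$chain == att$chain & a$resno == att$resno & a$atom == att$atom
  a <- a[!is_att, , drop = FALSE]
  reach <- halfw + 2.0
  keep <- abs(a$x - apos[1]) <= reach + max(VDW_RADII) &
    abs(a$y - apos[2]) <= reach + max(VDW_RADII) &
    abs(a$z - apos[3]) <= reach + max(VDW_RADII)
  a <- a[keep, , drop = FALSE]
  minsurf <- rep(Inf, length(px))
  if (nrow(a) > 0) {
    vdw <- atom_vdw(a$atom)
    for (i in seq_len(nrow(a))) {
      d <- sqrt((px - a$x[i])^2 + (py - a$y[i])^2 + (pz - a$z[i])^2) - vdw[i]
      minsurf <- pmin(minsurf, d)
    }
  }

  # linker emergence: near its covalent attachment the linker cannot be
  # sterically excluded by the atoms it is bonded to, so a small sphere
  # around the attachment point stays traversable during pathfinding
  d_att <- sqrt((px - apos[1])^2 + (py - apos[2])^2 + (pz - apos[3])^2)
  corridor <- minsurf >= dye$linker_width / 2 |
    d_att <= max(3, dye$linker_width)
  src <- as.integer((nhalf) * nd * nd + (nhalf) * nd + nhalf + 1L)  # center
  corridor[src] <- TRUE
  dist <- grid_dijkstra_cpp(c(nd, nd, nd), corridor, src, grid_spacing,
                            as.integer(nbr_radius), dye$linker_length)
  reachable <- dist <= dye$linker_length

  nr <- length(dye$dye_radii)
  w0 <- numeric(length(px))
  for (r in dye$dye_radii) w0 <- w0 + (minsurf >= r & reachable) / nr
  sel <- which(w0 > 0)
  if (length(sel) == 0L) {
    stop(sprintf("empty ACV for model %s: no accessible grid point (buried attachment?)",
                 model$model_id))
  }
  pts <- data.frame(
    x = px[sel], y = py[sel], z = pz[sel], weight = w0[sel],
    label = ifelse(minsurf[sel] <= dye$cv_thickness, "contact", "free")
  )
  wc <- sum(pts$weight[pts$label == "contact"])
  wf <- sum(pts$weight[pts$label == "free"])
  if (wc > 0 && wf > 0) {
    pts$weight[pts$label == "contact"] <-
      pts$weight[pts$label == "contact"] / wc * dye$cv_fraction
    pts$weight[pts$label == "free"] <-
      pts$weight[pts$label == "free"] / wf * (1 - dye$cv_fraction)
    if (dye$cv_fraction %in% c(0, 1)) {
      pts <- pts[pts$weight > 0, , drop = FALSE]
    }
  }
  pts$weight <- pts$weight / sum(pts$weight)
  mp <- c(sum(pts$x * pts$weight), sum(pts$y * pts$weight), sum(pts$z * pts$weight))
  structure(
    list(points = pts, mean_position = mp,
         grid_origin = c(ax[1], ay[1], az[1]), grid_spacing = grid_spacing,
         attachment_xyz = apos, model_id = model$model_id, dye = dye),
    class = "acv"
  )
}

#' @export
print.acv <- function(x, ...) {
  cat(sprintf(
    "<acv> model %s: %d points (%d contact), volume ~ %.0f A^3\n",
    x$model_id, nrow(x$points), sum(x$points$label == "contact"),
    sum(x$points$weight > 0) * x$grid_spacing^3
  ))
  invisible(x)
}

#' Multi-frame accessible contact volume (mACV)
#'
#' Weight-union of the ACVs of the same labeling position over several
#' frames of one model: each frame contributes equally to the total weight.
#' A single frame degenerates to a plain ACV.
#'
#' @param frames List of [structure_model()] frames.
#' @param dye A [dye_parameters()].
#' @inheritParams compute_acv
#' @return An `acv` object whose `points` concatenate the per-frame clouds.
#' @export
compute_macv <- function(frames, dye, grid_spacing = 1.0, nbr_radius = 3L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  acvs <- lapply(frames, compute_acv, dye = dye, grid_spacing = grid_spacing,
                 nbr_radius = nbr_radius)
  if (length(acvs) == 1L) return(acvs[[1L]])
  pts <- do.call(rbind, lapply(acvs, function(a) {
    p <- a$points
    p$weight <- p$weight / length(acvs)
    p
  }))
  mp <- c(sum(pts$x * pts$weight), sum(pts$y * pts$weight), sum(pts$z * pts$weight))
  out <- acvs[[1L]]
  out$points <- pts
  out$mean_position <- mp
  out
}

#' Transfer efficiency from a donor/acceptor ACV pair
#'
#' Samples `n_pairs` independent dye position pairs (weight-proportional from
#' each ACV) and converts the inter-dye distances to a FRET efficiency via
#' the Forster equation E = 1 / (1 + (R / R0)^6). `mode = "mean_distance"`
#' (default) applies the equation to the mean distance; `"mean_efficiency"`
#' averages the per-pair efficiencies.
#'
#' @param acv_donor,acv_acceptor Non-empty `acv` objects.
#' @param r0 Forster radius in Angstrom.
#' @param mode `"mean_distance"` or `"mean_efficiency"`.
#' @param n_pairs Number of sampled position pairs.
#' @param seed Optional RNG seed for the pair sampling.
#' @return One-row data frame: `model_id`, `E_DA`, `R_mean`.
#' @export
efficiency_from_acvs <- function(acv_donor, acv_acceptor, r0,
                                 mode = c("mean_distance", "mean_efficiency"),
                                 n_pairs = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(acv_donor, "acv"), inherits(acv_acceptor, "acv"), r0 > 0)
  pd <- acv_donor$points
  pa <- acv_acceptor$points
  if (nrow(pd) == 0L || nrow(pa) == 0L) stop("empty ACV passed to efficiency_from_acvs")
  with_rng(seed, {
    id <- sample.int(nrow(pd), n_pairs, replace = TRUE, prob = pd$weight)
    ia <- sample.int(nrow(pa), n_pairs, replace = TRUE, prob = pa$weight)
    r <- sqrt((pd$x[id] - pa$x[ia])^2 + (pd$y[id] - pa$y[ia])^2 +
                (pd$z[id] - pa$z[ia])^2)
    r_mean <- mean(r)
    e <- switch(mode,
                mean_distance = 1 / (1 + (r_mean / r0)^6),
                mean_efficiency = mean(1 / (1 + (r / r0)^6)))
    data.frame(model_id = acv_donor$model_id, E_DA = e, R_mean = r_mean)
  })
}

#' Per-model transfer efficiencies for a whole collection
#'
#' Computes donor and acceptor ACVs and the resulting efficiency for every
#' model of a collection.
#'
#' @param collection A [structure_collection()].
#' @param donor,acceptor [dye_parameters()] for the two dyes; the Forster
#'   radius is taken from `donor$forster_radius`.
#' @inheritParams compute_acv
#' @inheritParams efficiency_from_acvs
#' @return Data frame with one row per model: `model_id`, `E_DA`, `R_mean`.
#' @export
efficiency_records <- function(collection, donor, acceptor, grid_spacing = 1.0,
                               nbr_radius = 3L,
                               mode = c("mean_distance", "mean_efficiency"),
                               n_pairs = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "structure_collection"))
  with_rng(seed, {
    rows <- lapply(collection$models, function(m) {
      ad <- compute_acv(m, donor, grid_spacing, nbr_radius)
      aa <- compute_acv(m, acceptor, grid_spacing, nbr_radius)
      efficiency_from_acvs(ad, aa, donor$forster_radius, mode, n_pairs)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Export an ACV point cloud
#'
#' `write_acv_pdb()` writes one HETATM pseudo-atom per grid point with the
#' weight in the B-factor column; `write_acv_tsv()` writes a plain table
#' (`x`, `y`, `z`, `weight`, `label`).
#'
#' @param acv An `acv` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_acv_pdb <- function(acv, path) {
  p <- acv$points
  lines <- sprintf(
    "HETATM%5d  D   ACV A   1    %8.3f%8.3f%8.3f  1.00%6.2f",
    seq_len(nrow(p)) %% 100000L, p$x, p$y, p$z,
    pmin(p$weight * 1000, 999.99)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_acv_pdb
#' @export
write_acv_tsv <- function(acv, path) {
  utils::write.table(acv$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
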