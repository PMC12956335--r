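# shared fixtures, built in code and cached for the session

.toy_cache <- new.env(parent = emptyenv())

toy_collection <- function(n = 6, linker = 6, stem = 4, seed = 11, spread = 1) {
  key <- paste(n, linker, stem, seed, spread, sep = "_")
  if (is.null(.toy_cache[[key]])) {
    spec <- fixture_spec(n, linker_length_nt = linker, stem_length_bp = stem,
                         seed = seed, spread = spread)
    coll <- generate_toy_construct(spec)
    attr(coll, "spec") <- spec
    .toy_cache[[key]] <- coll
  }
  .toy_cache[[key]]
}

toy_reference <- function(coll) {
  key <- paste0("ref_", paste(unlist(attr(coll, "spec")), collapse = "_"))
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- toy_kl_reference(attr(coll, "spec"))
  }
  .toy_cache[[key]]
}

# fixed-column PDB ATOM record
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM  ") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f", record, serial, nm,
          resname, chain, resno, x, y, z)
}

# rotation matrix about an arbitrary axis (Rodrigues)
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# bimodal synthetic efficiency records (two Gaussian modes, clamped to [0,1])
bimodal_records <- function(n, seed, means = c(0.3, 0.7), sd = 0.05) {
  withr::with_seed(seed, {
    e <- c(rnorm(ceiling(n / 2), means[1], sd), rnorm(floor(n / 2), means[2], sd))
    e <- pmin(pmax(e, 0), 1)
    data.frame(model_id = sprintf("s%04d", seq_len(n)), E_DA = e)
  })
}

# Independent brute-force eRMSD oracle: direct transcription of the published
# G-vector formula, plain loops, no shared code with the package internals.
ermsd_oracle <- function(model_a, model_b, resnos, chain = "A") {
  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  frames <- function(model) {
    lapply(sort(resnos), function(r) {
      at <- function(nm) {
        a <- model$atoms
        row <- a[a$chain == chain & a$resno == r & a$atom == nm, c("x", "y", "z")]
        as.numeric(row[1, ])
      }
      c2 <- at("C2"); c4 <- at("C4"); c6 <- at("C6")
      o <- (c2 + c4 + c6) / 3
      x <- c2 - o; x <- x / sqrt(sum(x^2))
      z <- cross3(x, c4 - o); z <- z / sqrt(sum(z^2))
      y <- cross3(z, x)
      list(o = o, M = rbind(x, y, z))
    })
  }
  gvec <- function(fr) {
    n <- length(fr)
    cutoff <- 2.4
    gamma <- pi / cutoff
    G <- array(0, c(n, n, 4))
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == k) next
      r <- as.numeric(fr[[j]]$M %*% (fr[[k]]$o - fr[[j]]$o)) / c(5, 5, 3)
      rho <- sqrt(sum(r^2))
      if (rho < cutoff) {
        G[j, k, ] <- c(sin(gamma * rho) * r / rho, 1 + cos(gamma * rho)) / gamma
      }
    }
    G
  }
  ga <- gvec(frames(model_a))
  gb <- gvec(frames(model_b))
  sqrt(sum((ga - gb)^2) / length(resnos))
}

# single-point ACV at a fixed position (exercises the Forster conversion)
point_acv <- function(xyz, id = "pt") {
  structure(
    list(points = data.frame(x = xyz[1], y = xyz[2], z = xyz[3],
                             weight = 1, label = "free"),
         mean_position = xyz, grid_origin = xyz, grid_spacing = 1,
         attachment_xyz = xyz, model_id = id, dye = NULL),
    class = "acv"
  )
}

# ball-shaped ACV: uniform weights on grid points within `radius` of `center`
ball_acv <- function(center, radius = 4, spacing = 2, id = "ball") {
  ax <- seq(-radius, radius, by = spacing)
  g <- expand.grid(x = ax, y = ax, z = ax)
  g <- g[sqrt(rowSums(g^2)) <= radius, ]
  structure(
    list(points = data.frame(x = g$x + center[1], y = g$y + center[2],
                             z = g$z + center[3],
                             weight = 1 / nrow(g), label = "free"),
         mean_position = center, grid_origin = center - radius,
         grid_spacing = spacing, attachment_xyz = center, model_id = id,
         dye = NULL),
    class = "acv"
  )
}
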