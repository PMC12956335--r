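#' Specification of a synthetic two-stem FRET construct
#'
#' Describes a toy RNA built from two rigid ideal duplex blocks joined by a
#' flexible single-stranded poly(A) linker, emulating a construct in which two
#' structured elements are bridged by an unstructured region so that the
#' inter-dye distance spans a broad range across models.
#'
#' @param n_models Number of models to generate (>= 1).
#' @param linker_length_nt Number of single-stranded linker residues.
#' @param stem_length_bp Base pairs per duplex block.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param spread Non-negative scalar scaling the Gaussian perturbations of the
#'   linker backbone; 0 gives identical, fully extended models.
#' @param stem_seq Sequence of duplex strand 1 (recycled/truncated to
#'   `stem_length_bp`); the partner strand is the Watson-Crick complement.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_models, linker_length_nt = 10L, stem_length_bp = 4L,
                         seed = 1L, spread = 1, stem_seq = "GGGG") {
  stopifnot(n_models >= 1, linker_length_nt >= 1, stem_length_bp >= 1,
            spread >= 0, is.numeric(seed))
  structure(
    list(n_models = as.integer(n_models),
         linker_length_nt = as.integer(linker_length_nt),
         stem_length_bp = as.integer(stem_length_bp),
         seed = as.integer(seed), spread = spread,
         stem_seq = toupper(stem_seq)),
    class = "fixture_spec"
  )
}

# --- idealized nucleobase templates ---------------------------------------
# Planar (z = 0) heavy-atom skeletons carrying only the atoms the pipeline
# needs: the ring system (eRMSD frame from C2/C4/C6), WC-edge atoms, the
# glycosidic nitrogen, C1', and exocyclic substituents. Coordinates are
# MMFF94-relaxed base geometries projected onto their best-fit plane, all in
# one handedness convention (N1->C2->N3 counterclockwise); C1' stands in for
# the sugar at the glycosidic bond.
BASE_TEMPLATES <- list(
  A = data.frame(
    atom = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9", "N6", "C1'"),
    x = c(2.0883, 1.1656, -0.1789, -0.5519, 0.2717, 1.6557, -0.4754, -1.7284, -1.8209, 2.6055, -3.0314),
    y = c(0.8780, 1.8657, 1.7592, 0.4691, -0.6451, -0.4037, -1.8078, -1.4012, -0.0366, -1.4179, 0.7404),
    z = 0),
  G = data.frame(
    atom = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9", "N2", "O6", "C1'"),
    x = c(1.9851, 1.6084, 0.3675, -0.5254, -0.2793, 1.1008, -1.4456, -2.3961, -1.8852, 2.6176, 1.4918, -2.6396),
    y = c(-0.2611, 1.0671, 1.4737, 0.4552, -0.8995, -1.3320, -1.6233, -0.7092, 0.5624, 1.9746, -2.4951, 1.7872),
    z = 0),
  C = data.frame(
    atom = c("N1", "C2", "N3", "C4", "C5", "C6", "N4", "O2", "C1'"),
    x = c(-1.1301, -0.6730, 0.6855, 1.5008, 1.0571, -0.2603, 2.8383, -1.4581, -2.5602),
    y = c(0.4771, -0.8460, -1.0636, -0.0571, 1.3503, 1.5413, -0.3439, -1.7917, 0.7335),
    z = 0),
  U = data.frame(
    atom = c("N1", "C2", "N3", "C4", "C5", "C6", "O2", "O4", "C1'"),
    x = c(-1.1229, -0.7334, 0.6208, 1.5893, 1.1116, -0.2029, -1.5099, 2.7874, -2.5400),
    y = c(0.4952, -0.8399, -1.0574, -0.0972, 1.2943, 1.5232, -1.7922, -0.3531, 0.8269),
    z = 0)
)

base_template <- function(base) {
  out <- BASE_TEMPLATES[[base]]
  if (is.null(out)) stop("unknown base: ", base)
  attr(out, "glyco") <- if (base %in% c("A", "G")) "N9" else "N1"
  out
}

.fretsel_cache <- new.env(parent = emptyenv())

# Solve the coplanar placement of the complementary base so the canonical
# edge hydrogen bonds and the C1'-C1' distance take standard values. The
# distance constraints admit two rigid-placement branches (one physical, one
# with the edges crossed and atoms overlapping); the branch with the largest
# minimum inter-base contact distance is the physical cis pair. Deterministic
# multi-start Nelder-Mead; cached after the first call.
wc_pair_template <- function(kind = c("GC", "AU")) {
  kind <- match.arg(kind)
  key <- paste0("wc_", kind)
  if (!is.null(.fretsel_cache[[key]])) return(.fretsel_cache[[key]])
  b1 <- base_template(substr(kind, 1, 1))
  b2 <- base_template(substr(kind, 2, 2))
  g1 <- attr(b1, "glyco")
  g2 <- attr(b2, "glyco")
  targets <- if (kind == "GC") {
    list(c("N1", "N3", "2.95"), c("O6", "N4", "2.91"), c("N2", "O2", "2.86"),
         c("C1'", "C1'", "10.4"))
  } else {
    list(c("N1", "N3", "2.82"), c("N6", "O4", "2.95"), c("C2", "O2", "3.5"),
         c("C1'", "C1'", "10.4"))
  }
  p2_0 <- as.matrix(b2[c("x", "y", "z")])
  xyz1 <- as.matrix(b1[c("x", "y", "z")])
  at1 <- function(name) as.numeric(b1[b1$atom == name, c("x", "y", "z")])
  place <- function(par) {
    th <- par[1]
    R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
    sweep(p2_0 %*% t(R), 2, c(par[2], par[3], 0), "+")
  }
  obj <- function(par) {
    p2 <- place(par)
    at2 <- function(name) as.numeric(p2[which(b2$atom == name)[1], ])
    sum(vapply(targets, function(tg) {
      (sqrt(sum((at1(tg[1]) - at2(tg[2]))^2)) - as.numeric(tg[3]))^2
    }, numeric(1)))
  }
  best <- NULL
  starts <- expand.grid(th = seq(0, 2 * pi, length.out = 25)[-25],
                        dx = c(5.8, 0, -5.8, 4, -4), dy = c(0, 5.8, -5.8, 4, -4))
  for (si in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[si, ]), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$value < 0.05) {
      p2 <- place(fit$par)
      mind <- min(sqrt(pmax(0, outer(rowSums(xyz1^2), rowSums(p2^2), "+") -
                              2 * xyz1 %*% t(p2))))
      if (mind >= 2.2) {   # the physical branch; the other one overlaps
        fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                            control = list(maxit = 4000, reltol = 1e-13))
        best <- list(par = fit$par, mind = mind)
        break
      }
    }
  }
  if (is.null(best)) stop("WC pair template construction failed for ", kind)
  p2 <- place(best$par)
  b2$x <- p2[, 1]; b2$y <- p2[, 2]; b2$z <- p2[, 3]
  # center the pair on the C1'-C1' midpoint (helix stacking origin)
  mid <- (at1("C1'") + as.numeric(b2[b2$atom == "C1'", c("x", "y", "z")])) / 2
  for (cc in c("x", "y", "z")) {
    b1[[cc]] <- b1[[cc]] - mid[match(cc, c("x", "y", "z"))]
    b2[[cc]] <- b2[[cc]] - mid[match(cc, c("x", "y", "z"))]
  }
  tmpl <- list(b1 = b1, b2 = b2, glyco1 = g1, glyco2 = g2)
  .fretsel_cache[[key]] <- tmpl
  tmpl
}

wc_partner <- function(b) c(A = "U", U = "A", G = "C", C = "G")[[b]]

rot_z <- function(th) cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))

# Rigid ideal duplex block: pairs stacked with A-form-like rise and twist.
# Local residue numbering: strand 1 = 1..s bottom-up, strand 2 = s+1..2s so
# that local residue j pairs with 2s+1-j. Dye-attachment carbons "CY" are
# grown from C1' of the requested local residues.
build_stem <- function(seq1, rise = 2.81, twist_deg = 32.7, attach_local = integer(0)) {
  s <- length(seq1)
  rows <- list()
  for (k in seq_len(s)) {
    b <- seq1[k]
    tm <- wc_pair_template(if (b %in% c("G", "C")) "GC" else "AU")
    swap <- b %in% c("C", "U")   # template strand 1 carries G or A
    first <- if (swap) tm$b2 else tm$b1
    second <- if (swap) tm$b1 else tm$b2
    R <- rot_z((k - 1) * twist_deg * pi / 180)
    lift <- c(0, 0, (k - 1) * rise)
    put <- function(df, resno, resname) {
      xyz <- sweep(as.matrix(df[c("x", "y", "z")]) %*% t(R), 2, lift, "+")
      data.frame(atom = df$atom, resname = resname, resno = resno, chain = "A",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
    rows[[length(rows) + 1L]] <- put(first, k, b)
    rows[[length(rows) + 1L]] <- put(second, 2L * s + 1L - k, wc_partner(b))
  }
  atoms <- do.call(rbind, rows)
  # crude backbone phosphate: radially outward from the helix axis at C1'
  c1 <- atoms[atoms$atom == "C1'", ]
  pr <- c1
  rxy <- sqrt(c1$x^2 + c1$y^2)
  pr$atom <- "P"
  pr$x <- c1$x * (rxy + 2.5) / rxy
  pr$y <- c1$y * (rxy + 2.5) / rxy
  pr$z <- c1$z + 1.0
  atoms <- rbind(atoms, pr)
  for (loc in attach_local) {
    c1i <- atoms[atoms$atom == "C1'" & atoms$resno == loc, ]
    gly <- atoms[atoms$atom %in% c("N1", "N9") & atoms$resno == loc, ]
    gly <- gly[if (c1i$resname[1] %in% c("A", "G")) gly$atom == "N9" else gly$atom == "N1", ]
    u <- c(c1i$x - gly$x, c1i$y - gly$y, c1i$z - gly$z)
    u <- u / sqrt(sum(u^2))
    atoms <- rbind(atoms, data.frame(
      atom = "CY", resname = c1i$resname[1], resno = loc, chain = "A",
      x = c1i$x + 1.54 * u[1], y = c1i$y + 1.54 * u[2], z = c1i$z + 1.54 * u[3]
    ))
  }
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  atoms
}

# orthonormal frame completion: any unit t -> (n, b) perpendicular pair
perp_frame <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n <- ref - t * sum(ref * t)
  n <- n / sqrt(sum(n^2))
  b <- c(t[2] * n[3] - t[3] * n[2],
         t[3] * n[1] - t[1] * n[3],
         t[1] * n[2] - t[2] * n[1])
  list(n = n, b = b)
}

#' Generate a synthetic two-stem construct collection
#'
#' Each model contains two copies of a rigid ideal duplex block (base-pair
#' list known by construction) joined by a single-stranded poly(A) linker
#' whose virtual-backbone bend/torsion angles receive Gaussian perturbations
#' scaled by `spread`, producing a broad distribution of inter-attachment
#' distances. Models with heavy-atom clashes (< 2 A between non-neighbour
#' residues) are rejected and redrawn. Donor and acceptor attachment carbons
#' ("CY") exist in every model.
#'
#' @param spec A [fixture_spec()].
#' @return A [structure_collection()] with attribute `construct`, a list with
#'   elements `stem1_pairs`, `stem2_pairs` (2-column matrices of paired
#'   residue numbers), `stem1_resnos`, `linker_resnos`, `donor`, `acceptor`
#'   (attachment descriptors `list(chain, resno, atom)`).
#' @export
generate_toy_construct <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  s <- spec$stem_length_bp
  L <- spec$linker_length_nt
  seq1 <- strsplit(spec$stem_seq, "")[[1]]
  seq1 <- rep(seq1, length.out = s)
  if (!all(seq1 %in% c("A", "C", "G", "U"))) stop("stem_seq must be RNA letters")
  stem1 <- build_stem(seq1, attach_local = s)           # donor on top of strand 1
  stem2 <- build_stem(seq1, attach_local = s)           # acceptor, same geometry
  ade <- base_template("A")
  step_len <- 5.9
  with_rng(spec$seed, {
    models <- vector("list", spec$n_models)
    for (im in seq_len(spec$n_models)) {
      for (try in 1:60) {
        atoms <- build_one_construct(stem1, stem2, ade, s, L, spec$spread, step_len)
        if (!has_clash(atoms)) break
        if (try == 60) stop("could not draw a clash-free model after 60 tries")
      }
      models[[im]] <- structure_model(sprintf("toy#%d", im), atoms, "fixture")
    }
    coll <- structure_collection(models)
    off2 <- 2L * s + L
    attr(coll, "construct") <- list(
      stem1_pairs = cbind(seq_len(s), 2L * s + 1L - seq_len(s)),
      stem2_pairs = cbind(off2 + seq_len(s), off2 + 2L * s + 1L - seq_len(s)),
      stem1_resnos = seq_len(2L * s),
      linker_resnos = 2L * s + seq_len(L),
      donor = list(chain = "A", resno = s, atom = "CY"),
      acceptor = list(chain = "A", resno = off2 + s, atom = "CY")
    )
    coll
  })
}

build_one_construct <- function(stem1, stem2, ade, s, L, spread, step_len) {
  # linker leaves the bottom end of stem 1 (local residue 2s) heading -z
  start <- as.numeric(stem1[stem1$atom == "C1'" & stem1$resno == 2L * s,
                            c("x", "y", "z")])
  t <- c(0, 0, -1)
  pts <- matrix(NA_real_, L + 1L, 3)
  dirs <- matrix(NA_real_, L + 1L, 3)
  p <- start
  for (k in seq_len(L + 1L)) {
    bend <- abs(spread * stats::rnorm(1, 0, 40 * pi / 180))
    bend <- min(bend, 2.0)
    psi <- stats::runif(1, 0, 2 * pi)
    fr <- perp_frame(t)
    t <- cos(bend) * t + sin(bend) * (cos(psi) * fr$n + sin(psi) * fr$b)
    t <- t / sqrt(sum(t^2))
    p <- p + step_len * t
    pts[k, ] <- p
    dirs[k, ] <- t
  }
  lk <- vector("list", L)
  for (k in seq_len(L)) {
    fr <- perp_frame(dirs[k, ])
    M <- cbind(fr$n, fr$b, dirs[k, ])
    c1 <- as.numeric(ade[ade$atom == "C1'", c("x", "y", "z")])
    xyz <- sweep(as.matrix(ade[c("x", "y", "z")]), 2, c1, "-") %*% t(M)
    xyz <- sweep(xyz, 2, pts[k, ], "+")
    res <- data.frame(atom = ade$atom, resname = "A", resno = 2L * s + k,
                      chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    pp <- (pts[k, ] + (if (k == 1) start else pts[k - 1L, ])) / 2 + 1.5 * fr$n
    res <- rbind(res, data.frame(atom = "P", resname = "A", resno = 2L * s + k,
                                 chain = "A", x = pp[1], y = pp[2], z = pp[3]))
    lk[[k]] <- res
  }
  # stem 2 rigidly placed at the linker end, its local helix axis (+z, the
  # stacking direction away from its residue-2s end) aligned to the final
  # linker direction so the duplex continues away from the linker
  tend <- dirs[L + 1L, ]
  fr <- perp_frame(tend)
  Rz <- cbind(fr$n, fr$b, tend)    # right-handed: n x b = t, so det(Rz) = +1
  anchor <- as.numeric(stem2[stem2$atom == "C1'" & stem2$resno == 2L * s,
                             c("x", "y", "z")])
  off2 <- 2L * s + L
  xyz2 <- as.matrix(stem2[c("x", "y", "z")]) %*% t(Rz)
  shift <- pts[L + 1L, ] - as.numeric(Rz %*% anchor)
  xyz2 <- sweep(xyz2, 2, shift, "+")
  st2 <- stem2
  st2$x <- xyz2[, 1]; st2$y <- xyz2[, 2]; st2$z <- xyz2[, 3]
  st2$resno <- st2$resno + off2
  rbind(stem1, do.call(rbind, lk), st2)
}

# heavy-atom clash between residues more than one position apart
has_clash <- function(atoms, cutoff = 2.0) {
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  near <- d < cutoff
  diag(near) <- FALSE
  if (!any(near)) return(FALSE)
  dr <- abs(outer(atoms$resno, atoms$resno, "-"))
  any(near & dr > 1L)
}

#' Generate a synthetic smFRET target distribution
#'
#' Draws `n_bursts` efficiencies from a Gaussian truncated to \[0, 1\]
#' (exact inverse-CDF sampling) and bins them at `bin_width`, emulating a
#' background- and gamma-corrected experimental efficiency histogram.
#'
#' @param mean,sd Mean and sd of the untruncated Gaussian (efficiency units).
#' @param n_bursts Number of draws.
#' @param bin_width Histogram bin width; must divide 1 evenly.
#' @param seed RNG seed.
#' @return A [target_distribution()] with attribute `draws` (the samples).
#' @export
generate_synthetic_smfret <- function(mean = 0.32, sd = 0.14, n_bursts = 1e4,
                                      bin_width = 0.05, seed = 1L) {
  stopifnot(mean >= 0, mean <= 1, sd > 0)
  m <- check_bin_count(bin_width)
  with_rng(seed, {
    lo <- stats::pnorm(0, mean, sd)
    hi <- stats::pnorm(1, mean, sd)
    u <- stats::runif(n_bursts, lo, hi)
    e <- stats::qnorm(u, mean, sd)
    e <- pmin(pmax(e, 0), 1)
    idx <- pmin(floor(e / bin_width), m - 1L) + 1L
    counts <- tabulate(idx, m)
    td <- target_distribution(counts / sum(counts), bin_width)
    attr(td, "draws") <- e
    td
  })
}

check_bin_count <- function(bin_width) {
  stopifnot(bin_width > 0, bin_width <= 1)
  m <- 1 / bin_width
  if (abs(m - round(m)) > 1e-9) stop("bin_width must divide 1 evenly")
  as.integer(round(m))
}

# Evaluate `code` under a private RNG stream; the global .Random.seed is
# restored afterwards. seed = NULL uses (and advances) the ambient stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
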