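# Build a prot_structure from bare atom specs, filling structural defaults.
mk_structure <- function(x, y, z, elety = "CB", resid = "ALA",
                         resno = seq_along(x), chain = "A",
                         radius = NA_real_, id = "fixture") {
  n <- length(x)
  atoms <- data.frame(
    chain = rep_len(chain, n), resno = rep_len(resno, n), insert = "",
    resid = rep_len(resid, n), elety = rep_len(elety, n), elesym = "C",
    x = x, y = y, z = z, o = 1, is_hetero = FALSE, is_hydrogen = FALSE,
    radius = rep_len(radius, n), stringsAsFactors = FALSE)
  epiunmask:::new_structure(id, atoms)
}

# Random blob of carbon-like atoms, one per residue, private RNG stream.
# A minimum separation of 2.8 A (a physical nonbonded contact distance)
# is enforced by rejection so atoms never interpenetrate unphysically.
rand_structure <- function(n, seed, spread = max(6, 3.5 * n^(1 / 3)),
                           min_sep = 2.8) {
  epiunmask:::with_seed(seed, {
    pts <- matrix(stats::runif(3, 0, spread), ncol = 3)
    tries <- 0
    while (nrow(pts) < n && (tries <- tries + 1) < 1e5) {
      cand <- stats::runif(3, 0, spread)
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
        (pts[, 3] - cand[3])^2
      if (all(d2 >= min_sep^2)) pts <- rbind(pts, cand)
    }
    mk_structure(pts[, 1], pts[, 2], pts[, 3], radius = 1.7,
                 resid = "GLY", elety = "CA")
  })
}

# Independent Monte-Carlo SASA oracle: uniform random points per sphere
# (rejection-free via normalised Gaussians), no Fibonacci lattice, no cell
# list. Only for tiny structures.
mc_sasa_total <- function(xyz, radius, probe = 1.4, n_mc = 1e5, seed = 42) {
  epiunmask:::with_seed(seed, {
    rext <- radius + probe
    total <- 0
    for (i in seq_len(nrow(xyz))) {
      g <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      p <- sweep(g * rext[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_mc)
      for (j in seq_len(nrow(xyz))[-i]) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        acc <- acc & d2 >= rext[j]^2
      }
      total <- total + mean(acc) * 4 * pi * rext[i]^2
    }
    total
  })
}

# Closed-form total SASA of two equal spheres of expanded radius R at
# centre distance d: each loses a spherical cap of height R - d/2.
two_sphere_analytic <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
}

# Brute-force probit MLE over a (intercept, slope) lattice, refined twice.
# Independent of glm: direct binomial log-likelihood evaluation.
probit_grid_mle <- function(dose, n, dead) {
  ld <- log10(dose)
  ll <- function(a, b) {
    p <- pmin(1 - 1e-12, pmax(1e-12, pnorm(a + b * ld)))
    sum(dead * log(p) + (n - dead) * log(1 - p))
  }
  a_rng <- c(-10, 10); b_rng <- c(0.05, 10)
  best <- c(NA, NA)
  for (pass in 1:3) {
    as <- seq(a_rng[1], a_rng[2], length.out = 61)
    bs <- seq(b_rng[1], b_rng[2], length.out = 61)
    val <- outer(as, bs, Vectorize(ll))
    ij <- which(val == max(val), arr.ind = TRUE)[1, ]
    best <- c(as[ij[1]], bs[ij[2]])
    da <- diff(a_rng) / 60; db <- diff(b_rng) / 60
    a_rng <- best[1] + c(-2, 2) * da
    b_rng <- pmax(1e-3, best[2] + c(-2, 2) * db)
  }
  list(intercept = best[1], slope = best[2], lc50 = 10^(-best[1] / best[2]))
}

# Write a minimal but valid PDB text fixture; returns the path.
write_mini_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, elety, alt, resid, chain, resno, x, y, z, occ, 0, element)
}
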