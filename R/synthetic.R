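# Run code with a private RNG stream: the caller's global .Random.seed is
# left untouched and a fixed seed always yields identical draws.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Paired two-state synthetic structures with planted buried residues
#'
#' Builds a compact pseudo-protein of single-atom glycine-like residues on
#' a cubic lattice. In state A every planted residue is enclosed by a shell
#' of occluding atoms (extra `SHL` residues on a sphere around it), making
#' it geometrically buried; in state B the shells are removed, so the
#' planted residues are exposed. All non-planted residues are identical in
#' the two states. The generator verifies the plant: each planted residue
#' must be buried (ratio below `buried_max`) in state A and exposed (ratio
#' above `exposed_min`) in state B, otherwise it errors with the achieved
#' ratios. Atoms are carbon-like with a single radius, so burial is
#' analytically controllable; structural realism is explicitly not a goal.
#'
#' @param n_residues Number of lattice residues (default 45).
#' @param planted Residue numbers to bury in state A; `NULL` draws
#'   `n_planted` of them with the seeded generator.
#' @param n_planted Number of plants when `planted` is `NULL`.
#' @param spacing Lattice spacing in angstrom (default 10).
#' @param shell_radius Occluding-shell radius in angstrom (default 4).
#' @param shell_atoms Atoms per occluding shell (default 32).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param out_dir If given, writes `state_A.pdb`, `state_B.pdb` and a
#'   `truth.json` sidecar there.
#' @param thresholds [exposure_thresholds()] used for the plant
#'   verification.
#' @return List with `state_a`, `state_b` (`prot_structure`s), `planted`
#'   (residue numbers), and `paths` when `out_dir` was given.
#' @export
make_paired_structures <- function(n_residues = 45, planted = NULL,
                                   n_planted = 3, spacing = 10,
                                   shell_radius = 4, shell_atoms = 32,
                                   seed = 1, out_dir = NULL,
                                   thresholds = exposure_thresholds()) {
  side <- ceiling(n_residues^(1 / 3))
  grid <- expand.grid(x = 0:(side - 1), y = 0:(side - 1), z = 0:(side - 1))
  grid <- grid[seq_len(n_residues), , drop = FALSE] * spacing
  if (is.null(planted)) {
    if (n_planted < 1) stop("need at least one planted residue")
    planted <- with_seed(seed, sort(sample(n_residues, n_planted)))
  }
  planted <- sort(unique(as.integer(planted)))
  if (!all(planted %in% seq_len(n_residues))) {
    stop("planted residue numbers must lie in 1..n_residues")
  }
  core <- data.frame(
    chain = "A", resno = seq_len(n_residues), insert = "", resid = "GLY",
    elety = "CA", elesym = "C",
    x = grid$x, y = grid$y, z = grid$z,
    o = 1, is_hetero = FALSE, is_hydrogen = FALSE, radius = NA_real_,
    stringsAsFactors = FALSE
  )
  shells <- do.call(rbind, lapply(seq_along(planted), function(k) {
    p <- planted[k]
    sp <- sphere_points(shell_atoms) * shell_radius
    data.frame(
      chain = "A", resno = 900L + seq_len(shell_atoms) + shell_atoms * k,
      insert = "", resid = "SHL", elety = "C", elesym = "C",
      x = sp[, 1] + core$x[p], y = sp[, 2] + core$y[p],
      z = sp[, 3] + core$z[p],
      o = 1, is_hetero = FALSE, is_hydrogen = FALSE, radius = NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  sa <- new_structure("synthetic_state_A", rbind(core, shells),
                      "synthetic paired-structure generator, state A")
  sb <- new_structure("synthetic_state_B", core,
                      "synthetic paired-structure generator, state B")
  ta <- exposure_table(shrake_rupley(assign_radii(sa)),
                       thresholds = thresholds)
  tb <- exposure_table(shrake_rupley(assign_radii(sb)),
                       thresholds = thresholds)
  ra <- ta$ratio[match(planted, ta$resno)]
  rb <- tb$ratio[match(planted, tb$resno)]
  if (any(ra >= thresholds$buried_max)) {
    stop("shell too sparse/small to bury plant(s) ",
         paste(planted[ra >= thresholds$buried_max], collapse = ", "),
         "; achieved state-A ratio(s) ",
         paste(round(ra[ra >= thresholds$buried_max], 1), collapse = ", "),
         "%")
  }
  if (any(rb <= thresholds$exposed_min)) {
    stop("planted residue(s) not exposed in state B; achieved ratio(s) ",
         paste(round(rb[rb <= thresholds$exposed_min], 1), collapse = ", "),
         "%")
  }
  out <- list(state_a = sa, state_b = sb, planted = planted)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pa <- file.path(out_dir, "state_A.pdb")
    pb <- file.path(out_dir, "state_B.pdb")
    pt <- file.path(out_dir, "truth.json")
    write_structure(sa, pa)
    write_structure(sb, pb)
    jsonlite::write_json(list(kind = "paired_structures", seed = seed,
                              planted = planted,
                              shell_radius = shell_radius,
                              spacing = spacing),
                         pt, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- c(state_a = pa, state_b = pb, truth = pt)
  }
  out
}

#' Synthetic one-site saturation binding curve
#'
#' Responses follow B(x) = Bmax * x / (Kd + x) plus iid Gaussian noise.
#'
#' @param kd,bmax True parameters (positive).
#' @param conc Concentrations; must span the true Kd (max > Kd) so the
#'   curve approaches saturation.
#' @param sd Gaussian noise standard deviation (response units).
#' @param replicates Replicates per concentration.
#' @param seed RNG seed.
#' @param out_file Optional CSV path (`conc_nM`, `response`, `replicate`);
#'   a `truth.json` sidecar is written next to it.
#' @return Data frame with columns `conc_nM`, `response`, `replicate`;
#'   the truth parameters are attached as attribute `"truth"`.
#' @export
make_binding_curve <- function(kd = 29, bmax = 1,
                               conc = 3 * 2^(0:7), sd = 0.05,
                               replicates = 3, seed = 1, out_file = NULL) {
  if (kd <= 0 || bmax <= 0) stop("kd and bmax must be positive")
  if (max(conc) <= kd) {
    warning("concentration range does not span the true Kd; ",
            "the curve will look near-linear")
  }
  x <- rep(conc, times = replicates)
  repl <- rep(seq_len(replicates), each = length(conc))
  y0 <- bmax * x / (kd + x)
  y <- with_seed(seed, y0 + stats::rnorm(length(x), 0, sd))
  out <- data.frame(conc_nM = x, response = y, replicate = repl)
  attr(out, "truth") <- list(kind = "binding_curve", kd = kd, bmax = bmax,
                             sd = sd, seed = seed)
  if (!is.null(out_file)) {
    utils::write.csv(out, out_file, row.names = FALSE)
    jsonlite::write_json(attr(out, "truth"),
                         sub("\\.csv$", "_truth.json", out_file),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Synthetic probit dose-mortality bioassay
#'
#' Deaths per dose are Binomial(n, Phi(slope * (log10 d - log10 lc50))), so
#' the kill probability at d = lc50 is exactly one half.
#'
#' @param lc50,slope True LC50 (dose units) and probit slope per log10 dose.
#' @param doses Dose vector (> 0).
#' @param n Subjects per dose (scalar or vector).
#' @param seed RNG seed.
#' @param out_file Optional CSV path (`dose`, `n`, `dead`) with truth
#'   sidecar.
#' @return Data frame `dose`, `n`, `dead`, with truth attribute.
#' @export
make_bioassay <- function(lc50 = 15, slope = 2,
                          doses = c(1.9, 5.6, 17, 50, 150, 450),
                          n = 144, seed = 1, out_file = NULL) {
  if (lc50 <= 0 || slope <= 0) stop("lc50 and slope must be positive")
  if (any(doses <= 0)) stop("doses must be > 0")
  n <- rep_len(n, length(doses))
  p <- stats::pnorm(slope * (log10(doses) - log10(lc50)))
  dead <- with_seed(seed, stats::rbinom(length(doses), n, p))
  out <- data.frame(dose = doses, n = n, dead = dead)
  attr(out, "truth") <- list(kind = "bioassay", lc50 = lc50, slope = slope,
                             seed = seed)
  if (!is.null(out_file)) {
    utils::write.csv(out, out_file, row.names = FALSE)
    jsonlite::write_json(attr(out, "truth"),
                         sub("\\.csv$", "_truth.json", out_file),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Synthetic log-normal cell-area populations
#'
#' Emulates per-cell area tables from segmented microscopy images: a
#' control and a treated group of images, log-normal cell areas, with the
#' treated group optionally thinned (mortality: each cell is removed
#' independently with probability `thinning`) and size-shifted (swelling:
#' areas multiplied by `1 + size_shift`).
#'
#' @param n_images Images per group.
#' @param cells_per_image Expected control cells per image (Poisson).
#' @param meanlog,sdlog Log-normal parameters of the control area
#'   distribution (area units are arbitrary, e.g. px^2).
#' @param thinning Treated-group cell removal probability in `[0, 1)`.
#' @param size_shift Relative treated-area increase (0.3 = 30 percent).
#' @param seed RNG seed.
#' @param out_file Optional CSV path (`group`, `image_id`, `cell_id`,
#'   `area`) with truth sidecar.
#' @return Data frame `group`, `image_id`, `cell_id`, `area`, truth
#'   attribute attached.
#' @export
make_cell_population <- function(n_images = 10, cells_per_image = 100,
                                 meanlog = 5, sdlog = 0.4,
                                 thinning = 0, size_shift = 0, seed = 1,
                                 out_file = NULL) {
  if (thinning < 0 || thinning >= 1) stop("thinning must be in [0, 1)")
  out <- with_seed(seed, {
    rows <- lapply(c("control", "treated"), function(grp) {
      lam <- cells_per_image * if (grp == "treated") 1 - thinning else 1
      do.call(rbind, lapply(seq_len(n_images), function(img) {
        k <- stats::rpois(1, lam)
        if (k == 0L) return(NULL)
        area <- stats::rlnorm(k, meanlog, sdlog)
        if (grp == "treated") area <- area * (1 + size_shift)
        data.frame(group = grp, image_id = img, cell_id = seq_len(k),
                   area = area, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  attr(out, "truth") <- list(kind = "cell_population", thinning = thinning,
                             size_shift = size_shift, seed = seed)
  if (!is.null(out_file)) {
    utils::write.csv(out, out_file, row.names = FALSE)
    jsonlite::write_json(attr(out, "truth"),
                         sub("\\.csv$", "_truth.json", out_file),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
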