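#' Deterministic quadrature points on the unit sphere
#'
#' Generates `n` points by the Fibonacci (golden-spiral) lattice. The lattice
#' is deterministic: the same `n` always yields the same point set, and the
#' points are close to uniformly distributed for any `n`.
#'
#' @param n Number of points (minimum 12).
#' @return An `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 12) {
    stop("n must be a single number >= 12")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- i * ga
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Shrake-Rupley quadrature parameters
#'
#' @param probe_radius Probe sphere radius in angstrom (1.4 approximates a
#'   water molecule).
#' @param n_points Quadrature points per atom. 960 gives isolated-sphere
#'   areas accurate to well under 1 percent.
#' @return A `sasa_params` object.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 12) stop("n_points must be >= 12")
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 point_scheme = "fibonacci"),
            class = "sasa_params")
}

#' Solvent-accessible surface area by Shrake-Rupley quadrature
#'
#' For every atom, `n_points` test points are placed on the expanded sphere
#' of radius (van der Waals radius + probe radius); a point is accessible if
#' it lies outside every neighbouring atom's expanded sphere, and the atom's
#' area is the accessible fraction times the expanded-sphere area
#' 4*pi*(r+p)^2. Neighbour candidates come from a grid cell list with cutoff
#' r_i + r_j + 2*probe, so runtime scales linearly with atom count for
#' globular structures.
#'
#' @param s A `prot_structure` with radii assigned (see [assign_radii()]).
#' @param params A [sasa_params()] object.
#' @return A `sasa_result`: list with `atoms` (the atom table plus an `area`
#'   column, in square angstrom), `residues` (per-residue `total` and
#'   `sidechain` aggregates; for glycine the side-chain scope is the CA
#'   area), `params`, and `context` (structure id plus chain subset).
#' @export
shrake_rupley <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "prot_structure"))
  a <- s$atoms
  if (any(is.na(a$radius))) {
    i <- which(is.na(a$radius))[1]
    stop("atom without radius: ", a$chain[i], "/", a$resid[i], a$resno[i],
         "/", a$elety[i], "; run assign_radii() first")
  }
  n <- nrow(a)
  pts <- sphere_points(params$n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rext <- a$radius + params$probe_radius
  nb <- neighbour_pairs(xyz, a$radius, params$probe_radius)
  area <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rext[i]
    js <- nb[[i]]
    if (length(js) == 0L) {
      area[i] <- 4 * pi * ri^2
      next
    }
    px <- pts[, 1] * ri + xyz[i, 1]
    py <- pts[, 2] * ri + xyz[i, 2]
    pz <- pts[, 3] * ri + xyz[i, 3]
    acc <- rep(TRUE, params$n_points)
    for (j in js) {
      d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      acc <- acc & (d2 >= rext[j]^2)
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / params$n_points * 4 * pi * ri^2
  }
  a$area <- area
  res <- aggregate_residues(a)
  structure(list(atoms = a, residues = res, params = params,
                 context = paste0(s$id, " [",
                                  paste(unique(a$chain), collapse = ""), "]")),
            class = "sasa_result")
}

# Grid cell list: returns, for each atom, the indices of atoms within
# r_i + r_j + 2*probe of it (candidates pre-filtered by exact distance).
neighbour_pairs <- function(xyz, radius, probe) {
  n <- nrow(xyz)
  cutmax <- 2 * max(radius) + 2 * probe
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutmax)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  split_idx <- split(seq_len(n), key)
  cellkeys <- as.numeric(names(split_idx))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- vector("list", n)
  for (ci in seq_along(split_idx)) {
    idx <- split_idx[[ci]]
    c0 <- cell[idx[1], ]
    neigh_keys <- (c0[1] + offs[, 1]) + 1e4 * (c0[2] + offs[, 2]) +
      1e8 * (c0[3] + offs[, 3])
    cand <- unlist(split_idx[match(neigh_keys, cellkeys)], use.names = FALSE)
    cand <- cand[!is.na(cand)]
    for (i in idx) {
      js <- cand[cand != i]
      if (length(js) > 0L) {
        d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
          (xyz[js, 3] - xyz[i, 3])^2
        cut <- (radius[i] + radius[js] + 2 * probe)^2
        js <- js[d2 < cut]
      }
      nb[[i]] <- js
    }
  }
  nb
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

aggregate_residues <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  side <- !(a$elety %in% BACKBONE_ATOMS) | (a$resid == "GLY" & a$elety == "CA")
  res <- data.frame(
    chain = a$chain[first],
    resno = a$resno[first],
    insert = a$insert[first],
    resid = a$resid[first],
    total = as.numeric(tapply(a$area, factor(key, levels = key[first]), sum)),
    stringsAsFactors = FALSE
  )
  sc <- tapply(a$area * side, factor(key, levels = key[first]), sum)
  res$sidechain <- as.numeric(sc)
  rownames(res) <- NULL
  res
}

#' Look up one residue's aggregated surface area
#'
#' @param sr A `sasa_result`.
#' @param resno Author residue number.
#' @param chain Chain identifier (may be omitted when unambiguous).
#' @param scope `"total"` (all atoms) or `"sidechain"` (atoms outside
#'   N/CA/C/O/OXT; for glycine, the CA area).
#' @param insert Insertion code, default `""`.
#' @return Area in square angstrom.
#' @export
residue_area <- function(sr, resno, chain = NULL,
                         scope = c("total", "sidechain"), insert = "") {
  stopifnot(inherits(sr, "sasa_result"))
  scope <- match.arg(scope)
  r <- sr$residues
  hit <- r$resno == resno & r$insert == insert
  if (!is.null(chain)) hit <- hit & r$chain == chain
  if (sum(hit) == 0L) {
    stop("residue ", resno, if (!is.null(chain)) paste0(" chain ", chain),
         " not found in SASA result")
  }
  if (sum(hit) > 1L) {
    stop("residue ", resno, " is ambiguous across chains ",
         paste(r$chain[hit], collapse = ", "), "; give chain=")
  }
  r[[scope]][hit]
}

#' Write a per-residue SASA table as TSV
#'
#' Columns: structure_id, chain, resno, resname, total_A2, sidechain_A2.
#'
#' @param sr A `sasa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(sr, path) {
  r <- sr$residues
  out <- data.frame(structure_id = sub(" \\[.*", "", sr$context),
                    chain = r$chain, resno = r$resno, resname = r$resid,
                    total_A2 = round(r$total, 2),
                    sidechain_A2 = round(r$sidechain, 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
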