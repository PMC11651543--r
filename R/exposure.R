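#' Gly-X-Gly reference areas for relative solvent accessibility
#'
#' `default_reference_scale()` loads the shipped theoretical maximum-ASA
#' table (Tien et al. 2013 values, random-coil Gly-X-Gly context);
#' `read_reference_scale()` reads a user table from TSV with columns
#' `resname` and `max_asa`.
#'
#' @param path TSV path.
#' @param name Scale label.
#' @return A `reference_scale` object (named numeric vector of reference
#'   areas in square angstrom, indexed by 3-letter residue code).
#' @export
read_reference_scale <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("resname", "max_asa") %in% names(tab))) {
    stop("reference scale TSV must have columns resname, max_asa")
  }
  v <- stats::setNames(tab$max_asa, toupper(tab$resname))
  if (any(v <= 50 | v >= 400)) {
    stop("reference areas must lie in (50, 400) square angstrom")
  }
  structure(list(name = name, by_residue = v), class = "reference_scale")
}

#' @rdname read_reference_scale
#' @export
default_reference_scale <- function() {
  read_reference_scale(
    system.file("extdata", "max_asa_gxg.tsv", package = "epiunmask"),
    name = "theoretical_gxg")
}

#' Relative exposure of a residue, in percent of its reference area
#'
#' @param area Absolute SASA in square angstrom.
#' @param resid 3-letter residue code.
#' @param scale A `reference_scale`.
#' @return 100 * area / reference. Not capped at 100: residues in extended
#'   or terminal contexts can exceed their random-coil reference.
#' @export
exposure_ratio <- function(area, resid, scale = default_reference_scale()) {
  stopifnot(inherits(scale, "reference_scale"))
  ref <- scale$by_residue[toupper(resid)]
  if (any(is.na(ref))) {
    stop("residue code(s) absent from reference scale '", scale$name, "': ",
         paste(unique(resid[is.na(ref)]), collapse = ", "))
  }
  unname(100 * area / ref)
}

#' Exposure classification thresholds
#'
#' A residue is solvent-exposed if its surface ratio strictly exceeds
#' `exposed_min` percent and buried if strictly below `buried_max` percent;
#' everything else (including the boundary values themselves) is
#' intermediate.
#'
#' @param exposed_min Exposed threshold in percent (default 50).
#' @param buried_max Buried threshold in percent (default 20).
#' @export
exposure_thresholds <- function(exposed_min = 50, buried_max = 20) {
  if (!(0 < buried_max && buried_max < exposed_min && exposed_min < 100)) {
    stop("need 0 < buried_max < exposed_min < 100")
  }
  structure(list(exposed_min = exposed_min, buried_max = buried_max),
            class = "exposure_thresholds")
}

#' Classify surface ratios as exposed, buried or intermediate
#'
#' @param ratio Surface ratio(s) in percent (>= 0).
#' @param thresholds An [exposure_thresholds()] object.
#' @return Character vector over `{"exposed", "buried", "intermediate"}`.
#' @export
classify_exposure <- function(ratio, thresholds = exposure_thresholds()) {
  stopifnot(inherits(thresholds, "exposure_thresholds"), all(ratio >= 0))
  out <- rep("intermediate", length(ratio))
  out[ratio > thresholds$exposed_min] <- "exposed"
  out[ratio < thresholds$buried_max] <- "buried"
  out
}

#' Per-residue exposure table for one conformational state
#'
#' Aggregates a SASA result into one exposure record per residue number.
#' When the structure is a homo-oligomer (the same residue numbers repeated
#' across symmetry-equivalent chains), areas are averaged over chains by
#' default so that local deposition differences between copies do not decide
#' a classification.
#'
#' @param sr A `sasa_result`.
#' @param scale Reference scale for ratio normalisation.
#' @param thresholds Classification thresholds.
#' @param scope `"total"` or `"sidechain"` area for the ratio.
#' @param average_chains Average over chains sharing a residue number
#'   (default `TRUE`). With `FALSE`, the table keeps one row per chain and
#'   residue.
#' @return A data frame with columns `resno`, `resid`, `abs_area`, `ratio`,
#'   `klass` (and `chain` when `average_chains = FALSE`).
#' @export
exposure_table <- function(sr, scale = default_reference_scale(),
                           thresholds = exposure_thresholds(),
                           scope = c("total", "sidechain"),
                           average_chains = TRUE) {
  stopifnot(inherits(sr, "sasa_result"))
  scope <- match.arg(scope)
  r <- sr$residues
  r <- r[toupper(r$resid) %in% names(scale$by_residue), , drop = FALSE]
  if (nrow(r) == 0L) stop("no residues with a reference-scale entry")
  if (average_chains) {
    key <- paste(r$resno, r$insert, r$resid, sep = "\r")
    first <- !duplicated(key)
    area <- as.numeric(tapply(r[[scope]], factor(key, levels = key[first]),
                              mean))
    out <- data.frame(resno = r$resno[first], insert = r$insert[first],
                      resid = r$resid[first], abs_area = area,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chain = r$chain, resno = r$resno, insert = r$insert,
                      resid = r$resid, abs_area = r[[scope]],
                      stringsAsFactors = FALSE)
  }
  out$ratio <- exposure_ratio(out$abs_area, out$resid, scale)
  out$klass <- classify_exposure(out$ratio, thresholds)
  out[order(out$resno, out$insert), , drop = FALSE]
}

#' Pair per-residue exposure tables of two conformational states
#'
#' Residues are matched by (residue number + offset, residue name); a
#' residue number present in both states but with different residue names is
#' excluded and reported, as are residues present in only one state.
#'
#' @param tab_a,tab_b Exposure tables from [exposure_table()] (state A, e.g.
#'   protoxin, and state B, e.g. activated toxin).
#' @param offset Added to state A residue numbers before matching, for
#'   depositions with shifted numbering.
#' @return A `paired_exposure` object: list with `pairs` (data frame with
#'   `resno`, `resid`, `ratio_A`, `ratio_B`, `abs_A`, `abs_B`), `unpaired_A`,
#'   `unpaired_B`, `mismatched` (residue numbers whose names differ).
#' @export
pair_states <- function(tab_a, tab_b, offset = 0) {
  if (nrow(tab_a) == 0L || nrow(tab_b) == 0L) {
    stop("both exposure tables must be non-empty")
  }
  ka <- paste(tab_a$resno + offset, tab_a$insert, sep = "\r")
  kb <- paste(tab_b$resno, tab_b$insert, sep = "\r")
  m <- match(ka, kb)
  hit <- !is.na(m)
  same <- hit & tab_a$resid == tab_b$resid[m]
  mism <- hit & !same
  pairs <- data.frame(
    resno = tab_b$resno[m[same]],
    insert = tab_b$insert[m[same]],
    resid = tab_a$resid[same],
    ratio_A = tab_a$ratio[same], ratio_B = tab_b$ratio[m[same]],
    abs_A = tab_a$abs_area[same], abs_B = tab_b$abs_area[m[same]],
    stringsAsFactors = FALSE
  )
  if (nrow(pairs) == 0L) {
    stop("no residues could be paired between the two states",
         " (check numbering offset)")
  }
  structure(list(
    pairs = pairs[order(pairs$resno), , drop = FALSE],
    unpaired_A = tab_a$resno[!hit],
    unpaired_B = tab_b$resno[!(seq_len(nrow(tab_b)) %in% m)],
    mismatched = tab_b$resno[m[mism]]
  ), class = "paired_exposure")
}

#' Detect residues that become solvent-exposed between two states
#'
#' Two criteria are evaluated per paired residue. The relative-ratio
#' criterion flags a residue whose surface ratio strictly exceeds
#' `exposed_min` in state B but is strictly below it in state A
#' (mirroring a GETAREA-style analysis of exposure ratios). The
#' absolute-area criterion flags a residue whose absolute area grows by at
#' least `abs_gain_factor` and ends above `abs_min` square angstrom in state
#' B (mirroring a PDBePISA-style reading of raw areas). The consensus flag
#' is the conjunction of the two.
#'
#' @param paired A `paired_exposure` from [pair_states()].
#' @param thresholds [exposure_thresholds()].
#' @param abs_gain_factor Minimum multiplicative growth of the absolute area
#'   (default 1.5).
#' @param abs_min Minimum state-B absolute area in square angstrom
#'   (default 50).
#' @return The `pairs` data frame with added logical columns
#'   `becomes_exposed_ratio`, `becomes_exposed_abs`, `consensus`.
#' @export
becomes_exposed <- function(paired, thresholds = exposure_thresholds(),
                            abs_gain_factor = 1.5, abs_min = 50) {
  stopifnot(inherits(paired, "paired_exposure"))
  p <- paired$pairs
  t0 <- thresholds$exposed_min
  p$becomes_exposed_ratio <- (p$ratio_B > t0) & (p$ratio_A < t0)
  p$becomes_exposed_abs <- (p$abs_B >= abs_gain_factor * p$abs_A) &
    (p$abs_B > abs_min)
  p$consensus <- p$becomes_exposed_ratio & p$becomes_exposed_abs
  p
}

#' Domain interval maps
#'
#' `read_domain_map()` reads a TSV with columns `domain`, `start`, `end`
#' (author residue numbers, inclusive, non-overlapping);
#' `vip3aa_domain_map()` returns the shipped Vip3Aa five-domain
#' architecture (domain III = 328-532).
#'
#' @param path TSV path.
#' @return A data frame with columns `domain`, `start`, `end`.
#' @export
read_domain_map <- function(path) {
  dm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("domain", "start", "end") %in% names(dm))) {
    stop("domain map TSV needs columns domain, start, end")
  }
  dm <- dm[order(dm$start), , drop = FALSE]
  if (any(dm$start > dm$end)) stop("domain start must be <= end")
  if (nrow(dm) > 1L && any(dm$start[-1] <= dm$end[-nrow(dm)])) {
    stop("domain intervals must not overlap")
  }
  dm
}

#' @rdname read_domain_map
#' @export
vip3aa_domain_map <- function() {
  read_domain_map(system.file("extdata", "vip3aa_domains.tsv",
                              package = "epiunmask"))
}

assign_domain <- function(resno, dm) {
  out <- rep("unassigned", length(resno))
  for (k in seq_len(nrow(dm))) {
    out[resno >= dm$start[k] & resno <= dm$end[k]] <- dm$domain[k]
  }
  out
}

#' Per-domain exposure counts
#'
#' For a single-state exposure table, counts exposed residues per domain;
#' for a two-state differential table (output of [becomes_exposed()]),
#' additionally counts consensus becomes-exposed residues per domain.
#' Residues outside every interval are counted under `"unassigned"`.
#'
#' @param records An exposure table or differential table.
#' @param dm Domain map data frame.
#' @param thresholds [exposure_thresholds()], used when `records` carries a
#'   single-state `ratio` column only.
#' @return A data frame with columns `domain`, `n_residues`, `n_exposed`
#'   and, for differential input, `n_becomes_exposed`.
#' @export
domain_summary <- function(records, dm = vip3aa_domain_map(),
                           thresholds = exposure_thresholds()) {
  doms <- c(dm$domain, "unassigned")
  if (nrow(records) == 0L) {
    out <- data.frame(domain = doms, n_residues = 0L, n_exposed = 0L)
    if (TRUE) out$n_becomes_exposed <- 0L
    return(out)
  }
  d <- assign_domain(records$resno, dm)
  f <- factor(d, levels = doms)
  out <- data.frame(domain = doms,
                    n_residues = as.integer(table(f)))
  if ("consensus" %in% names(records)) {
    shared_exposed <- records$ratio_A > thresholds$exposed_min &
      records$ratio_B > thresholds$exposed_min
    out$n_exposed <- as.integer(tapply(shared_exposed, f, sum, default = 0))
    out$n_becomes_exposed <- as.integer(tapply(records$consensus, f, sum,
                                               default = 0))
  } else {
    exposed <- records$klass == "exposed"
    out$n_exposed <- as.integer(tapply(exposed, f, sum, default = 0))
  }
  out
}

#' Overlapping-fragment binding sets
#'
#' `fragment_set()` builds one from vectors; `read_fragment_set()` reads a
#' TSV with columns `name`, `start`, `end`, `binds` (0/1);
#' `vip3aa_fragment_set()` returns the shipped Vip3Aa F4-F9 fragment table
#' with the observed brush-border-membrane binding outcomes (F6, F7 and F8
#' bind).
#'
#' @param name Fragment names (unique).
#' @param start,end Residue-number bounds, `start < end`.
#' @param binds Logical (or 0/1) binding outcome per fragment.
#' @param path TSV path.
#' @return A `fragment_set` data frame.
#' @export
fragment_set <- function(name, start, end, binds) {
  if (anyDuplicated(name)) stop("fragment names must be unique")
  if (any(start >= end)) stop("fragment start must be < end")
  structure(data.frame(name = as.character(name), start = as.integer(start),
                       end = as.integer(end), binds = as.logical(binds),
                       stringsAsFactors = FALSE),
            class = c("fragment_set", "data.frame"))
}

#' @rdname fragment_set
#' @export
read_fragment_set <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE)
  fragment_set(f$name, f$start, f$end, f$binds)
}

#' @rdname fragment_set
#' @export
vip3aa_fragment_set <- function() {
  read_fragment_set(system.file("extdata", "vip3aa_fragments.tsv",
                                package = "epiunmask"))
}

#' Infer candidate binding regions from fragment overlaps
#'
#' A candidate region is the intersection of a pair of binding fragments:
#' when two overlapping fragments both retain binding, the shared interval
#' is the parsimonious location of a binding site. Intersections with
#' non-binding fragments are not subtracted, because a fragment may fail to
#' bind for reasons other than lacking the site (misfolding, truncated
#' epitope). The output is independent of fragment input order.
#'
#' @param frags A `fragment_set`.
#' @return Data frame with columns `start`, `end`, `support` (the fragment
#'   pair), sorted by `start`. Zero rows (with a warning) when fewer than
#'   one binding fragment is present or no binding pair overlaps.
#' @export
infer_binding_regions <- function(frags) {
  stopifnot(inherits(frags, "fragment_set"))
  b <- frags[frags$binds, , drop = FALSE]
  b <- b[order(b$start, b$name), , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      support = character(0))
  if (nrow(b) == 0L) {
    warning("no binding fragments; nothing to infer")
    return(empty)
  }
  out <- empty
  if (nrow(b) >= 2L) {
    for (i in seq_len(nrow(b) - 1L)) {
      for (j in (i + 1L):nrow(b)) {
        s <- max(b$start[i], b$start[j])
        e <- min(b$end[i], b$end[j])
        if (s <= e) {
          out <- rbind(out, data.frame(
            start = s, end = e,
            support = paste(b$name[i], b$name[j], sep = "+")))
        }
      }
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}
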