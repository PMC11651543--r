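#' Run the full two-state exposure pipeline
#'
#' Orchestrates: parse (if paths), radii assignment, Shrake-Rupley SASA on
#' both conformations, exposure normalisation, state pairing, dual-criterion
#' becomes-exposed detection, per-domain counts, and (when `residues` is
#' given) anchor-atom distance tables in both states.
#'
#' @param state_a,state_b Structure file paths or `prot_structure` objects
#'   (state A = e.g. protoxin, state B = e.g. activated toxin).
#' @param chains Chain subset (`"all"` or chain ids) defining the SASA
#'   context.
#' @param scale Reference scale ([default_reference_scale()]).
#' @param thresholds [exposure_thresholds()].
#' @param scope `"total"` or `"sidechain"` ratio scope.
#' @param abs_gain_factor,abs_min Absolute-area criterion constants, see
#'   [becomes_exposed()].
#' @param residues Optional residue keys for the distance block.
#' @param rule [atom_rule()] for distances.
#' @param domain_map Domain map for [domain_summary()]; `NULL` skips domain
#'   counts.
#' @param params [sasa_params()].
#' @param offset Residue-numbering offset A -> B for [pair_states()].
#' @param out_dir Optional directory: writes `differential.tsv`,
#'   `consensus.tsv`, `domains.tsv`, `distances_A/B.tsv` and
#'   `summary.json`.
#' @return An `exposure_report`: list with `differential` (per-residue
#'   table with flags), `consensus` (becomes-exposed subset), `domains`,
#'   `distances` (list A/B or `NULL`), `unpaired`, `params`.
#' @export
run_exposure_pipeline <- function(state_a, state_b, chains = "all",
                                  scale = default_reference_scale(),
                                  thresholds = exposure_thresholds(),
                                  scope = "total",
                                  abs_gain_factor = 1.5, abs_min = 50,
                                  residues = NULL, rule = atom_rule(),
                                  domain_map = NULL,
                                  params = sasa_params(), offset = 0,
                                  out_dir = NULL) {
  load_state <- function(x) {
    if (inherits(x, "prot_structure")) x else parse_structure(x)
  }
  sa <- select_chains(load_state(state_a), chains)
  sb <- select_chains(load_state(state_b), chains)
  sra <- shrake_rupley(assign_radii(sa), params)
  srb <- shrake_rupley(assign_radii(sb), params)
  ta <- exposure_table(sra, scale, thresholds, scope)
  tb <- exposure_table(srb, scale, thresholds, scope)
  paired <- pair_states(ta, tb, offset)
  diff <- becomes_exposed(paired, thresholds, abs_gain_factor, abs_min)
  consensus <- diff[diff$consensus, , drop = FALSE]
  domains <- if (!is.null(domain_map)) {
    domain_summary(diff, domain_map, thresholds)
  }
  distances <- NULL
  if (!is.null(residues) && length(residues) >= 2L) {
    distances <- list(
      A = pairwise_distance_table(sa, residues, rule = rule),
      B = pairwise_distance_table(sb, residues, rule = rule)
    )
  }
  rep <- structure(list(
    differential = diff, consensus = consensus, domains = domains,
    distances = distances,
    unpaired = list(A = paired$unpaired_A, B = paired$unpaired_B,
                    mismatched = paired$mismatched),
    params = list(context_A = sra$context, context_B = srb$context,
                  scope = scope, thresholds = unclass(thresholds),
                  abs_gain_factor = abs_gain_factor, abs_min = abs_min,
                  sasa = unclass(params), scale = scale$name)
  ), class = "exposure_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(render_table(rep, "table1"), "differential.tsv")
  wt(render_table(rep[["consensus"]], "table1"), "consensus.tsv")
  if (!is.null(rep$domains)) wt(rep$domains, "domains.tsv")
  if (!is.null(rep$distances)) {
    wt(as.data.frame(round(rep$distances$A, 1)), "distances_A.tsv")
    wt(as.data.frame(round(rep$distances$B, 1)), "distances_B.tsv")
  }
  jsonlite::write_json(
    list(params = rep$params,
         n_paired = nrow(rep$differential),
         consensus_residues = paste0(
           substr(rep$consensus$resid, 1, 3), rep$consensus$resno),
         unpaired = rep$unpaired),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.exposure_report <- function(x, ...) {
  cat("<exposure_report>\n  paired residues:", nrow(x$differential),
      "\n  becomes-exposed (consensus):",
      paste0(x$consensus$resid, x$consensus$resno, collapse = ", "),
      "\n")
  invisible(x)
}

#' Render report tables in publication layout
#'
#' `"table1"`/`"table3"` renders a per-residue differential-exposure table
#' (surface ratio percent in each state, absolute square-angstrom areas in
#' each state, flags); `"table2"` renders an assay table from per-variant
#' LC50 and Kd values, computing the fold columns relative to the reference
#' (first) row with [fold_change()] and reporting both rounded and exact
#' folds.
#'
#' @param x For `"table1"`/`"table3"`: an `exposure_report` or differential
#'   data frame. For `"table2"`: a data frame with columns `toxin`, `lc50`,
#'   `kd` (first row = reference).
#' @param style `"table1"`, `"table2"` or `"table3"`.
#' @return A data frame formatted for writing as TSV.
#' @export
render_table <- function(x, style = c("table1", "table2", "table3")) {
  style <- match.arg(style)
  if (style %in% c("table1", "table3")) {
    d <- if (inherits(x, "exposure_report")) x$differential else x
    need <- c("resno", "resid", "ratio_A", "ratio_B", "abs_A", "abs_B")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(
      residue = paste0(d$resid, d$resno),
      ratio_protoxin_pct = round(d$ratio_A, 1),
      ratio_toxin_pct = round(d$ratio_B, 1),
      area_protoxin_A2 = round(d$abs_A, 2),
      area_toxin_A2 = round(d$abs_B, 2)
    )
    for (fl in c("becomes_exposed_ratio", "becomes_exposed_abs",
                 "consensus")) {
      if (fl %in% names(d)) out[[fl]] <- d[[fl]]
    }
    return(out)
  }
  need <- c("toxin", "lc50", "kd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ref_lc <- x$lc50[1]
  ref_kd <- x$kd[1]
  data.frame(
    toxin = x$toxin,
    lc50 = x$lc50,
    fold_reduction_toxicity = c(NA, round_half_away(
      x$lc50[-1] / ref_lc, 0)),
    fold_reduction_toxicity_exact = c(NA, x$lc50[-1] / ref_lc),
    kd = x$kd,
    fold_decrease_affinity = c(NA, round_half_away(x$kd[-1] / ref_kd, 1)),
    fold_decrease_affinity_exact = c(NA, x$kd[-1] / ref_kd)
  )
}
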