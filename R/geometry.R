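#' Side-chain distance-anchor atom rule
#'
#' Maps each residue type to the single atom used as its distance anchor:
#' the epsilon-carbon (CE) for lysine, the beta-carbon (CB) for valine and
#' every other side-chain-bearing residue, and the alpha-carbon (CA) for
#' glycine, which has no CB.
#'
#' @param overrides Named character vector of residue-code to atom-name
#'   overrides, e.g. `c(ARG = "CZ")`.
#' @return An `atom_rule` object.
#' @export
atom_rule <- function(overrides = NULL) {
  rule <- c(LYS = "CE", GLY = "CA")
  if (!is.null(overrides)) rule[toupper(names(overrides))] <- overrides
  structure(list(by_residue = rule, default = "CB"), class = "atom_rule")
}

anchor_atom <- function(resid, rule) {
  a <- rule$by_residue[toupper(resid)]
  ifelse(is.na(a), rule$default, a)
}

# Residue keys may be integers (385) or strings with a one-letter code
# prefix ("K385"), in which case the letter is checked against the residue
# found in the structure.
parse_reskey <- function(key) {
  if (is.numeric(key)) {
    return(list(resno = as.integer(key), aa = NA_character_))
  }
  m <- regmatches(key, regexec("^([A-Za-z]?)([0-9]+)$", key))[[1]]
  if (length(m) == 0L) stop("cannot parse residue key '", key, "'")
  list(resno = as.integer(m[3]),
       aa = if (m[2] == "") NA_character_ else toupper(m[2]))
}

AA_321 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")

anchor_coords <- function(s, key, chain, rule) {
  k <- parse_reskey(key)
  a <- s$atoms
  hit <- a$resno == k$resno & a$chain == chain
  if (!any(hit)) {
    stop("residue ", k$resno, " not found in chain ", chain,
         " of ", s$id)
  }
  resid <- a$resid[hit][1]
  if (!is.na(k$aa) && !identical(AA_321[[k$aa]], resid)) {
    stop("residue ", k$resno, " in chain ", chain, " is ", resid,
         ", not ", AA_321[[k$aa]])
  }
  atom <- anchor_atom(resid, rule)
  sel <- hit & a$elety == atom
  if (!any(sel)) {
    stop("residue ", resid, k$resno, " (chain ", chain,
         ") lacks anchor atom ", atom)
  }
  c(a$x[sel][1], a$y[sel][1], a$z[sel][1])
}

#' Distance between the anchor atoms of two residues
#'
#' @param s A `prot_structure`.
#' @param res_a,res_b Residue keys: integers or strings like `"K385"` (the
#'   one-letter prefix is validated against the structure).
#' @param chain Chain identifier; defaults to the first chain containing
#'   both residues, with a message naming the choice.
#' @param rule An [atom_rule()].
#' @return Euclidean distance in angstrom (full precision; round to one
#'   decimal for reporting).
#' @export
residue_pair_distance <- function(s, res_a, res_b, chain = NULL,
                                  rule = atom_rule()) {
  stopifnot(inherits(s, "prot_structure"))
  if (is.null(chain)) {
    ra <- parse_reskey(res_a)$resno
    rb <- parse_reskey(res_b)$resno
    for (ch in unique(s$atoms$chain)) {
      has <- s$atoms$chain == ch
      if (any(s$atoms$resno[has] == ra) && any(s$atoms$resno[has] == rb)) {
        chain <- ch
        break
      }
    }
    if (is.null(chain)) {
      stop("no chain contains both residues ", ra, " and ", rb)
    }
    message("using chain ", chain)
  }
  pa <- anchor_coords(s, res_a, chain, rule)
  pb <- anchor_coords(s, res_b, chain, rule)
  sqrt(sum((pa - pb)^2))
}

#' Symmetric anchor-atom distance table over a residue set
#'
#' @param s A `prot_structure`.
#' @param residues Vector of two or more residue keys.
#' @param chain Chain identifier (required for multi-chain structures when
#'   ambiguous; see [residue_pair_distance()]).
#' @param rule An [atom_rule()].
#' @return A symmetric matrix of distances in angstrom with zero diagonal,
#'   dimnames the residue keys.
#' @export
pairwise_distance_table <- function(s, residues, chain = NULL,
                                    rule = atom_rule()) {
  if (length(residues) < 2L) stop("need at least two residues")
  if (is.null(chain)) {
    nos <- vapply(residues, function(k) parse_reskey(k)$resno, 1L)
    for (ch in unique(s$atoms$chain)) {
      if (all(nos %in% s$atoms$resno[s$atoms$chain == ch])) {
        chain <- ch
        break
      }
    }
    if (is.null(chain)) stop("no chain contains all requested residues")
    message("using chain ", chain)
  }
  xyz <- t(vapply(residues, anchor_coords, numeric(3),
                  s = s, chain = chain, rule = rule))
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(as.character(residues), as.character(residues))
  d
}
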