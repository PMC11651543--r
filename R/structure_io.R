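#' Parse a protein structure from PDB or mmCIF
#'
#' Reads a structure file into a uniform atom table. Only the first model is
#' kept; waters and non-polymer heteroatoms are excluded by default; for
#' residues deposited with alternate locations, the highest-occupancy
#' conformer is retained (ties broken towards the lexicographically first
#' altloc identifier). Hydrogens, if present, are kept but flagged so that
#' downstream surface-area calculations can drop them.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. With `"auto"` the format
#'   is inferred from the file extension (`.cif`/`.mmcif` vs anything else).
#' @param keep_hetero Keep non-water HETATM records (default `FALSE`).
#' @return An object of class `prot_structure`: a list with elements `id`
#'   (file stem or supplied identifier), `atoms` (a data frame with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `elesym`, `x`, `y`, `z`,
#'   `o`, `is_hetero`, `is_hydrogen`, `radius`) and `meta` (free-text
#'   provenance).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            keep_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    } else {
      # read.cif warns about its beta status and secondary-structure
      # records on every call; atom records are validated below anyway
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- raw$atom
  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  keep <- !is_water
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no polymer atoms found in '", path, "'")
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at <- filter_altloc(at)
  elesym <- if (!is.null(at$elesy)) at$elesy else rep("", nrow(at))
  missing_ele <- is.na(elesym) | elesym == ""
  if (any(missing_ele)) {
    elesym[missing_ele] <- vapply(at$elety[missing_ele], guess_element, "")
  }
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = as.character(at$insert),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesym = toupper(as.character(elesym)),
    x = at$x, y = at$y, z = at$z,
    o = at$o,
    is_hetero = at$type != "ATOM",
    stringsAsFactors = FALSE
  )
  atoms$is_hydrogen <- atoms$elesym %in% c("H", "D")
  atoms$radius <- NA_real_
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'")
  }
  new_structure(
    id = sub("\\.[^.]*(\\.gz)?$", "", basename(path)),
    atoms = atoms,
    meta = paste0("parsed from ", path, " (", format, ")")
  )
}

new_structure <- function(id, atoms, meta = "") {
  stopifnot(nrow(atoms) > 0L)
  structure(list(id = id, atoms = atoms, meta = meta),
            class = "prot_structure")
}

#' @export
print.prot_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("<prot_structure> ", x$id, "\n",
      "  chains: ", paste(ch, collapse = " "), "\n",
      "  residues: ", nrow(unique(x$atoms[c("chain", "resno", "insert")])),
      ", atoms: ", nrow(x$atoms),
      if (all(!is.na(x$atoms$radius))) " (radii assigned)" else "",
      "\n", sep = "")
  invisible(x)
}

# Highest-occupancy altloc conformer per (chain, resno, insert, elety);
# ties go to the lexicographically first altloc ("" sorts before "A").
filter_altloc <- function(at) {
  if (all(at$alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  if (nchar(nm) == 0L) return("")
  first <- toupper(substr(nm, 1, 1))
  if (first %in% c("C", "N", "O", "S", "P", "H")) first else toupper(nm)
}

#' Restrict a structure to selected chains
#'
#' @param s A `prot_structure`.
#' @param chains Character vector of chain identifiers, or `"all"`.
#' @return A `prot_structure` containing only the requested chains. The
#'   surface-area context of downstream calculations is whatever the subset
#'   contains, so whole-assembly and isolated-monomer analyses are obtained
#'   by different subsets.
#' @export
select_chains <- function(s, chains = "all") {
  stopifnot(inherits(s, "prot_structure"))
  if (identical(chains, "all")) return(s)
  avail <- unique(s$atoms$chain)
  bad <- setdiff(chains, avail)
  if (length(bad) > 0L) {
    stop("unknown chain id(s) ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  }
  new_structure(s$id, s$atoms[s$atoms$chain %in% chains, , drop = FALSE],
                paste0(s$meta, "; chains ", paste(chains, collapse = "")))
}

#' Write a structure as a PDB file
#'
#' @param s A `prot_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "prot_structure"))
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resno,
    resid = a$resid,
    insert = a$insert,
    chain = a$chain,
    elety = a$elety,
    o = a$o,
    b = rep(0, nrow(a)),
    elesy = a$elesym
  )
  invisible(path)
}

#' Van der Waals radii sets
#'
#' `default_radii()` loads the Bondi-style element radii table shipped with
#' the package; `read_radii()` reads a user set from a four-column TSV
#' (`resname`, `atomname`, `element`, `radius`; `*` is a wildcard).
#' Lookup during [assign_radii()] resolves by (residue name, atom name)
#' first, then element, then `default_radius`.
#'
#' @param path TSV file path.
#' @param name Label for the set.
#' @param default_radius Fallback radius in angstrom for unmatched atoms.
#' @return A `radii_set` object.
#' @export
read_radii <- function(path, name = basename(path), default_radius = 1.7) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("resname", "atomname", "element", "radius")
  if (!all(need %in% names(tab))) {
    stop("radii TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$radius <= 0.5 | tab$radius >= 3.0)) {
    stop("all radii must lie in (0.5, 3.0) angstrom")
  }
  structure(list(name = name, table = tab, default_radius = default_radius),
            class = "radii_set")
}

#' @rdname read_radii
#' @export
default_radii <- function() {
  read_radii(system.file("extdata", "radii_bondi.tsv", package = "epiunmask"),
             name = "bondi")
}

#' Assign van der Waals radii to every atom
#'
#' @param s A `prot_structure`.
#' @param radii A `radii_set` (default: the shipped Bondi-style table).
#' @param ignore_hydrogens Drop hydrogen/deuterium atoms (default `TRUE`;
#'   cryo-EM depositions generally lack them anyway).
#' @return The structure with a filled `radius` column. Unmatched atoms fall
#'   back to the set's `default_radius`; their count is reported via a
#'   message.
#' @export
assign_radii <- function(s, radii = default_radii(), ignore_hydrogens = TRUE) {
  stopifnot(inherits(s, "prot_structure"), inherits(radii, "radii_set"))
  a <- s$atoms
  if (ignore_hydrogens) a <- a[!a$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left after hydrogen removal")
  tab <- radii$table
  r <- rep(NA_real_, nrow(a))
  exact <- tab[tab$resname != "*" & tab$atomname != "*", , drop = FALSE]
  if (nrow(exact) > 0L) {
    m <- match(paste(a$resid, a$elety), paste(exact$resname, exact$atomname))
    r[!is.na(m)] <- exact$radius[m[!is.na(m)]]
  }
  byele <- tab[tab$resname == "*" & tab$atomname == "*", , drop = FALSE]
  todo <- is.na(r)
  m <- match(a$elesym[todo], byele$element)
  r[todo][!is.na(m)] <- byele$radius[m[!is.na(m)]]
  unmatched <- sum(is.na(r))
  if (unmatched > 0L) {
    message(unmatched, " atom(s) not in radii set '", radii$name,
            "'; using default radius ", radii$default_radius, " A")
    r[is.na(r)] <- radii$default_radius
  }
  a$radius <- r
  out <- new_structure(s$id, a, s$meta)
  attr(out, "radii_set") <- radii$name
  attr(out, "n_unmatched") <- unmatched
  out
}
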