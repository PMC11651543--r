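#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Clustal formats (parsing delegated to
#' Biostrings). All rows must have equal aligned length.
#'
#' @param path Alignment file.
#' @param format `"auto"`, `"fasta"` or `"clustal"`. `"auto"` sniffs the
#'   first non-blank line (`>` means FASTA).
#' @return An `msa_alignment`: list with `ids` and `seqs` (aligned strings,
#'   gaps as `-`).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 10, warn = FALSE)
    first <- first[nzchar(trimws(first))][1]
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      stop("failed to parse ", format, " alignment '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  seqs <- as.character(aln)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("ragged alignment rows in '", path, "'")
  }
  structure(list(ids = ids, seqs = gsub("\\.", "-", unname(seqs))),
            class = "msa_alignment")
}

aln_seq <- function(a, id) {
  i <- match(id, a$ids)
  if (is.na(i)) {
    stop("sequence id '", id, "' not in alignment (ids: ",
         paste(a$ids, collapse = ", "), ")")
  }
  a$seqs[i]
}

#' Map reference residue numbers to alignment columns
#'
#' The i-th non-gap character of the reference row corresponds to residue
#' number `offset + i` and to its (1-based) alignment column.
#'
#' @param a An `msa_alignment`.
#' @param ref_id Id of the reference sequence.
#' @param offset Numbering offset: residue number of the first reference
#'   character minus one (default 0, i.e. numbering starts at 1).
#' @return A `column_map`: data frame with `resno`, `column`, `ref_char`,
#'   both coordinates strictly increasing.
#' @export
map_reference_positions <- function(a, ref_id, offset = 0) {
  stopifnot(inherits(a, "msa_alignment"))
  chars <- strsplit(aln_seq(a, ref_id), "")[[1]]
  nongap <- which(chars != "-")
  cm <- data.frame(resno = offset + seq_along(nongap),
                   column = nongap,
                   ref_char = chars[nongap],
                   stringsAsFactors = FALSE)
  attr(cm, "ref_id") <- ref_id
  class(cm) <- c("column_map", "data.frame")
  cm
}

#' Residue conservation across homologs at chosen reference positions
#'
#' @param a An `msa_alignment`.
#' @param cm A `column_map` from [map_reference_positions()].
#' @param positions Reference residue numbers to report.
#' @return A list with `table` (data frame: one row per position x homolog
#'   with columns `resno`, `ref_char`, `id`, `residue`, `identical`),
#'   `conserved_in` (named list: per position, ids whose residue is
#'   identical to the reference's), and `unmappable` (positions falling on
#'   reference gaps or outside the map). Conservation means exact amino
#'   acid identity.
#' @export
conservation_report <- function(a, cm, positions) {
  stopifnot(inherits(a, "msa_alignment"), inherits(cm, "column_map"))
  ref_id <- attr(cm, "ref_id")
  m <- match(positions, cm$resno)
  unmappable <- positions[is.na(m)]
  ok <- positions[!is.na(m)]
  cols <- cm$column[m[!is.na(m)]]
  refc <- cm$ref_char[m[!is.na(m)]]
  rows <- list()
  conserved <- stats::setNames(vector("list", length(ok)), as.character(ok))
  mat <- do.call(rbind, strsplit(a$seqs, ""))
  for (k in seq_along(ok)) {
    res <- mat[, cols[k]]
    rows[[k]] <- data.frame(resno = ok[k], ref_char = refc[k], id = a$ids,
                            residue = res, identical = res == refc[k],
                            stringsAsFactors = FALSE)
    conserved[[k]] <- a$ids[res == refc[k]]
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(resno = integer(0), ref_char = character(0),
                    id = character(0), residue = character(0),
                    identical = logical(0)),
       conserved_in = conserved,
       unmappable = unmappable,
       ref_id = ref_id)
}
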