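#' Taxonomic ranks used throughout the package
#'
#' Fixed seven-rank hierarchy from domain to species. Lineages are represented
#' as character vectors of length 7 (named by rank), with `NA` from the first
#' unannotated rank downward; a named rank implies named ancestors.
#'
#' @format Character vector of rank names.
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Parse a semicolon-separated lineage string
#'
#' @param x Lineage string, ranks separated by `;` from domain downward; may
#'   be truncated at any rank. `""` or `NA` yields a fully unannotated
#'   lineage.
#' @return Character vector of length 7, named by [TAX_RANKS], `NA`-padded.
#' @export
lineage_parse <- function(x) {
  out <- rep(NA_character_, length(TAX_RANKS))
  names(out) <- TAX_RANKS
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(out)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts[!nzchar(parts)] <- NA_character_
  n <- min(length(parts), length(TAX_RANKS))
  out[seq_len(n)] <- parts[seq_len(n)]
  lineage_validate(out)
}

#' Format a lineage vector back into a string
#'
#' @param lin Character vector as returned by [lineage_parse()].
#' @return Single string with trailing unannotated ranks dropped.
#' @export
lineage_format <- function(lin) {
  lin <- lineage_validate(lin)
  keep <- !is.na(lin)
  if (!any(keep)) return("")
  paste(lin[seq_len(max(which(keep)))], collapse = ";")
}

# Enforce gap-freeness: everything below the first NA rank is blanked.
lineage_validate <- function(lin) {
  stopifnot(length(lin) == length(TAX_RANKS))
  first_na <- which(is.na(lin))
  if (length(first_na) > 0 && first_na[1] < length(lin)) {
    lin[first_na[1]:length(lin)] <- NA_character_
  }
  names(lin) <- TAX_RANKS
  lin
}

# Depth (number of annotated ranks) of a lineage vector.
lineage_depth <- function(lin) sum(!is.na(lin))

# TRUE if `anc` is an ancestor of (or equal to) `lin`.
lineage_is_ancestor <- function(anc, lin) {
  d <- lineage_depth(anc)
  if (d == 0) return(TRUE)
  all(anc[seq_len(d)] == lin[seq_len(d)]) && lineage_depth(lin) >= d
}

# Empty (fully unannotated) lineage.
lineage_empty <- function() lineage_parse("")
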