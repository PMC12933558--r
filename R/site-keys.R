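# Canonical site keys identify one modified residue:
#   PROTEIN:<residue letter><1-based position>:<ptm type>
# e.g. MAPK1:Y187:phosphorylation

#' Format canonical PTM site keys
#'
#' @param protein Character vector of protein symbols.
#' @param residue One-letter amino-acid codes.
#' @param position 1-based integer residue positions.
#' @param ptm_type Modification type names (e.g. `"phosphorylation"`).
#' @return Character vector of keys such as `"MAPK1:Y187:phosphorylation"`.
#' @seealso [parse_site_keys()]
#' @export
#' @examples
#' format_site_key("MAPK1", "Y", 187, "phosphorylation")
format_site_key <- function(protein, residue, position, ptm_type) {
  paste0(toupper(protein), ":", toupper(residue), as.integer(position), ":",
         ptm_type)
}

#' Parse canonical PTM site keys
#'
#' Inverse of [format_site_key()]. Malformed keys yield `NA` fields (and are
#' reported by callers); protein symbols may contain any character except the
#' colon separator.
#'
#' @param keys Character vector of site keys.
#' @return A data frame with columns `key`, `protein`, `residue`, `position`
#'   (integer), `ptm_type`, and logical `ok`.
#' @export
#' @examples
#' parse_site_keys(c("MAPK1:Y187:phosphorylation", "bad-key"))
parse_site_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([A-Za-z])([0-9]+):(.+)$", keys))
  bad <- vapply(m, length, 1L) != 5L
  pick <- function(i) vapply(m, function(x) if (length(x) == 5L) x[[i]] else NA_character_, "")
  pos <- suppressWarnings(as.integer(pick(4L)))
  bad <- bad | is.na(pos) | pos < 1L
  data.frame(
    key = keys,
    protein = ifelse(bad, NA_character_, toupper(pick(2L))),
    residue = ifelse(bad, NA_character_, toupper(pick(3L))),
    position = ifelse(bad, NA_integer_, pos),
    ptm_type = ifelse(bad, NA_character_, pick(5L)),
    ok = !bad,
    stringsAsFactors = FALSE
  )
}
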