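#' Canonical leukocyte subset and group labels
#'
#' Six leukocyte populations are supported: total lymphocytes, granulocytes
#' (the surrogate marker for hematopoietic stem cells), CD20+ B cells,
#' CD45RA+CD20- "naive" T cells, CD45RA- memory T cells and CD45RA+CD57+
#' mature NK/T cells. Common immunophenotype shorthand ("CD20+",
#' "CD45RA+ CD20-", "CD45RA-", "CD57+") is accepted anywhere a subset label
#' is read from a file and mapped onto the canonical names.
#'
#' @format character vector of the six canonical subset labels.
#' @export
TELO_SUBSETS <- c("lymphocytes", "granulocytes", "B_CD20pos",
                  "naiveT_CD45RAposCD20neg", "memoryT_CD45RAneg",
                  "matureNKT_CD57pos")

#' @rdname TELO_SUBSETS
#' @format character vector of the recognised cohort group labels.
#' @export
TELO_GROUPS <- c("healthy", "carrier_TERT", "carrier_TERC",
                 "relative_parent", "relative_sibling",
                 "relative_unspecified")

# immunophenotype shorthand -> canonical label (unicode minus accepted too)
.subset_aliases <- c(
  "CD20+"            = "B_CD20pos",
  "CD45RA+ CD20-"    = "naiveT_CD45RAposCD20neg",
  "CD45RA+CD20-"     = "naiveT_CD45RAposCD20neg",
  "CD45RA-"          = "memoryT_CD45RAneg",
  "CD45RA-CD20-"     = "memoryT_CD45RAneg",
  "CD57+"            = "matureNKT_CD57pos",
  "CD45RA+CD57+"     = "matureNKT_CD57pos")

#' Normalise subset labels to the canonical enumeration
#'
#' @param x character vector of subset labels or aliases.
#' @return character vector of canonical labels.
#' @examples
#' canonical_subset(c("CD20+", "lymphocytes"))
#' @export
canonical_subset <- function(x) {
  x <- gsub("−", "-", trimws(as.character(x)))
  out <- ifelse(x %in% TELO_SUBSETS, x, unname(.subset_aliases[x]))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown subset label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(TELO_SUBSETS, collapse = ", "),
         " or aliases ", paste(names(.subset_aliases), collapse = ", "))
  }
  out
}
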