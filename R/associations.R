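# Reading and preprocessing Morbid-Map-style disease-gene association lists:
# tag-based reliability filtering, deterministic merging of disease subtypes,
# and construction of the labelled binary association matrix.

#' Read a disease-gene association TSV
#'
#' Expects tab-separated columns `disease_name`, `gene_symbol` and an
#' optional reliability `tag` (e.g. `"(3)"`, `"[]"`, `"?"`). Lines starting
#' with `#` are comments; lines with fewer than two fields are counted and
#' skipped with a warning. No filtering happens here; see [filterByTag()].
#'
#' @param path path to the TSV file.
#' @return data.frame of association records with columns
#'   `disease`, `gene`, `tag`.
#' @export
readAssociations <- function(path) {
  if (!file.exists(path)) stop("cannot read association file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]),
                logical(1))
  if (any(bad)) warning("skipping ", sum(bad), " malformed association line(s)")
  fields <- fields[!bad]
  data.frame(
    disease = vapply(fields, `[`, "", 1L),
    gene = vapply(fields, `[`, "", 2L),
    tag = vapply(fields, function(f) if (length(f) >= 3) f[3] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Keep only records with an accepted reliability tag
#'
#' Morbid-Map entries tagged `"(3)"` have a known molecular basis; `"[]"`
#' marks laboratory-test anomalies and `"?"` provisional links. The default
#' keeps only `"(3)"`.
#'
#' @param records data.frame from [readAssociations()].
#' @param acceptedTags character vector of tags to retain.
#' @return filtered record data.frame.
#' @export
filterByTag <- function(records, acceptedTags = "(3)") {
  records[records$tag %in% acceptedTags, , drop = FALSE]
}

# default subtype-stripping rules, applied in order to lowercased names
.defaultMergeRules <- c(
  "\\[[^]]*\\]",                                  # bracketed suffixes
  "\\([^)]*\\)",                                  # parenthesized suffixes
  ",?\\s*type\\s+[0-9ivxlc]+[a-z]?\\b",           # ", type 2" / "type iia"
  ",\\s*[0-9]+[a-z]?\\b",                          # ", 3" numeric subtype
  ",?\\s*\\b[ivxlc]+\\b\\s*$",                     # trailing roman numeral
  "\\s+[0-9]+[a-z]?\\s*$",                         # trailing bare subtype number
  ",?\\s*\\bsomatic\\b",                           # somatic qualifier
  ",?\\s*\\bsusceptibility to\\b.*$"               # susceptibility clauses
)

#' Canonicalize disease names and merge subtypes
#'
#' Disease subtypes (e.g. `"Leigh syndrome, type 1"` and
#' `"Leigh syndrome, type 2"`) are merged under one canonical name by a
#' deterministic rule: lowercase, apply the removal regexes in order, then
#' trim residual punctuation and whitespace. Duplicate (disease, gene) pairs
#' are collapsed. Running the merge twice is a no-op.
#'
#' @param records data.frame of association records.
#' @param rules character vector of regexes removed from lowercased names,
#'   in order; defaults cover bracketed/parenthesized suffixes, `", type N"`,
#'   numeric and roman-numeral subtype designators, and somatic qualifiers.
#' @return record data.frame with canonical disease names and no duplicates.
#' @export
mergeSubtypes <- function(records, rules = .defaultMergeRules) {
  nm <- tolower(records$disease)
  for (r in rules) nm <- gsub(r, "", nm, perl = TRUE)
  nm <- gsub("\\s+", " ", nm)
  nm <- gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", nm)
  out <- records
  out$disease <- nm
  out <- out[nzchar(out$disease) & nzchar(out$gene), , drop = FALSE]
  out[!duplicated(out[, c("disease", "gene")]), , drop = FALSE]
}

#' Build a binary AssociationMatrix from records
#'
#' Diseases not in `annotatedDiseases` (e.g. lacking any phenotype-ontology
#' annotation, hence no similarity row) are dropped with a warning; gene
#' columns orphaned by that removal are dropped too. Labels are ordered
#' lexicographically for reproducible indexing.
#'
#' @param records data.frame of (merged, filtered) association records.
#' @param annotatedDiseases optional character vector; when given, only these
#'   diseases are retained.
#' @return An [AssociationMatrix-class] with binary entries.
#' @export
buildAssociationMatrix <- function(records, annotatedDiseases = NULL) {
  if (!is.null(annotatedDiseases)) {
    drop <- setdiff(unique(records$disease), annotatedDiseases)
    if (length(drop))
      warning("dropping ", length(drop), " unannotated disease(s): ",
              paste(utils::head(drop, 5), collapse = ", "),
              if (length(drop) > 5) ", ..." else "")
    records <- records[records$disease %in% annotatedDiseases, , drop = FALSE]
  }
  if (!nrow(records)) stop("no associations left after filtering")
  diseases <- sort(unique(records$disease))
  genes <- sort(unique(records$gene))
  A <- Matrix::sparseMatrix(
    i = match(records$disease, diseases),
    j = match(records$gene, genes),
    x = 1,
    dims = c(length(diseases), length(genes))
  )
  A@x[] <- 1  # duplicates collapse to 1
  associationMatrix(A, diseases, genes)
}

#' Partition diseases by number of associated genes
#'
#' Splits disease labels into the multiple-gene class (row sum >= 2) and the
#' single-gene class (row sum == 1), mirroring the separate evaluation of
#' the two regimes.
#'
#' @param A a binary [AssociationMatrix-class].
#' @return list with character vectors `multiple` and `single`.
#' @export
diseaseClasses <- function(A) {
  rs <- Matrix::rowSums(A@assoc != 0)
  if (any(rs == 0))
    stop("disease(s) with no associations: ",
         paste(utils::head(A@diseases[rs == 0], 5), collapse = ", "))
  list(multiple = A@diseases[rs >= 2], single = A@diseases[rs == 1])
}

#' Write an AssociationMatrix as a TSV edge list
#'
#' Columns `disease`, `gene`, `weight`; zero entries are omitted. All labels
#' are preserved on read only if every row/column has at least one nonzero.
#'
#' @param A an [AssociationMatrix-class].
#' @param path output path.
#' @export
writeAssociationMatrix <- function(A, path) {
  M <- as(A@assoc, "TsparseMatrix")
  df <- data.frame(disease = A@diseases[M@i + 1L], gene = A@genes[M@j + 1L],
                   weight = M@x)
  df <- df[order(df$disease, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssociationMatrix
#' @return `readAssociationMatrix` returns the [AssociationMatrix-class].
#' @export
readAssociationMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  diseases <- sort(unique(df$disease))
  genes <- sort(unique(df$gene))
  A <- Matrix::sparseMatrix(i = match(df$disease, diseases),
                            j = match(df$gene, genes),
                            x = df$weight,
                            dims = c(length(diseases), length(genes)))
  associationMatrix(A, diseases, genes)
}
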