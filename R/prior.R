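# Similarity-weighted prior for sparsely annotated diseases.
#
# For a disease i' with few or no usable associations, pseudo-association
# weights are borrowed from similar diseases: gene j receives the mean
# disease similarity of the diseases already associated with j,
#
#   p_{i'j} = sum_{i != i'} s^d_{i i'} a_{ij}  /  sum_{i != i'} a_{ij},
#
# and 0 when no other disease is associated with j (no evidence, no prior).

#' Similarity-weighted prior vector for one disease
#'
#' @param A an [AssociationMatrix-class] (typically the binary training
#'   matrix).
#' @param Sd disease [SimilarityMatrix-class] with labels matching `A`.
#' @param disease the disease label `i'` receiving the prior.
#' @return named numeric vector over genes, entries in `[0, 1]` (bounded by
#'   the largest similarity); zero for genes with no other associated
#'   disease.
#' @export
priorVector <- function(A, Sd, disease) {
  if (!identical(Sd@labels, A@diseases))
    stop("disease labels of A and Sd disagree")
  i <- match(disease, A@diseases)
  if (is.na(i)) stop("unknown disease: ", disease)
  M <- A@assoc
  s <- Sd@values[i, ]
  s[i] <- 0
  num <- as.numeric(s %*% M)
  den <- Matrix::colSums(M) - as.numeric(M[i, ])
  p <- ifelse(den > 0, num / den, 0)
  names(p) <- A@genes
  p
}

#' Add prior vectors to association-matrix rows
#'
#' Returns a new matrix; the input is not modified. With `mode = "add"` the
#' prior is added entrywise to the disease's row (known associations keep
#' their weight and gain the prior); with `mode = "replace_zeros"` only zero
#' entries receive the prior.
#'
#' @param A an [AssociationMatrix-class].
#' @param priors named list mapping disease label to its prior vector (as
#'   returned by [priorVector()]); at most one prior per disease.
#' @param mode `"add"` (default) or `"replace_zeros"`.
#' @return a new, generally non-binary [AssociationMatrix-class].
#' @export
augmentAssociations <- function(A, priors, mode = c("add", "replace_zeros")) {
  mode <- match.arg(mode)
  if (!length(priors)) return(A)
  if (is.null(names(priors)) || anyDuplicated(names(priors)))
    stop("priors must be a named list with one entry per disease")
  M <- as.matrix(A@assoc)
  for (d in names(priors)) {
    i <- match(d, A@diseases)
    if (is.na(i)) stop("unknown disease in priors: ", d)
    p <- priors[[d]]
    if (length(p) != ncol(M)) stop("prior length mismatch for ", d)
    if (mode == "add") {
      M[i, ] <- M[i, ] + p
    } else {
      zero <- M[i, ] == 0
      M[i, zero] <- p[zero]
    }
  }
  associationMatrix(M, A@diseases, A@genes)
}
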