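#' Principal component analysis of the dosage matrix
#'
#' Accession-by-locus dosages are centred per locus; missing calls are
#' imputed by the locus mean before centring (the standard dosage-PCA
#' convention). Components come from the singular value decomposition via
#' [stats::prcomp].
#'
#' @param x a [SnpGenotypes-class] object.
#' @param k number of components to return, `1 <= k <= min(N, L)`.
#' @return a list with `scores` (N x k), `loadings` (L x k), and
#'   `varianceFraction` (length k, descending, summing to at most 1; all 0
#'   for a constant matrix).
#' @export
genoPCA <- function(x, k = 2) {
  if (length(k) != 1L || k <= 0) stop("k must be a positive integer")
  A <- t(dosages(x))                 # accessions x loci
  storage.mode(A) <- "double"
  if (k > min(dim(A))) stop("k exceeds min(N, L)")
  mu <- colMeans(A, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  naIdx <- which(is.na(A))
  if (length(naIdx)) A[naIdx] <- mu[((naIdx - 1L) %/% nrow(A)) + 1L]
  A <- sweep(A, 2L, mu)
  pc <- prcomp(A, center = FALSE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       varianceFraction = vf)
}

#' Write PCA scores as TSV
#'
#' @param pca result of [genoPCA()].
#' @param path output path.
#' @param labels optional extra label column (e.g. population or core flag).
#' @return `path`, invisibly.
#' @export
writePcaScores <- function(pca, path, labels = NULL) {
  out <- data.frame(accession = rownames(pca$scores), pca$scores,
                    check.names = FALSE)
  if (!is.null(labels)) out$label <- labels
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
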