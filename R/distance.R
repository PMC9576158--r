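## Genetic distances: modified Rogers between accessions, Nei (1972) between
## populations.

#' Modified Rogers distance matrix between accessions
#'
#' For accessions i, j with alternate-allele dosages `x` in 0..2,
#' `MR_ij = sqrt( sum_l (x_il - x_jl)^2 / (4 L_ij) )` over the `L_ij` loci
#' called in both (pairwise-complete). Entries lie in `[0, 1]`; opposite
#' homozygotes at every shared locus attain 1. MR is a metric on
#' complete-data panels.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param subset accessions to include (default all).
#' @return a symmetric numeric matrix with accession ids as dimnames.
#' @export
modifiedRogers <- function(x, subset = "all") {
  idx <- .resolveSubset(x, subset)
  d <- dosages(x)[, idx, drop = FALSE]
  M <- !is.na(d)
  X <- d; X[!M] <- 0L
  storage.mode(X) <- "double"
  storage.mode(M) <- "double"
  A <- crossprod(X^2, M)                      # (i,j): sum_l x_il^2 m_jl
  num <- A + t(A) - 2 * crossprod(X)
  L <- crossprod(M)
  if (any(L[upper.tri(L)] == 0)) {
    ij <- which(L == 0 & upper.tri(L), arr.ind = TRUE)[1L, ]
    stop("accessions share no called locus: ",
         colnames(d)[ij[1L]], " / ", colnames(d)[ij[2L]])
  }
  D <- sqrt(pmax(num, 0) / (4 * L))
  diag(D) <- 0
  dimnames(D) <- list(colnames(d), colnames(d))
  D
}

#' Nei (1972) genetic distance matrix between populations
#'
#' `D = -ln I` with normalized gene identity
#' `I = sum_l sum_a p_a q_a / sqrt(sum_l sum_a p_a^2 * sum_l sum_a q_a^2)`,
#' where p and q run over the two populations' allele-frequency profiles.
#' For each pair only loci with defined frequencies in both populations
#' enter the sums. A pair with `I = 0` (no shared allele anywhere) gets the
#' finite `cap` with a warning so downstream tree building stays defined.
#'
#' @param x a [SnpGenotypes-class] with populations attached.
#' @param cap distance assigned when the gene identity is 0 (default 10).
#' @return a symmetric numeric matrix over population labels.
#' @export
neiDistance <- function(x, cap = 10) {
  pops <- populations(x)
  if (is.null(pops)) stop("no populations attached")
  labs <- unique(pops)
  if (length(labs) < 2L) stop("need at least two populations")
  P <- vapply(labs, function(l) alleleFrequencies(x, which(pops == l))$p,
              numeric(nrow(x)))
  if (nrow(x) == 1L) P <- matrix(P, nrow = 1L, dimnames = list(NULL, labs))
  K <- length(labs)
  D <- matrix(0, K, K, dimnames = list(labs, labs))
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    ok <- !is.na(P[, a]) & !is.na(P[, b])
    pa <- P[ok, a]; pb <- P[ok, b]
    jab <- sum(pa * pb + (1 - pa) * (1 - pb))
    ja <- sum(pa^2 + (1 - pa)^2)
    jb <- sum(pb^2 + (1 - pb)^2)
    I <- jab / sqrt(ja * jb)
    if (I <= 0) {
      warning("zero gene identity between ", labs[a], " and ", labs[b],
              "; distance capped at ", cap)
      dd <- cap
    } else dd <- max(-log(min(I, 1)), 0)
    D[a, b] <- D[b, a] <- dd
  }
  D
}

#' Write a distance matrix as TSV
#'
#' @param D symmetric labelled matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(D, path) {
  out <- data.frame(id = rownames(D), D, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
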