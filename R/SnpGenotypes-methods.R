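#' Construct a SnpGenotypes object
#'
#' @param dosage integer matrix of alternate-allele dosages, loci in rows and
#'   accessions in columns; entries 0/1/2 or `NA` (missing call). Row names
#'   are locus ids, column names accession ids.
#' @param loci either a `GRanges` with `ref`/`alt` metadata columns or a
#'   data.frame with columns `locus`, `chrom`, `pos`, `ref`, `alt`. When
#'   `NULL`, placeholder metadata (chromosome `"un"`, positions 1..L, alleles
#'   A/T) are generated — adequate for purely statistical work.
#' @param populations optional named character vector mapping accession id to
#'   population label; must cover every accession.
#' @return a validated [SnpGenotypes-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA, 0L, 2L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
#' g <- snpGenotypes(d)
#' nAccessions(g)
#' @export
snpGenotypes <- function(dosage, loci = NULL, populations = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("locus", seq_len(nrow(dosage)))
  if (is.null(loci)) {
    loci <- GRanges(
      seqnames = rep("un", nrow(dosage)),
      ranges = IRanges::IRanges(start = seq_len(max(nrow(dosage), 1L))[seq_len(nrow(dosage))], width = 1L),
      ref = rep("A", nrow(dosage)), alt = rep("T", nrow(dosage)))
    names(loci) <- rownames(dosage)
  } else if (is.data.frame(loci)) {
    loci <- .lociFrameToGRanges(loci, rownames(dosage))
  } else {
    if (is.null(names(loci))) names(loci) <- rownames(dosage)
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(dosage))
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = loci, colData = cd)
  x <- new("SnpGenotypes", se)
  if (!is.null(populations)) x <- attachPopulations(x, populations)
  validObject(x)
  x
}

.lociFrameToGRanges <- function(df, locusIds) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("locus metadata needs columns chrom, pos, ref, alt")
  if ("locus" %in% names(df)) {
    idx <- match(locusIds, df$locus)
    if (anyNA(idx))
      stop("locus metadata missing for: ",
           paste(head(locusIds[is.na(idx)], 5), collapse = ", "))
    df <- df[idx, , drop = FALSE]
  }
  gr <- GRanges(seqnames = as.character(df$chrom),
                ranges = IRanges::IRanges(start = as.integer(df$pos), width = 1L),
                ref = as.character(df$ref), alt = as.character(df$alt))
  names(gr) <- locusIds
  gr
}

#' @describeIn snpGenotypes loci-by-accessions dosage matrix.
#' @param x a `SnpGenotypes` object.
#' @export
setMethod("dosages", "SnpGenotypes", function(x) assay(x, "dosage"))

#' @describeIn snpGenotypes accession ids (column names).
#' @export
setMethod("accessionIds", "SnpGenotypes", function(x) colnames(x))

#' @describeIn snpGenotypes named character vector of population labels, or
#'   `NULL` when no map is attached.
#' @export
setMethod("populations", "SnpGenotypes", function(x) {
  if (!"population" %in% names(colData(x))) return(NULL)
  setNames(as.character(colData(x)$population), colnames(x))
})

#' @describeIn snpGenotypes replace population labels (named by accession).
#' @param value named character vector accession id -> population.
#' @export
setMethod("populations<-", "SnpGenotypes", function(x, value) {
  attachPopulations(x, value)
})

#' @describeIn snpGenotypes locus metadata as a `GRanges`.
#' @export
setMethod("lociInfo", "SnpGenotypes", function(x) rowRanges(x))

#' @describeIn snpGenotypes number of loci (rows).
#' @export
setMethod("nLoci", "SnpGenotypes", function(x) nrow(x))

#' @describeIn snpGenotypes number of accessions (columns).
#' @export
setMethod("nAccessions", "SnpGenotypes", function(x) ncol(x))

setMethod("show", "SnpGenotypes", function(object) {
  cat("SnpGenotypes:", nrow(object), "loci x", ncol(object), "accessions\n")
  d <- assay(object, "dosage")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(d))))
  p <- populations(object)
  if (is.null(p)) cat("  populations: <none attached>\n")
  else cat("  populations:", length(unique(p)), "labels\n")
  chr <- unique(as.character(seqnames(rowRanges(object))))
  cat("  chromosomes:", length(chr), "\n")
})

setMethod("show", "CoreSelection", function(object) {
  cat("CoreSelection of", length(object@selected), "accessions\n")
  cat(sprintf("  objective: %.6f (weights mr = %g, sh = %g)\n",
              object@objective, object@weights[["mr"]], object@weights[["sh"]]))
  cat(sprintf("  allele coverage: %.4f\n", object@coverage))
  if (length(object@perRegionCounts))
    cat("  regions represented:", sum(object@perRegionCounts > 0L), "\n")
})

#' @describeIn optimizeCore accession ids selected into the core.
#' @export
setMethod("selectedIds", "CoreSelection", function(object) object@selected)

#' @describeIn optimizeCore size of the core.
#' @export
setMethod("coreSize", "CoreSelection", function(object) length(object@selected))
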