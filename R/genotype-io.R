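## Reading, writing, filtering and population-labelling of genotype panels.
## Two on-disk dialects are supported:
##   * VCF 4.x (GT field only, biallelic SNP records; others skipped),
##   * a TSV dosage dialect: header `accession<TAB>locus1<TAB>...`, cells
##     0/1/2/NA, with locus metadata in a side file
##     `locus<TAB>chrom<TAB>pos<TAB>ref<TAB>alt`.

#' Read a genotype matrix from VCF or TSV
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"tsv"`. Defaults to a guess from the extension.
#' @param lociPath for `format = "tsv"`, optional path to the locus-metadata
#'   side file (`locus chrom pos ref alt`, tab-separated with header). When
#'   absent, placeholder metadata are generated.
#' @return a [SnpGenotypes-class] object. For VCF input, multi-allelic or
#'   non-SNP records are skipped and their count reported in a message.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"), lociPath = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "vcf") .readVcfGenotypes(path) else .readTsvGenotypes(path, lociPath)
}

.readTsvGenotypes <- function(path, lociPath = NULL) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", comment.char = ""),
    error = function(e) stop("unparseable TSV genotype file: ", conditionMessage(e)))
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("unparseable TSV genotype file: no accessions or no loci")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate accession id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  d <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- !is.na(cells) & cells != "NA" & is.na(d)
  if (any(bad)) stop("unparseable genotype cell(s), e.g. '", cells[bad][1L], "'")
  dimnames(d) <- list(ids, colnames(tab)[-1L])
  loci <- NULL
  if (!is.null(lociPath)) {
    loci <- read.table(lociPath, header = TRUE, sep = "\t",
                       colClasses = c("character", "character", "integer",
                                      "character", "character"))
    names(loci) <- c("locus", "chrom", "pos", "ref", "alt")
  }
  snpGenotypes(t(d), loci = loci)
}

.readVcfGenotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("unparseable VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) stop("unparseable VCF: no records")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nskip <- sum(!keep)
  if (nskip > 0L)
    message("skipped ", nskip, " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (anyDuplicated(colnames(gt)))
    stop("duplicate accession id: ",
         paste(unique(colnames(gt)[duplicated(colnames(gt))]), collapse = ", "))
  core <- gsub("\\|", "/", gt)
  d <- matrix(NA_integer_, nrow = nrow(core), ncol = ncol(core))
  d[core %in% c("0/0")] <- 0L
  d[core %in% c("0/1", "1/0")] <- 1L
  d[core %in% c("1/1")] <- 2L   # half-calls and '.' stay missing
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  dimnames(d) <- list(ids, colnames(gt))
  loci <- GRanges(seqnames = fix[keep, "CHROM"],
                  ranges = IRanges::IRanges(start = as.integer(fix[keep, "POS"]),
                                            width = 1L),
                  ref = ref[keep], alt = alt[keep])
  names(loci) <- ids
  snpGenotypes(d, loci = loci)
}

#' Write a genotype matrix to VCF or TSV
#'
#' Inverse of [readGenotypes()]: a read-write-read round trip reproduces
#' calls, accession ids and locus metadata exactly.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param lociPath for TSV, path of the locus-metadata side file (default:
#'   `paste0(path, ".loci")`).
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("tsv", "vcf"),
                           lociPath = paste0(path, ".loci")) {
  format <- match.arg(format)
  d <- dosages(x)
  gr <- lociInfo(x)
  if (format == "tsv") {
    out <- data.frame(accession = colnames(d), t(d), check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- data.frame(locus = rownames(d),
                       chrom = as.character(seqnames(gr)),
                       pos = start(gr),
                       ref = as.character(mcols(gr)$ref),
                       alt = as.character(mcols(gr)$alt))
    write.table(meta, lociPath, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gtcode <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtcode[d[ok] + 1L]
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t"),
               paste(as.character(seqnames(gr)), start(gr), rownames(d),
                     as.character(mcols(gr)$ref), as.character(mcols(gr)$alt),
                     ".", "PASS", ".", "GT",
                     apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Filter loci on minor allele frequency and call rate
#'
#' Keeps exactly the loci with `MAF >= mafMin` and call rate (fraction of
#' non-missing calls, the "integrity" of genotyping panels) `>= callRateMin`;
#' both thresholds inclusive. MAF is computed on non-missing calls only. The
#' accession set and surviving call values are unchanged; the operation is
#' idempotent.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param callRateMin minimum call rate (default 0.5).
#' @return the filtered [SnpGenotypes-class]; a warning is raised when no
#'   locus survives (an empty-locus object is still returned).
#' @export
filterLoci <- function(x, mafMin = 0.01, callRateMin = 0.5) {
  stopifnot(mafMin >= 0, mafMin <= 1, callRateMin >= 0, callRateMin <= 1)
  d <- dosages(x)
  called <- !is.na(d)
  nCalled <- rowSums(called)
  p <- ifelse(nCalled > 0L, rowSums(d, na.rm = TRUE) / (2 * nCalled), NA_real_)
  maf <- pmin(p, 1 - p)
  callRate <- nCalled / ncol(d)
  keep <- !is.na(maf) & maf >= mafMin & callRate >= callRateMin
  message("filterLoci: kept ", sum(keep), " of ", nrow(d), " loci (removed ",
          sum(!keep), ")")
  if (!any(keep)) warning("no locus passed the filter")
  x[keep, ]
}

#' Attach population labels to accessions
#'
#' @param x a [SnpGenotypes-class] object.
#' @param map either a path to a two-column headerless TSV
#'   (`accession<TAB>population`) or a named character vector. Map entries
#'   for unknown accessions are ignored with a warning; an accession of `x`
#'   absent from the map is an error naming the missing ids.
#' @return `x` with populations attached.
#' @export
attachPopulations <- function(x, map) {
  if (is.character(map) && is.null(names(map)) && length(map) == 1L) {
    tab <- read.table(map, header = FALSE, sep = "\t",
                      colClasses = "character", comment.char = "")
    if (ncol(tab) != 2L) stop("population map must have exactly two columns")
    map <- setNames(tab[[2L]], tab[[1L]])
  }
  ids <- colnames(x)
  extra <- setdiff(names(map), ids)
  if (length(extra))
    warning("population map contains ", length(extra),
            " unknown accession(s), ignored: ",
            paste(head(extra, 5), collapse = ", "))
  missingIds <- setdiff(ids, names(map))
  if (length(missingIds))
    stop("no population label for accession(s): ",
         paste(missingIds, collapse = ", "))
  colData(x)$population <- unname(map[ids])
  validObject(x)
  x
}

#' Write a population map
#'
#' @param x a [SnpGenotypes-class] with populations attached.
#' @param path output path (two-column headerless TSV).
#' @return `path`, invisibly.
#' @export
writePopulations <- function(x, path) {
  p <- populations(x)
  if (is.null(p)) stop("no populations attached")
  write.table(data.frame(names(p), unname(p)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
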