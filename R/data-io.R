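#' Construct a GenotypePanel
#'
#' Rows are sorted by chromosome then position at construction so that
#' positions are strictly increasing within each chromosome.
#'
#' @param dosage integer matrix, SNPs x samples, values 0/1/2/NA counting
#'   copies of the alternate allele; rownames = SNP ids, colnames = sample ids.
#' @param chrom per-SNP chromosome label.
#' @param pos per-SNP 1-based physical position in base pairs.
#' @param breed per-sample breed code (recycled names from colnames).
#' @param ref,alt optional per-SNP allele characters (alt = the counted
#'   allele).
#' @return a [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(dosage, chrom, pos, breed, ref = NULL, alt = NULL) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage needs SNP rownames and sample colnames")
  storage.mode(dosage) <- "integer"
  rd <- DataFrame(chrom = as.character(chrom), pos = as.integer(pos))
  if (!is.null(ref)) rd$ref <- as.character(ref)
  if (!is.null(alt)) rd$alt <- as.character(alt)
  o <- order(rd$chrom, rd$pos)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage[o, , drop = FALSE]),
    rowData = rd[o, , drop = FALSE],
    colData = DataFrame(breed = as.character(breed), row.names = colnames(dosage)))
  new("GenotypePanel", se)
}

#' Read PLINK PED/MAP text files into a GenotypePanel
#'
#' Biallelic SNPs only. The alternate (counted) allele of every SNP is the
#' panel-wide minor allele; on a tie the lexicographically larger allele
#' character is taken as alternate. The PLINK missing code \code{"0 0"}
#' becomes \code{NA}. Heterozygotes are recognized regardless of the allele
#' order within a genotype. The PED family id is used as the breed code.
#'
#' @param pedPath,mapPath paths to whitespace-delimited PED and MAP files.
#' @return a [GenotypePanel-class].
#' @export
readPlink <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  colnames(map)[1:4] <- c("chrom", "snp", "cm", "pos")
  ped <- read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nsnp <- nrow(map)
  if (ncol(ped) != 6 + 2 * nsnp)
    stop("PED column count does not match MAP (expected ",
         6 + 2 * nsnp, ", got ", ncol(ped), ")")
  ids <- ped[[2]]
  if (anyDuplicated(ids))
    stop("duplicated sample id: ", ids[duplicated(ids)][1])
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(nsnp) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(nsnp), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  dosage <- matrix(NA_integer_, nsnp, length(ids),
                   dimnames = list(map$snp, ids))
  refAll <- altAll <- character(nsnp)
  for (l in seq_len(nsnp)) {
    obs <- c(a1[, l], a2[, l])
    obs <- obs[!is.na(obs)]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("SNP ", map$snp[l], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # alternate = minor allele; tie -> lexicographically larger character
    alt <- if (cnt[2] < cnt[1]) alleles[2]
           else if (cnt[1] < cnt[2]) alleles[1]
           else max(alleles)
    ref <- setdiff(alleles, alt)[1]
    if (is.na(ref)) ref <- alt
    d <- (a1[, l] == alt) + (a2[, l] == alt)
    dosage[l, ] <- as.integer(d)
    refAll[l] <- ref; altAll[l] <- alt
  }
  GenotypePanel(dosage, chrom = map$chrom, pos = map$pos,
                breed = ped[[1]], ref = refAll, alt = altAll)
}

#' Write a GenotypePanel as PLINK PED/MAP text files
#'
#' Inverse of [readPlink()]: allele characters are taken from the panel's
#' \code{ref}/\code{alt} row metadata (defaulting to A/B), missing genotypes
#' are written as \code{"0 0"}, and the breed code goes in the family-id
#' column.
#'
#' @param x a GenotypePanel.
#' @param pedPath,mapPath output paths.
#' @export
writePlink <- function(x, pedPath, mapPath) {
  rd <- rowData(x)
  ref <- if ("ref" %in% colnames(rd)) rd$ref else rep("A", nrow(x))
  alt <- if ("alt" %in% colnames(rd)) rd$alt else rep("B", nrow(x))
  map <- data.frame(rd$chrom, rownames(x), 0, rd$pos)
  write.table(map, mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  d <- dosages(x)
  n <- ncol(d); L <- nrow(d)
  geno <- matrix("0", 2 * L, n)
  for (l in seq_len(L)) {
    g <- d[l, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, alt[l], ref[l]))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, alt[l], ref[l]))
    geno[2 * l - 1, ] <- first
    geno[2 * l, ] <- second
  }
  ped <- cbind(breeds(x), colnames(d), "0", "0", "0", "-9", t(geno))
  write.table(ped, pedPath, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read/write the transposed genotype TSV alternative format
#'
#' Rows are SNPs, with columns \code{snp}, \code{chrom}, \code{pos} followed
#' by one column per sample holding dosages 0/1/2 or NA. The breed table is
#' supplied separately (see [readBreedTable()]).
#'
#' @param path TSV path.
#' @param breed named character vector mapping sample id to breed code.
#' @return a [GenotypePanel-class].
#' @export
readGenotypeTsv <- function(path, breed) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  ids <- setdiff(colnames(tab), c("snp", "chrom", "pos"))
  d <- as.matrix(tab[, ids, drop = FALSE])
  rownames(d) <- tab$snp
  GenotypePanel(d, chrom = tab$chrom, pos = tab$pos, breed = breed[ids])
}

#' @rdname readGenotypeTsv
#' @param x a GenotypePanel.
#' @export
writeGenotypeTsv <- function(x, path) {
  out <- cbind(snpInfo(x), as.data.frame(dosages(x), check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the breed metadata table
#'
#' TSV with columns \code{breed}, \code{group}, \code{lon}, \code{lat} (and
#' optionally \code{n}). Groups are free-form labels such as EUT/WAT/ZEB/HYB.
#'
#' @param path TSV path.
#' @return data.frame with unique breed codes.
#' @export
readBreedTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(tab$breed)) stop("breed codes must be unique")
  tab
}

#' @rdname readBreedTable
#' @param tab a breed metadata data.frame.
#' @export
writeBreedTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-breed alternate-allele frequencies
#'
#' Frequencies are sums of dosages over non-missing individuals of a breed
#' divided by twice the count of those individuals. A breed with no called
#' genotype at a SNP yields an undefined cell (NaN, denominator 0), never a
#' silent zero.
#'
#' @param x a GenotypePanel.
#' @return a [FreqTable-class] (breeds x SNPs).
#' @export
computeBreedFreqs <- function(x) {
  d <- dosages(x)
  br <- breeds(x)
  ok <- !is.na(d)
  d0 <- d; d0[!ok] <- 0L
  # rowsum over samples grouped by breed; matrices are SNP x sample
  sums <- rowsum(t(d0), br)            # breeds x SNPs
  nInd <- rowsum(t(ok) * 1L, br)
  nObs <- 2L * nInd
  f <- sums / nObs                      # 0/0 -> NaN for undefined cells
  storage.mode(nObs) <- "integer"
  new("FreqTable", freq = as.matrix(f), nObs = as.matrix(nObs))
}

#' Cap the number of individuals per breed
#'
#' Each breed keeps \code{min(n, maxN)} individuals drawn uniformly without
#' replacement; deterministic for a fixed seed.
#'
#' @param x a GenotypePanel.
#' @param maxN maximum individuals retained per breed (>= 1).
#' @param seed integer seed.
#' @return a GenotypePanel with at most \code{maxN} samples per breed.
#' @export
subsampleBreeds <- function(x, maxN, seed = 1L) {
  stopifnot(maxN >= 1)
  br <- breeds(x)
  set.seed(seed)
  keep <- unlist(lapply(split(names(br), br), function(ids) {
    if (length(ids) <= maxN) ids else sample(ids, maxN)
  }), use.names = FALSE)
  x[, colnames(x) %in% keep]
}

#' Validate a labelled distance matrix
#'
#' Checks symmetry (to 1e-12), a zero diagonal, no NaN/NA, and a lower bound
#' on entries (0 by default; pairwise F_ST matrices may carry small negative
#' estimates and use \code{lower = -0.05}).
#' @param d square numeric matrix with dimnames.
#' @param lower smallest admissible entry.
#' @return invisibly \code{d}, or an error.
#' @export
checkDistanceMatrix <- function(d, lower = 0) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  if (any(d < lower)) stop("entries below the admissible bound ", lower)
  invisible(d)
}

#' Write/read trees and matrices; JSON run reports
#'
#' Thin wrappers around \pkg{ape} Newick I/O and tab-separated matrices so
#' every artifact of the pipeline is a plain-text file. Node supports travel
#' as Newick internal-node labels.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname writeNewick
#' @param m labelled numeric matrix.
#' @export
writeMatrixTsv <- function(m, path) {
  write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readMatrixTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  as.matrix(tab)
}

#' @rdname writeNewick
#' @param report a named list (run configuration, seed, stage summaries).
#' @export
writeJsonReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
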