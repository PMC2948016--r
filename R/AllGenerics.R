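#' @rdname GenotypePanel-class
#' @param x a \code{GenotypePanel} (or \code{FreqTable} where noted).
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("breeds", function(x) standardGeneric("breeds"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("breedNames", function(x) standardGeneric("breedNames"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname FreqTable-class
#' @param x a \code{FreqTable}.
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' @rdname FreqTable-class
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' Accessors for GenotypePanel
#'
#' @param x a GenotypePanel.
#' @return \code{dosages}: the SNPs x samples integer dosage matrix;
#'   \code{breeds}: a named character vector mapping sample to breed code;
#'   \code{breedNames}: the sorted unique breed codes; \code{snpInfo}: a
#'   data.frame of SNP id, chromosome and position.
#' @name GenotypePanel-accessors
#' @keywords internal
NULL

setMethod("dosages", "GenotypePanel", function(x) assay(x, "dosage"))

setMethod("breeds", "GenotypePanel", function(x)
  setNames(as.character(colData(x)$breed), colnames(x)))

setMethod("breedNames", "GenotypePanel", function(x)
  sort(unique(as.character(colData(x)$breed))))

setMethod("snpInfo", "GenotypePanel", function(x) {
  rd <- rowData(x)
  data.frame(snp = rownames(x), chrom = as.character(rd$chrom),
             pos = as.integer(rd$pos), row.names = NULL,
             stringsAsFactors = FALSE)
})

setMethod("freqs", "FreqTable", function(x) x@freq)
setMethod("nObs", "FreqTable", function(x) x@nObs)

setMethod("show", "GenotypePanel", function(object) {
  d <- dosages(object)
  miss <- mean(is.na(d))
  cat(sprintf("GenotypePanel: %d SNPs x %d individuals, %d breeds (%.2f%% missing)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$breed)), 100 * miss))
  cat("chromosomes:", paste(unique(as.character(rowData(object)$chrom)),
                            collapse = " "), "\n")
})

setMethod("show", "FreqTable", function(object) {
  cat(sprintf("FreqTable: %d breeds x %d SNPs (%d undefined cells)\n",
              nrow(object@freq), ncol(object@freq), sum(is.nan(object@freq))))
})

setMethod("show", "QCReport", function(object) {
  cat("SNP QC cascade:\n")
  cat(sprintf("  input            %d\n", object@nInput))
  cat(sprintf("  - call rate      %d\n", object@nDroppedCallrate))
  cat(sprintf("  - monomorphic    %d\n", object@nDroppedMonomorphic))
  cat(sprintf("  - HWE (q-value)  %d\n", object@nDroppedHwe))
  cat(sprintf("  retained         %d\n", object@nRetained))
})

setMethod("show", "OrdinationResult", function(object) {
  k <- min(5L, length(object@eigenvalues))
  cat(sprintf("%s: %d axes over %d entities\n", object@method[1],
              length(object@eigenvalues), nrow(object@scores)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", object@varFraction[seq_len(k)]), collapse = " "),
      if (length(object@eigenvalues) > k) "..." else "", "\n")
})

setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf("SpatialGraph: %d nodes, %d edges\n", length(object@nodes),
              sum(object@adjacency) / 2))
})

setMethod("show", "SpcaResult", function(object) {
  k <- min(3L, length(object@eigenvalues))
  cat(sprintf("SpcaResult: %d breeds, %d axes\n",
              nrow(object@scores), length(object@eigenvalues)))
  cat("  leading Moran's I:",
      paste(sprintf("%.3f", object@moranAxis[seq_len(k)]), collapse = " "), "\n")
})

setMethod("show", "AdmixtureResult", function(object) {
  cat(sprintf("AdmixtureResult: K = %d, %d individuals, %d iterations (%s)\n",
              object@K, nrow(object@Q), object@nIter,
              if (object@converged) "converged" else "max iterations"))
  cat(sprintf("  final log-likelihood: %.3f\n",
              object@loglik[length(object@loglik)]))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d SNPs, %d groups, %d breeds (+%d hybrids), seed %d\n",
              object@nSnps, nrow(object@groups), nrow(object@breeds),
              nrow(object@hybrids), as.integer(object@seed)))
})
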