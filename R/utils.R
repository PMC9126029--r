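#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm sd var cor qnorm rbinom runif rgamma setNames
#' @importFrom utils read.table write.table head tail
NULL

## -log10 of the upper-tail standard-normal probability of z.
## Used by every scan that standardizes a statistic to z-scores.
neglog10_upper <- function(z) -pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)

## -log10 of the two-sided standard-normal probability of z.
neglog10_twosided <- function(z) {
  -(log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

## TSV writer used by all exporters: literal "NA", no quoting, tab separated.
write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

## 1-based closed [start, end] -> BED 0-based half-open.
to_bed <- function(chrom, start_bp, end_bp, name = ".", score = 0) {
  data.frame(chrom = chrom, start = start_bp - 1L, end = end_bp,
             name = name, score = score, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
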