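# Run code with a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a stage seed from a root seed; keeps results < 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + match(stage, c(
    "chrom", "abundance", "hfa", "cv", "perm", "roc", "decoy"
  )) * 1009L) %% 2147483629L
}

#' Write a data.frame as tab-separated text (UTF-8, '.' decimal, header, NA
#' for missing)
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#' @param path input file.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
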