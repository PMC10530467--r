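# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a semicolon-delimited annotation field into a character set
#'
#' Empty strings, `NA` and the literal placeholders used in annotation tables
#' ("no data", "not found", "ns", "-", ".") all map to the empty set.
#' @param x character vector of length 1
#' @return character vector (possibly empty), trimmed, duplicates removed
#' @keywords internal
split_set <- function(x) {
  if (length(x) == 0 || is.na(x)) return(character(0))
  x <- trimws(x)
  if (x %in% c("", "no data", "not found", "ns", "-", ".", "NA")) {
    return(character(0))
  }
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  unique(out[nzchar(out)])
}

join_set <- function(x) paste(sort(unique(x)), collapse = ";")

# Numeric-aware chromosome ordering key ("chr1" < "chr2" < "chr10" < "chrX").
chrom_order_key <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(x))
  num[toupper(x) == "X"] <- 23
  num[toupper(x) == "Y"] <- 24
  num[toupper(x) %in% c("M", "MT")] <- 25
  num[is.na(num)] <- 26
  num
}

# Canonical per-record variant ordering used by every module's output.
variant_order <- function(df) {
  order(chrom_order_key(df$chrom), df$pos, df$alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# write.table with the conventions used for every TSV the package emits
# (bit-stable: no quoting, no row names, "." for NA).
write_tsv <- function(df, path, na = ".") {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = na)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "."), ...)
}
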