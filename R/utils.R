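#' @import methods
#' @importFrom stats rbinom rnorm runif setNames rpois
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

## complement lookup including N
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a character sequence
#' @param x single nucleotide string (A/C/G/T/N, uppercase)
#' @return reverse-complemented string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## fast vector form used by the simulator (character vector of single bases)
revcomp_vec <- function(v) rev(unname(.comp[v]))

#' Check a nucleotide alphabet
#' @keywords internal
check_alphabet <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  invisible(TRUE)
}

#' GC content of a sequence
#'
#' GC base count divided by unambiguous base count; ambiguous bases (N) are
#' excluded from both numerator and denominator.
#'
#' @param x nucleotide string or `DNAString`
#' @return proportion in \[0,1\]
#' @export
gc_content <- function(x) {
  if (!is(x, "DNAString")) x <- Biostrings::DNAString(as.character(x))
  f <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  sum(f[c("G", "C")]) / sum(f)
}

#' Rotate a circular sequence
#'
#' @param x nucleotide string
#' @param offset new origin (1-based); position `offset` becomes position 1
#' @return rotated string of the same length
#' @export
rotate_seq <- function(x, offset) {
  n <- nchar(x)
  offset <- ((offset - 1) %% n) + 1
  if (offset == 1) return(x)
  paste0(substr(x, offset, n), substr(x, 1, offset - 1))
}

## map 1-based positions through a rotation that made `offset` position 1
rotate_pos <- function(pos, offset, len) ((pos - offset) %% len) + 1

## substring by interval, tolerating circular wrap when end > len
substr_circ <- function(x, start, end) {
  n <- nchar(x)
  if (end <= n) return(substr(x, start, end))
  paste0(substr(x, start, n), substr(x, 1, end - n))
}

## random DNA string
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## IRanges helper: data.frame(start,end) -> IRanges
as_iranges <- function(df) IRanges::IRanges(start = df$start, end = df$end)

## interval complement of `ir` within [1, len], merged and as data.frame
interval_complement <- function(ir, len) {
  cov <- IRanges::reduce(ir)
  gaps <- IRanges::gaps(cov, start = 1, end = len)
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}

#' Construct an annotated genome
#'
#' A light container for one organelle sequence plus typed features.
#' Intervals are 1-based closed throughout the package.
#'
#' @param id genome identifier
#' @param seq nucleotide string (uppercase A/C/G/T/N)
#' @param topology `"circular"` or `"linear"`
#' @param features `data.frame` with columns `type`, `start`, `end`,
#'   `strand`, `name`; may be empty
#' @return an object of class `annotated_genome`
#' @export
annotated_genome <- function(id, seq, topology = c("circular", "linear"),
                             features = NULL) {
  topology <- match.arg(topology)
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence for genome '", id, "'")
  check_alphabet(seq, paste0("genome '", id, "'"))
  if (is.null(features))
    features <- data.frame(type = character(), start = integer(),
                           end = integer(), strand = character(),
                           name = character())
  stopifnot(all(c("type", "start", "end", "strand", "name") %in% names(features)))
  if (nrow(features)) {
    bad <- features$start < 1 | features$end > nchar(seq) |
      features$start > features$end
    if (any(bad))
      stop("feature(s) out of bounds in genome '", id, "': ",
           paste(features$name[bad], collapse = ", "))
  }
  structure(list(id = id, seq = seq, topology = topology,
                 features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d features, GC %.2f%%\n",
              x$id, format(nchar(x$seq), big.mark = ","), x$topology,
              nrow(x$features), 100 * gc_content(x$seq)))
  invisible(x)
}

#' @export
length.annotated_genome <- function(x) nchar(x$seq)

## coerce annotated_genome | DNAString | character -> plain string
as_seq <- function(x) {
  if (is(x, "annotated_genome")) return(x$seq)
  toupper(as.character(x))
}

## external tool discovery
find_tool <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p))
    stop("required external tool '", name, "' not found on PATH", call. = FALSE)
  unname(p)
}

## write a TSV with '#'-prefixed header lines, the package's one dialect
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in c(comments, "coordinates: 1-based inclusive"))
    writeLines(paste0("# ", cm), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    df[] <- lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- "."
      col
    })
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, na.strings = ".")
}
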