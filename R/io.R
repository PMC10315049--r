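#' Read a FASTA file
#'
#' @param path FASTA file (plain or gzipped)
#' @return named `DNAStringSet`; names carry the full description line
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(x) && any(Biostrings::width(x) == 0L))
    stop("empty sequence record(s) in ", path)
  x
}

#' Write sequences to FASTA
#'
#' @param x named `DNAStringSet`, named character vector, or
#'   `annotated_genome`
#' @param path output path
#' @export
write_fasta <- function(x, path) {
  if (is(x, "annotated_genome")) x <- setNames(c(x$seq), x$id)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read features from GFF3
#'
#' Returns the package's flat feature table: `type`, `start`, `end`
#' (1-based closed, as in the file), `strand`, `name` plus `seqid` and
#' `attributes`. Features are validated against `seq_len` when given.
#'
#' @param path GFF3 file
#' @param seq_len optional named integer vector of sequence lengths for
#'   bounds checking
#' @return data.frame of features
#' @export
read_gff3 <- function(path, seq_len = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##gff-version", lines[1]))
    stop("missing ##gff-version pragma in ", path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body))
    return(data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), name = character(),
                      attributes = character()))
  f <- read.table(text = body, sep = "\t", quote = "",
                  stringsAsFactors = FALSE,
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attributes"))
  if (any(!f$strand %in% c("+", "-", ".")))
    stop("unknown strand value in ", path)
  if (any(f$start < 1 | f$end < f$start))
    stop("invalid coordinates in ", path)
  if (!is.null(seq_len)) {
    lim <- seq_len[f$seqid]
    bad <- !is.na(lim) & f$end > lim
    if (any(bad))
      stop("feature(s) beyond sequence end in ", path, " (",
           paste(head(f$seqid[bad]), collapse = ", "), ")")
  }
  nm <- sub(".*(?:^|;)(?:Name|ID)=([^;]+).*", "\\1", f$attributes)
  nm[!grepl("(?:^|;)(?:Name|ID)=", f$attributes)] <- NA_character_
  data.frame(seqid = f$seqid, type = f$type, start = f$start, end = f$end,
             strand = f$strand, name = nm, attributes = f$attributes,
             stringsAsFactors = FALSE)
}

#' Write features to GFF3
#'
#' @param features data.frame with `seqid` (optional if `seqid` given),
#'   `type`, `start`, `end`, `strand`, `name`, optional `attributes`
#' @param path output path
#' @param seqid default sequence id when `features$seqid` is absent
#' @param source value for GFF column 2
#' @export
write_gff3 <- function(features, path, seqid = NULL, source = "mitocomp") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    sq <- if (!is.null(features$seqid)) features$seqid else
      rep(seqid %||% "seq", nrow(features))
    attr_col <- if (!is.null(features$attributes) &&
                    all(nzchar(features$attributes)))
      features$attributes
    else
      ifelse(is.na(features$name), ".", paste0("Name=", features$name))
    strand <- features$strand
    strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
    writeLines(paste(sq, source, features$type, features$start,
                     features$end, ".", strand, ".", attr_col, sep = "\t"),
               con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
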