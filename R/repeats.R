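## maximal exact matches >= k between s1 and s2 (or within s1 when self),
## found as runs of shared k-mers along diagonals: a maximal match of
## length len >= k is exactly a run of len-k+1 consecutive shared k-mers
## on one diagonal, and runs are left/right maximal by construction.
.kmer_match_runs <- function(s1, s2 = NULL, k, self = is.null(s2)) {
  n1 <- nchar(s1)
  if (n1 < k) return(data.frame(start1 = integer(), start2 = integer(),
                                len = integer()))
  km1 <- substring(s1, 1:(n1 - k + 1), k:n1)
  if (self) {
    km2 <- km1
  } else {
    n2 <- nchar(s2)
    if (n2 < k) return(data.frame(start1 = integer(), start2 = integer(),
                                  len = integer()))
    km2 <- substring(s2, 1:(n2 - k + 1), k:n2)
  }
  d1 <- data.frame(kmer = km1, p1 = seq_along(km1), stringsAsFactors = FALSE)
  d2 <- data.frame(kmer = km2, p2 = seq_along(km2), stringsAsFactors = FALSE)
  m <- merge(d1, d2, by = "kmer")
  if (self) m <- m[m$p2 > m$p1, , drop = FALSE]
  if (!nrow(m)) return(data.frame(start1 = integer(), start2 = integer(),
                                  len = integer()))
  dg <- m$p2 - m$p1
  o <- order(dg, m$p1)
  p1 <- m$p1[o]; dg <- dg[o]
  newrun <- c(TRUE, diff(p1) != 1L | diff(dg) != 0L)
  run_id <- cumsum(newrun)
  starts <- p1[newrun]
  lens <- tabulate(run_id) + k - 1L
  data.frame(start1 = starts, start2 = starts + dg[newrun], len = lens)
}

## circular canonicalisation of a pair list against genome length L
.canon_pairs <- function(df, L, circular) {
  if (!nrow(df)) return(df)
  if (circular) {
    df$len <- pmin(df$len, L)
    df$start1 <- ((df$start1 - 1L) %% L) + 1L
    df$start2 <- ((df$start2 - 1L) %% L) + 1L
  }
  swap <- df$start2 < df$start1
  tmp <- df$start1[swap]; df$start1[swap] <- df$start2[swap]
  df$start2[swap] <- tmp
  df <- df[df$start1 != df$start2, , drop = FALSE]
  df[!duplicated(df[c("start1", "start2", "len")]), , drop = FALSE]
}

## drop pairs whose two copies overlap (tandem-style), circularity-aware
.drop_overlapping <- function(df, L, circular) {
  if (!nrow(df)) return(df)
  e1 <- df$start1 + df$len - 1L
  e2 <- df$start2 + df$len - 1L
  ov <- e1 >= df$start2
  if (circular) ov <- ov | (e2 > L & ((e2 - 1L) %% L) + 1L >= df$start1)
  df[!ov, , drop = FALSE]
}

## In a doubled circular sequence a repeat whose copy crosses the origin
## also produces truncated images near the ends of the doubled string.
## A pair P is such an image of a longer pair Q (same strand relation)
## when both of P's copies sit inside Q's copies at offsets consistent
## with trimming Q's exact match. Input must be sorted by length desc.
.dedup_modular_submatches <- function(pairs, L) {
  n <- nrow(pairs)
  if (n < 2L) return(pairs)
  keep <- rep(TRUE, n)
  inside <- function(ps, plen, qs, qlen) {
    t <- (ps - qs) %% L
    if (t + plen > qlen) NA_integer_ else t
  }
  consistent <- function(i, j) {      # is i a trimmed image of j?
    plen <- pairs$length[i]; qlen <- pairs$length[j]
    for (sw in 1:2) {
      p1 <- if (sw == 1) pairs$start1[i] else pairs$start2[i]
      p2 <- if (sw == 1) pairs$start2[i] else pairs$start1[i]
      t1 <- inside(p1, plen, pairs$start1[j], qlen)
      t2 <- inside(p2, plen, pairs$start2[j], qlen)
      if (is.na(t1) || is.na(t2)) next
      if (pairs$relation[j] == "direct") {
        if (t1 == t2) return(TRUE)
      } else {
        if (t1 + plen + t2 == qlen) return(TRUE)
      }
    }
    FALSE
  }
  for (i in 2:n) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (pairs$length[j] <= pairs$length[i]) next
      if (pairs$relation[j] != pairs$relation[i]) next
      if (consistent(i, j)) { keep[i] <- FALSE; break }
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Find dispersed repeats in a genome
#'
#' Enumerates all maximal exact repeated segments of at least `min_len` bp,
#' in both direct and inverted orientation. Circular genomes are handled by
#' concatenation-doubling with modular deduplication, so the census is
#' invariant to the linearisation point. A greedy longest-first pass (ties
#' by coordinate) then selects non-redundant repeat units, masking copies
#' already claimed by a longer repeat; near-identical copies of an inexact
#' repeat family appear as several exact units.
#'
#' @param genome `annotated_genome` or nucleotide string
#' @param min_len minimal repeat size (bp)
#' @param circular treat the sequence as circular; defaults to the genome's
#'   topology (`TRUE` for a bare string)
#' @return list of class `repeat_census`: `pairs` (all maximal repeat pairs:
#'   `start1`, `end1`, `start2`, `end2`, `relation`, `length`, `identity`),
#'   `units` (greedy non-redundant subset), `n_units`, `largest`,
#'   `content` (union bp of all copies / genome length)
#' @export
find_repeats <- function(genome, min_len = 30,
                         circular = !is(genome, "annotated_genome") ||
                           genome$topology == "circular") {
  s <- as_seq(genome)
  L <- nchar(s)
  S <- if (circular) paste0(s, s) else s
  fwd <- .kmer_match_runs(S, k = min_len)
  if (circular && nrow(fwd))
    fwd <- fwd[(fwd$start2 - fwd$start1) %% L != 0L, , drop = FALSE]
  if (nrow(fwd)) fwd <- fwd[fwd$start1 <= L, , drop = FALSE]
  fwd <- .canon_pairs(fwd, L, circular)
  fwd <- .drop_overlapping(fwd, L, circular)

  rcS <- revcomp(S)
  nS <- nchar(S)
  inv <- .kmer_match_runs(S, rcS, k = min_len, self = FALSE)
  if (nrow(inv)) {
    ## map the reverse-complement coordinate back to forward coordinates
    inv$start2 <- nS - (inv$start2 + inv$len - 1L) + 1L
    inv <- inv[inv$start1 <= L, , drop = FALSE]
    inv <- .canon_pairs(inv, L, circular)
    inv <- .drop_overlapping(inv, L, circular)
  }
  mk <- function(df, rel) {
    if (!nrow(df))
      return(data.frame(start1 = integer(), end1 = integer(),
                        start2 = integer(), end2 = integer(),
                        relation = character(), length = integer(),
                        identity = numeric()))
    data.frame(start1 = df$start1, end1 = df$start1 + df$len - 1L,
               start2 = df$start2, end2 = df$start2 + df$len - 1L,
               relation = rel, length = df$len, identity = 1,
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(fwd, "direct"), mk(inv, "inverted"))
  pairs <- pairs[order(-pairs$length, pairs$start1, pairs$start2), ,
                 drop = FALSE]
  if (circular) pairs <- .dedup_modular_submatches(pairs, L)
  rownames(pairs) <- NULL

  ## greedy longest-first unit selection: a pair is redundant when both of
  ## its copies are already >=90% covered by selected copies
  copy_ranges <- function(st, en) {
    .fold_intervals(data.frame(start = st, end = pmin(en, if (circular) 2L * L else L)), L)
  }
  mask <- IRanges::IRanges()
  sel <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    c1 <- as_iranges(copy_ranges(pairs$start1[i], pairs$end1[i]))
    c2 <- as_iranges(copy_ranges(pairs$start2[i], pairs$end2[i]))
    covered <- function(ir) {
      if (!length(mask)) return(0)
      sum(IRanges::width(IRanges::intersect(ir, mask))) / sum(IRanges::width(ir))
    }
    if (covered(c1) < 0.9 || covered(c2) < 0.9) {
      sel[i] <- TRUE
      mask <- IRanges::reduce(c(mask, c1, c2))
    }
  }
  units <- pairs[sel, , drop = FALSE]
  all_copies <- IRanges::reduce(c(
    as_iranges(copy_ranges(pairs$start1, pairs$end1)),
    as_iranges(copy_ranges(pairs$start2, pairs$end2))))
  structure(list(pairs = pairs, units = units, n_units = nrow(units),
                 largest = if (nrow(pairs)) max(pairs$length) else 0L,
                 content = sum(IRanges::width(all_copies)) / L,
                 genome_length = L, min_len = min_len,
                 circular = circular),
            class = "repeat_census")
}

#' @export
print.repeat_census <- function(x, ...) {
  cat(sprintf(paste0("<repeat_census> %d units (%d maximal pairs) >= %d bp; ",
                     "largest %d bp; content %.2f%%\n"),
              x$n_units, nrow(x$pairs), x$min_len, x$largest,
              100 * x$content))
  invisible(x)
}

#' Estimate repeat-mediated recombination frequency from long reads
#'
#' Each read is tested against the four junction conformations of a repeat
#' pair (two parental, two recombinant). A read counts only if it spans one
#' repeat copy entirely plus at least `flank` bp of unique sequence on both
#' sides, each flank matching one conformation at `read_identity` or
#' better; the conformation is assigned by the best-scoring flank pair and
#' ties are discarded. Frequency is recombinant / total spanning reads.
#'
#' @param genome `annotated_genome` or string the repeat lives in
#' @param rpt one row of a repeat pair table (`start1`, `end1`, `start2`,
#'   `end2`, `relation`), or a list with those fields
#' @param reads `DNAStringSet` or character vector of long reads
#' @param flank required unique flank (bp) on each side
#' @param read_identity minimum per-flank alignment identity
#' @return list of class `recombination_assay`: `counts` (parental_1,
#'   parental_2, recombinant_1, recombinant_2, ambiguous), `total`,
#'   `frequency` (NA when no read spans)
#' @export
recombination_frequency <- function(genome, rpt, reads, flank = 100,
                                    read_identity = 0.75) {
  s <- as_seq(genome)
  L <- nchar(s)
  st1 <- rpt$start1; en1 <- rpt$end1; st2 <- rpt$start2; en2 <- rpt$end2
  rel <- rpt$relation %||% "direct"
  rlen <- en1 - st1 + 1L
  if (rlen <= 100L)
    stop("assay requires repeat pairs larger than 100 bp")
  if (st1 - flank < 1L || en2 + flank > L)
    stop("repeat too close to sequence end; need ", flank, " bp flanks")
  if (st2 - en1 - 1L < 2L * flank)
    stop("repeat copies closer than 2 x flank; assay refused (overlap)")
  sub <- function(a, b) substr(s, a, b)
  A <- sub(st1 - flank, st1 - 1L); B <- sub(en1 + 1L, en1 + flank)
  C <- sub(st2 - flank, st2 - 1L); D <- sub(en2 + 1L, en2 + flank)
  R1 <- sub(st1, en1)
  ## left-side and right-side flank references per conformation:
  ## direct:   P1=A.R.B  P2=C.R.D  X1=A.R.D  X2=C.R.B
  ## inverted: P1=A.R.B  P2=C.R'.D X1=A.R.rc(C)  X2=rc(B).R'.D
  if (rel == "direct") {
    conf <- list(parental_1 = c(A, B), parental_2 = c(C, D),
                 recombinant_1 = c(A, D), recombinant_2 = c(C, B))
  } else {
    conf <- list(parental_1 = c(A, B), parental_2 = c(C, D),
                 recombinant_1 = c(A, revcomp(C)),
                 recombinant_2 = c(revcomp(B), D))
  }
  reads <- as.character(reads)
  counts <- c(parental_1 = 0L, parental_2 = 0L,
              recombinant_1 = 0L, recombinant_2 = 0L, ambiguous = 0L)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score_in <- function(pattern, read) {
    ## pattern must be wholly contained in the read
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pattern), Biostrings::DNAString(read),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 2, gapExtension = 1)
    n_id <- Biostrings::nmatch(pa)
    list(score = Biostrings::score(pa), identity = n_id / nchar(pattern),
         at = Biostrings::start(Biostrings::subject(pa)))
  }
  rc_reads <- vapply(reads, revcomp, "")
  for (i in seq_along(reads)) {
    rd <- reads[i]
    if (nchar(rd) < rlen + 2L * flank) next
    ## orient the read by the repeat body
    fw <- score_in(R1, rd); rv <- score_in(R1, rc_reads[i])
    if (max(fw$identity, rv$identity) < read_identity) next
    rd <- if (fw$score >= rv$score) rd else rc_reads[i]
    body <- if (fw$score >= rv$score) fw else rv
    left <- lapply(conf, function(fl) score_in(fl[1], rd))
    right <- lapply(conf, function(fl) score_in(fl[2], rd))
    tot <- vapply(seq_along(conf), function(k)
      left[[k]]$score + right[[k]]$score, 0)
    ok <- vapply(seq_along(conf), function(k)
      left[[k]]$identity >= read_identity &&
        right[[k]]$identity >= read_identity &&
        left[[k]]$at < body$at && right[[k]]$at > body$at, NA)
    if (!any(ok)) next
    tot[!ok] <- -Inf
    top <- which(tot == max(tot))
    if (length(top) > 1L) counts["ambiguous"] <- counts["ambiguous"] + 1L
    else counts[top] <- counts[top] + 1L
  }
  total <- sum(counts[1:4])
  structure(list(counts = counts, total = total,
                 frequency = if (total > 0)
                   unname((counts["recombinant_1"] + counts["recombinant_2"]) /
                            total) else NA_real_,
                 repeat_pair = list(start1 = st1, end1 = en1, start2 = st2,
                                    end2 = en2, relation = rel),
                 flank = flank),
            class = "recombination_assay")
}

#' @export
print.recombination_assay <- function(x, ...) {
  cat(sprintf(paste0("<recombination_assay> repeat %d-%d / %d-%d (%s): ",
                     "P1=%d P2=%d X1=%d X2=%d ambiguous=%d; frequency=%s\n"),
              x$repeat_pair$start1, x$repeat_pair$end1,
              x$repeat_pair$start2, x$repeat_pair$end2,
              x$repeat_pair$relation,
              x$counts["parental_1"], x$counts["parental_2"],
              x$counts["recombinant_1"], x$counts["recombinant_2"],
              x$counts["ambiguous"],
              if (is.na(x$frequency)) "undefined" else
                sprintf("%.4f", x$frequency)))
  invisible(x)
}

#' Export a repeat census as TSV
#' @param census `repeat_census`
#' @param path output path
#' @export
export_repeats <- function(census, path) {
  write_tsv(census$units, path, comments = c(
    sprintf("repeat units (greedy longest-first non-redundant), min_len=%d",
            census$min_len),
    sprintf("n_units=%d largest=%d content=%.4f",
            census$n_units, census$largest, census$content)))
}
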