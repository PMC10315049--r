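#' Local similarity search between two sequences
#'
#' Seed-and-extend local alignment via the NCBI `blastn` binary (word size
#' 11 by default, low-complexity filtering off so that every interval pair
#' containing an exact word-size seed is examined). Percent identity is
#' matches / alignment columns, gap columns included. Hits are filtered to
#' `identity >= min_identity` and alignment length `>= min_hit_len`; both
#' strands are searched. With `circular_subject = TRUE` the subject is
#' concatenation-doubled and hits deduplicated modulo its length, so the
#' result is invariant to the subject's linearisation point (hits crossing
#' the origin keep `send > subject length`).
#'
#' @param query sequence(s): string, named character vector, `DNAStringSet`
#'   or `annotated_genome`
#' @param subject single sequence (string / `DNAString` / `annotated_genome`)
#' @param min_identity minimum identity, proportion in (0, 1]
#' @param min_hit_len minimum alignment length (bp)
#' @param word_size exact-seed length
#' @param circular_subject double the subject and deduplicate modulo length
#' @param keep_alignment keep the gapped aligned strings (`qseq`, `sseq`)
#' @param evalue blastn e-value cutoff
#' @return data.frame of class `alignment_hits`: `qseqid`, `qstart`, `qend`,
#'   `sstart`, `send` (always `sstart <= send`), `strand`, `length`
#'   (alignment columns), `matches`, `mismatch`, `gaps`, `identity`, `score`
#'   and optionally `qseq`/`sseq`
#' @export
local_search <- function(query, subject, min_identity = 0.85,
                         min_hit_len = 90, word_size = 11,
                         circular_subject = FALSE, keep_alignment = TRUE,
                         evalue = 10) {
  stopifnot(min_identity > 0, min_identity <= 1, min_hit_len >= 1)
  qs <- .as_named_seqs(query, "query")
  ss <- as_seq(subject)
  if (!nchar(ss)) stop("empty subject sequence")
  check_alphabet(ss, "subject")
  for (i in seq_along(qs)) check_alphabet(qs[[i]], names(qs)[i])
  slen <- nchar(ss)
  if (circular_subject) ss <- paste0(ss, ss)

  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  write_fasta(qs, qf)
  write_fasta(c(subject_ = ss), sf)

  fields <- c("qseqid", "qstart", "qend", "sstart", "send", "pident",
              "length", "mismatch", "gapopen", "gaps", "bitscore", "sstrand")
  if (keep_alignment) fields <- c(fields, "qseq", "sseq")
  out <- system2(find_tool("blastn"),
                 c("-query", qf, "-subject", sf,
                   "-word_size", word_size,
                   "-perc_identity", formatC(min_identity * 100, format = "f"),
                   "-evalue", format(evalue),
                   "-dust", "no", "-soft_masking", "false",
                   "-outfmt", shQuote(paste("6", paste(fields, collapse = " ")))),
                 stdout = TRUE, stderr = FALSE)
  hits <- .parse_hit_table(out, fields)
  hits <- hits[hits$length >= min_hit_len &
                 hits$identity >= min_identity - 1e-9, , drop = FALSE]
  if (circular_subject && nrow(hits)) {
    dup <- hits$sstart > slen
    hits$sstart[dup] <- hits$sstart[dup] - slen
    hits$send[dup] <- hits$send[dup] - slen
    key <- with(hits, paste(qseqid, qstart, qend, sstart, send, strand))
    hits <- hits[!duplicated(key), , drop = FALSE]
    ## drop hits whose query interval lies within a longer hit on the same
    ## (modular) diagonal: split twins of an origin-crossing alignment
    diag_key <- ifelse(hits$strand == "+",
                       (hits$sstart - hits$qstart) %% slen,
                       (hits$send + hits$qstart) %% slen)
    grp <- paste(hits$qseqid, hits$strand, diag_key)
    keep <- rep(TRUE, nrow(hits))
    for (g in unique(grp[duplicated(grp)])) {
      i <- which(grp == g)
      for (a in i) for (b in i) {
        if (a == b || !keep[b]) next
        if (hits$qstart[a] <= hits$qstart[b] &&
            hits$qend[a] >= hits$qend[b] &&
            hits$length[a] > hits$length[b]) keep[b] <- FALSE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$qseqid, hits$qstart, hits$sstart), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "subject_length") <- slen
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

.as_named_seqs <- function(x, default_id) {
  if (is(x, "annotated_genome")) return(setNames(c(x$seq), x$id))
  if (is(x, "DNAStringSet")) {
    v <- as.character(x)
    if (is.null(names(v))) names(v) <- paste0(default_id, seq_along(v))
    return(v)
  }
  nm <- names(x)
  v <- toupper(as.character(x))
  names(v) <- nm
  if (any(!nzchar(v))) stop("empty ", default_id, " sequence")
  if (is.null(names(v)))
    names(v) <- if (length(v) == 1L) default_id else
      paste0(default_id, seq_along(v))
  v
}

.parse_hit_table <- function(lines, fields) {
  empty <- data.frame(qseqid = character(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      strand = character(), length = integer(),
                      matches = integer(), mismatch = integer(),
                      gapopen = integer(), gaps = integer(),
                      identity = numeric(),
                      score = numeric(), qseq = character(),
                      sseq = character(), stringsAsFactors = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  tab <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                    col.names = fields, quote = "")
  strand <- ifelse(tab$sstrand == "minus", "-", "+")
  s_lo <- pmin(tab$sstart, tab$send)
  s_hi <- pmax(tab$sstart, tab$send)
  out <- data.frame(qseqid = as.character(tab$qseqid), qstart = tab$qstart,
                    qend = tab$qend, sstart = s_lo, send = s_hi,
                    strand = strand, length = tab$length,
                    matches = tab$length - tab$mismatch - tab$gaps,
                    mismatch = tab$mismatch, gapopen = tab$gapopen,
                    gaps = tab$gaps,
                    identity = (tab$length - tab$mismatch - tab$gaps) /
                      tab$length,
                    score = tab$bitscore, stringsAsFactors = FALSE)
  if ("qseq" %in% fields) {
    out$qseq <- tab$qseq
    ## store subject alignment string in subject-forward orientation flag
    out$sseq <- tab$sseq
  }
  out
}

#' Chain alignment hits into collinear blocks
#'
#' Anchors are chained by dynamic programming under monotone-coordinate and
#' uniform-strand constraints with inter-anchor gaps at most `max_gap` in
#' both genomes; chain score is anchored matching bp minus
#' `gap_penalty` x gap bp, ties broken by leftmost query coordinate. Chains
#' are extracted best-first, each hit joining at most one block.
#'
#' @param hits `alignment_hits` from [local_search()] for one genome pair
#' @param max_gap maximum inter-anchor gap (bp) in either genome
#' @param gap_penalty per-bp chain gap penalty
#' @param one_to_one drop lower-scoring chains that mostly re-cover query
#'   or subject span already claimed by a better chain, so each genomic
#'   interval belongs to at most one block (duplicate copies then fall
#'   outside block coverage, as in locally-collinear-block synteny)
#' @return data.frame of class `collinear_blocks`: `block`, `strand`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `n_hits`, `anchored_bp`,
#'   `score`; member hits are kept in `attr(, "members")` /
#'   `attr(, "hits")`
#' @export
build_blocks <- function(hits, max_gap = 1000, gap_penalty = 0.01,
                         one_to_one = TRUE) {
  empty <- data.frame(block = integer(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      n_hits = integer(), anchored_bp = integer(),
                      score = numeric())
  if (length(unique(hits$qseqid)) > 1L)
    stop("build_blocks expects hits from a single genome pair")
  if (!nrow(hits)) {
    class(empty) <- c("collinear_blocks", "data.frame")
    attr(empty, "members") <- list(); attr(empty, "hits") <- hits
    return(empty)
  }
  h <- as.data.frame(hits)
  n <- nrow(h)
  used <- rep(FALSE, n)
  ord <- order(h$qstart, h$qend)
  blocks <- list(); members <- list()
  repeat {
    idx <- ord[!used[ord]]
    if (!length(idx)) break
    k <- length(idx)
    f <- h$matches[idx]; pred <- rep(0L, k)
    if (k > 1) for (i in 2:k) {
      hi <- idx[i]
      for (j in 1:(i - 1)) {
        hj <- idx[j]
        if (h$strand[hi] != h$strand[hj]) next
        gq <- h$qstart[hi] - h$qend[hj] - 1L
        if (gq < 0L || gq > max_gap) next
        gs <- if (h$strand[hi] == "+") h$sstart[hi] - h$send[hj] - 1L
              else h$sstart[hj] - h$send[hi] - 1L
        if (gs < 0L || gs > max_gap) next
        cand <- f[j] + h$matches[hi] - gap_penalty * (gq + gs)
        if (cand > f[i] + 1e-9) { f[i] <- cand; pred[i] <- j }
      }
    }
    best <- which.max(f)        # ties: smallest index = leftmost q
    chain <- integer()
    at <- best
    while (at != 0L) { chain <- c(idx[at], chain); at <- pred[at] }
    used[chain] <- TRUE
    blocks[[length(blocks) + 1L]] <- data.frame(
      strand = h$strand[chain[1]],
      q_start = min(h$qstart[chain]), q_end = max(h$qend[chain]),
      s_start = min(h$sstart[chain]), s_end = max(h$send[chain]),
      n_hits = length(chain), anchored_bp = sum(h$length[chain]),
      score = f[best], stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- chain
  }
  out <- do.call(rbind, blocks)
  if (one_to_one && nrow(out) > 1) {
    ## extraction order is best-first: keep a chain only if most of its
    ## span is novel on both axes
    keep <- logical(nrow(out))
    q_cov <- IRanges::IRanges(); s_cov <- IRanges::IRanges()
    frac_cov <- function(iv, cov) {
      if (!length(cov)) return(0)
      sum(IRanges::width(IRanges::intersect(iv, cov))) / IRanges::width(iv)
    }
    for (i in seq_len(nrow(out))) {
      qi <- IRanges::IRanges(out$q_start[i], out$q_end[i])
      si <- IRanges::IRanges(out$s_start[i], out$s_end[i])
      if (frac_cov(qi, q_cov) < 0.5 && frac_cov(si, s_cov) < 0.5) {
        keep[i] <- TRUE
        q_cov <- IRanges::reduce(c(q_cov, qi))
        s_cov <- IRanges::reduce(c(s_cov, si))
      }
    }
    out <- out[keep, , drop = FALSE]
    members <- members[keep]
  }
  o <- order(out$q_start, out$q_end)
  out <- out[o, , drop = FALSE]
  members <- members[o]
  out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("collinear_blocks", "data.frame")
  attr(out, "members") <- members
  attr(out, "hits") <- hits
  attr(out, "subject_length") <- attr(hits, "subject_length")
  out
}

## fold subject-side intervals of blocks back into [1, L] (circular wrap)
.fold_intervals <- function(df, len) {
  if (is.null(len) || !nrow(df)) return(df)
  wrap <- df$end > len
  if (!any(wrap)) return(df)
  folded <- rbind(
    df[!wrap, , drop = FALSE],
    data.frame(start = df$start[wrap], end = pmin(df$end[wrap], len)),
    data.frame(start = rep(1L, sum(wrap)), end = df$end[wrap] - len))
  folded[folded$start <= folded$end, , drop = FALSE]
}

#' Extract non-alignable regions from a pairwise comparison
#'
#' The complement of collinear-block coverage in each genome, with regions
#' separated by fewer than `merge_slack` covered bp merged, then filtered to
#' `>= min_region_len`. Region codes are `<pair><species letter><rank>`
#' in coordinate order (e.g. `CSC1` = pair CS, species C, region 1).
#'
#' @param genomeA,genomeB `annotated_genome`s (A was the query, B the
#'   subject of the comparison)
#' @param blocks `collinear_blocks` from [build_blocks()] on (A, B)
#' @param min_region_len minimum reported region length (bp)
#' @param merge_slack regions separated by fewer covered bp than this are
#'   merged
#' @param pair_label two-letter species-pair label; default from genome ids
#' @return named list of two data.frames (`code`, `genome`, `start`, `end`,
#'   `length`), one per genome
#' @export
nonalignable_regions <- function(genomeA, genomeB, blocks,
                                 min_region_len = 90, merge_slack = 50,
                                 pair_label = NULL) {
  la <- nchar(as_seq(genomeA)); lb <- nchar(as_seq(genomeB))
  ida <- if (is(genomeA, "annotated_genome")) genomeA$id else "A"
  idb <- if (is(genomeB, "annotated_genome")) genomeB$id else "B"
  if (is.null(pair_label))
    pair_label <- paste0(substr(ida, 1, 1), substr(idb, 1, 1))
  cov_a <- data.frame(start = blocks$q_start, end = blocks$q_end)
  cov_b <- .fold_intervals(
    data.frame(start = blocks$s_start, end = blocks$s_end),
    attr(blocks, "subject_length") %||% lb)
  one <- function(cov, len, id, letter) {
    gaps <- if (nrow(cov)) interval_complement(as_iranges(cov), len)
            else data.frame(start = 1L, end = len)
    if (nrow(gaps) > 1 && merge_slack > 0) {
      ir <- as_iranges(gaps)
      merged <- IRanges::reduce(ir, min.gapwidth = merge_slack)
      gaps <- data.frame(start = IRanges::start(merged),
                         end = IRanges::end(merged))
    }
    gaps$length <- gaps$end - gaps$start + 1L
    gaps <- gaps[gaps$length >= min_region_len, , drop = FALSE]
    if (!nrow(gaps))
      return(data.frame(code = character(), genome = character(),
                        start = integer(), end = integer(),
                        length = integer()))
    data.frame(code = paste0(pair_label, letter, seq_len(nrow(gaps))),
               genome = id, start = gaps$start, end = gaps$end,
               length = gaps$length, stringsAsFactors = FALSE)
  }
  out <- list(one(cov_a, la, ida, substr(ida, 1, 1)),
              one(cov_b, lb, idb, substr(idb, 1, 1)))
  names(out) <- c(ida, idb)
  out
}

#' Detect inversions from collinear blocks
#'
#' Minus-strand blocks above a length threshold, sorted by length
#' descending. Adjacent minus-strand blocks separated by less than
#' `merge_gap` in both genomes are merged first: insertions or deletions
#' inside one large inversion split its anchor chain, but it is still one
#' rearrangement.
#'
#' @param blocks `collinear_blocks`
#' @param min_len minimum query-side span (bp)
#' @param merge_gap maximum separation (bp) for merging split
#'   minus-strand blocks
#' @return data.frame: `q_start`, `q_end`, `s_start`, `s_end`, `length`
#' @export
detect_inversions <- function(blocks, min_len = 1000, merge_gap = 5000) {
  inv <- blocks[blocks$strand == "-", , drop = FALSE]
  inv <- inv[order(inv$q_start), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(inv))) {
    cur <- inv[i, c("q_start", "q_end", "s_start", "s_end")]
    if (length(merged)) {
      last <- merged[[length(merged)]]
      gap_q <- cur$q_start - last$q_end
      gap_s <- max(0, last$s_start - cur$s_end, cur$s_start - last$s_end)
      if (gap_q <= merge_gap && gap_s <= merge_gap) {
        last$q_end <- max(last$q_end, cur$q_end)
        last$s_start <- min(last$s_start, cur$s_start)
        last$s_end <- max(last$s_end, cur$s_end)
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- if (length(merged)) do.call(rbind, merged) else
    data.frame(q_start = integer(), q_end = integer(),
               s_start = integer(), s_end = integer())
  out$length <- out$q_end - out$q_start + 1L
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$length), , drop = FALSE]
}

#' Export alignment hits as 12-column tabular text
#'
#' The standard tabular pairwise-search dialect (1-based inclusive
#' coordinates); the e-value column is emitted as a `"."` placeholder.
#'
#' @param hits `alignment_hits`
#' @param path output path
#' @param query,subject names for a leading comment line
#' @export
export_hits <- function(hits, path, query = "query", subject = "subject") {
  df <- data.frame(query = if (nrow(hits)) hits$qseqid else character(),
                   subject = rep(subject, nrow(hits)),
                   pident = sprintf("%.2f", 100 * hits$identity),
                   length = hits$length, mismatch = hits$mismatch,
                   gapopen = hits$gapopen,
                   qstart = hits$qstart, qend = hits$qend,
                   sstart = ifelse(hits$strand == "+", hits$sstart, hits$send),
                   send = ifelse(hits$strand == "+", hits$send, hits$sstart),
                   evalue = rep(".", nrow(hits)), score = hits$score)
  write_tsv(df, path, comments = sprintf("hits: %s vs %s", query, subject))
}
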