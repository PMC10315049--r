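#' Detect chloroplast-derived regions in a mitogenome
#'
#' Searches the mitochondrial genome against its chloroplast genome
#' (identity >= `min_identity`, hits >= `min_len` bp) and collapses
#' qualifying hits into merged transferred regions on the mitochondrial
#' axis; totals are computed on the union. One copy of the chloroplast
#' inverted repeat is removed before searching by default (the largest
#' inverted self-duplication above `ir_min_len`); `remove_ir = FALSE`
#' restores full-length behaviour. When the chloroplast annotation carries
#' CDS features, each transferred gene copy is located by projecting the
#' annotation through the region's alignment and its pseudogenisation
#' status called against the chloroplast CDS.
#'
#' @param mt,cp `annotated_genome`s (or plain sequences)
#' @param min_identity minimum hit identity (default 0.85)
#' @param min_len minimum hit length (bp)
#' @param remove_ir drop one chloroplast inverted-repeat copy first
#' @param ir_min_len minimum inverted-repeat size considered an IR
#' @return list of class `transfer_summary`: `regions` (mt/cp intervals,
#'   strand, identity, length), `genes` (per transferred gene copy:
#'   region, name, status, cause), `total_bp` (union), `fraction`,
#'   `n_intact`, `n_pseudo`, `hits`
#' @export
detect_idt <- function(mt, cp, min_identity = 0.85, min_len = 90,
                       remove_ir = TRUE, ir_min_len = 8000) {
  mt_seq <- as_seq(mt)
  cp_seq <- as_seq(cp)
  if (!nchar(cp_seq)) stop("empty chloroplast genome")
  cp_feats <- if (is(cp, "annotated_genome")) cp$features else
    data.frame(type = character(), start = integer(), end = integer(),
               strand = character(), name = character())
  ir_removed <- NULL
  if (remove_ir && nchar(cp_seq) > 2 * ir_min_len) {
    self <- local_search(cp_seq, cp_seq, min_identity = 0.9,
                         min_hit_len = ir_min_len, keep_alignment = FALSE)
    inv <- self[self$strand == "-" & self$sstart > self$qend, , drop = FALSE]
    if (nrow(inv)) {
      top <- inv[which.max(inv$length), ]
      ir_removed <- c(top$sstart, top$send)
      cp_seq <- paste0(substr(cp_seq, 1, top$sstart - 1L),
                       substr(cp_seq, top$send + 1L, nchar(cp_seq)))
      keep <- cp_feats$end < top$sstart | cp_feats$start > top$send
      cp_feats <- cp_feats[keep, , drop = FALSE]
      w <- top$send - top$sstart + 1L
      later <- cp_feats$start > top$send
      cp_feats$start[later] <- cp_feats$start[later] - w
      cp_feats$end[later] <- cp_feats$end[later] - w
    }
  }
  hits <- local_search(mt_seq, cp_seq, min_identity = min_identity,
                       min_hit_len = min_len)
  L <- nchar(mt_seq)
  if (!nrow(hits)) {
    out <- list(regions = data.frame(region = integer(),
                                     mt_start = integer(), mt_end = integer(),
                                     cp_start = integer(), cp_end = integer(),
                                     strand = character(),
                                     identity = numeric(),
                                     length = integer()),
                genes = data.frame(region = integer(), name = character(),
                                   status = character(), cause = character()),
                total_bp = 0L, fraction = 0, n_intact = 0L, n_pseudo = 0L,
                hits = hits, ir_removed = ir_removed, genome_length = L)
    class(out) <- "transfer_summary"
    return(out)
  }
  un <- IRanges::reduce(IRanges::IRanges(hits$qstart, hits$qend))
  regions <- data.frame(region = seq_along(un),
                        mt_start = IRanges::start(un),
                        mt_end = IRanges::end(un))
  best <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    memb <- which(hits$qstart <= regions$mt_end[i] &
                    hits$qend >= regions$mt_start[i])
    best[i] <- memb[which.max(hits$score[memb])]
  }
  regions$cp_start <- hits$sstart[best]
  regions$cp_end <- hits$send[best]
  regions$strand <- hits$strand[best]
  regions$identity <- hits$identity[best]
  regions$length <- regions$mt_end - regions$mt_start + 1L

  genes <- data.frame(region = integer(), name = character(),
                      status = character(), cause = character(),
                      stringsAsFactors = FALSE)
  cds <- cp_feats[cp_feats$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    for (i in seq_len(nrow(regions))) {
      memb <- which(hits$qstart <= regions$mt_end[i] &
                      hits$qend >= regions$mt_start[i])
      for (hidx in memb) {
        h <- hits[hidx, ]
        ov <- which(cds$start <= h$send & cds$end >= h$sstart)
        for (gi in ov) {
          mt_iv <- .project_subject_interval(
            h, max(cds$start[gi], h$sstart), min(cds$end[gi], h$send))
          if (is.null(mt_iv)) next
          copy <- substr(mt_seq, mt_iv[1], mt_iv[2])
          if (h$strand == "-") copy <- revcomp(copy)
          ref <- substr(cp_seq, cds$start[gi], cds$end[gi])
          call <- tryCatch(call_pseudogene(copy, ref),
                           error = function(e)
                             list(status = "undetermined", cause = "error"))
          genes <- rbind(genes, data.frame(
            region = i, name = cds$name[gi], status = call$status,
            cause = call$cause, stringsAsFactors = FALSE))
        }
      }
    }
    genes <- genes[!duplicated(genes[c("name", "region")]), , drop = FALSE]
  }
  out <- list(regions = regions, genes = genes,
              total_bp = sum(IRanges::width(un)),
              fraction = sum(IRanges::width(un)) / L,
              n_intact = sum(genes$status == "intact"),
              n_pseudo = sum(genes$status == "pseudogene"),
              hits = hits, ir_removed = ir_removed, genome_length = L)
  class(out) <- "transfer_summary"
  out
}

## map a subject interval [a,b] (subject-forward coordinates within the
## hit) to query coordinates by walking the gapped alignment strings
.project_subject_interval <- function(hit, a, b) {
  if (is.null(hit$qseq) || is.na(hit$qseq)) return(NULL)
  qc <- strsplit(hit$qseq, "")[[1]]
  sc <- strsplit(hit$sseq, "")[[1]]
  qpos <- hit$qstart - 1L
  minus <- hit$strand == "-"
  spos <- if (minus) hit$send + 1L else hit$sstart - 1L
  qa <- qb <- NA_integer_
  for (i in seq_along(qc)) {
    if (qc[i] != "-") qpos <- qpos + 1L
    if (sc[i] != "-") spos <- spos + if (minus) -1L else 1L
    ## for minus-strand hits subject positions decrease; the window test
    ## holds either way and qa/qb accumulate the covered query range
    if (sc[i] != "-" && spos >= a && spos <= b && qc[i] != "-") {
      if (is.na(qa)) qa <- qpos
      qb <- qpos
    }
  }
  if (is.na(qa)) return(NULL)
  c(min(qa, qb), max(qa, qb))
}

#' @export
print.transfer_summary <- function(x, ...) {
  cat(sprintf(paste0("<transfer_summary> %d regions, %s bp (%.2f%% of ",
                     "mitogenome); gene copies: %d intact, %d pseudogene\n"),
              nrow(x$regions), format(x$total_bp, big.mark = ","),
              100 * x$fraction, x$n_intact, x$n_pseudo))
  invisible(x)
}

#' Call the pseudogenisation status of a transferred gene copy
#'
#' The copy is locally aligned to the reference CDS (both orientations).
#' It is intact when it covers at least `coverage` of the reference with
#' no net frame-disrupting indel and no internal stop codon; otherwise the
#' first disqualifying lesion in reference-coordinate order is reported,
#' with precedence frameshift < premature_stop < truncation on ties.
#'
#' @param mt_copy nucleotide string of the transferred copy
#' @param reference_cds the chloroplast CDS (length divisible by 3,
#'   starting with ATG)
#' @param coverage minimum aligned fraction of the reference for intactness
#' @param max_ambiguous maximum tolerated fraction of ambiguous bases
#' @return list: `status` (`"intact"`/`"pseudogene"`), `cause`
#'   (`"none"`, `"frameshift"`, `"premature_stop"`, `"truncation"`),
#'   `lesions` (data.frame of all lesions found)
#' @export
call_pseudogene <- function(mt_copy, reference_cds, coverage = 0.95,
                            max_ambiguous = 0.05) {
  ref <- toupper(as.character(reference_cds))
  copy <- toupper(as.character(mt_copy))
  if (nchar(ref) %% 3 != 0) stop("reference CDS length not divisible by 3")
  if (substr(ref, 1, 3) != "ATG") stop("reference CDS must start with ATG")
  n_amb <- nchar(copy) - sum(strsplit(copy, "")[[1]] %in% DNA_BASES)
  if (n_amb / nchar(copy) > max_ambiguous)
    stop("undetermined status: ambiguous bases exceed ",
         100 * max_ambiguous, "% of the copy")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  aln_one <- function(cp) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cp), Biostrings::DNAString(ref), type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
  a1 <- aln_one(copy); a2 <- aln_one(revcomp(copy))
  aln <- if (Biostrings::score(a1) >= Biostrings::score(a2)) a1 else a2
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s0 <- Biostrings::start(Biostrings::subject(aln))
  s1 <- Biostrings::end(Biostrings::subject(aln))
  cov <- (s1 - s0 + 1) / nchar(ref)

  lesions <- data.frame(pos = integer(), type = character(),
                        stringsAsFactors = FALSE)
  ## walk columns: indel runs and per-ref-position copy bases
  spos <- s0 - 1L
  net <- 0L
  run_len <- 0L; run_type <- ""; run_pos <- NA_integer_
  copy_at <- rep(NA_character_, nchar(ref))  # copy base on the ref grid
  frame_ok <- rep(FALSE, nchar(ref))
  flush_run <- function() {
    if (run_len > 0L && run_len %% 3L != 0L)
      lesions <<- rbind(lesions, data.frame(pos = run_pos,
                                            type = "frameshift_indel"))
  }
  for (i in seq_along(pat)) {
    gap_p <- pat[i] == "-"; gap_s <- sub[i] == "-"
    if (!gap_s) spos <- spos + 1L
    if (gap_p || gap_s) {
      this_type <- if (gap_p) "del" else "ins"
      if (run_len > 0L && run_type != this_type) { flush_run(); run_len <- 0L }
      if (run_len == 0L) { run_pos <- max(spos, s0); run_type <- this_type }
      run_len <- run_len + 1L
      net <- net + if (gap_p) -1L else 1L
    } else {
      flush_run(); run_len <- 0L
      copy_at[spos] <- pat[i]
      frame_ok[spos] <- net %% 3L == 0L
    }
  }
  flush_run()
  net_frameshift <- net %% 3L != 0L
  fs_pos <- if (nrow(lesions)) min(lesions$pos) else NA_integer_

  ## internal stops on the reference codon grid, in-frame segments only
  codon_starts <- seq(1L, nchar(ref) - 3L, by = 3L)  # exclude terminal codon
  stops <- c("TAA", "TAG", "TGA")
  stop_pos <- NA_integer_
  for (cs in codon_starts) {
    idx <- cs:(cs + 2L)
    if (any(is.na(copy_at[idx])) || !all(frame_ok[idx])) next
    if (paste(copy_at[idx], collapse = "") %in% stops) {
      stop_pos <- cs
      break
    }
  }

  out_lesions <- data.frame(pos = integer(), type = character(),
                            stringsAsFactors = FALSE)
  if (net_frameshift && !is.na(fs_pos))
    out_lesions <- rbind(out_lesions,
                         data.frame(pos = fs_pos, type = "frameshift"))
  if (!is.na(stop_pos))
    out_lesions <- rbind(out_lesions,
                         data.frame(pos = stop_pos, type = "premature_stop"))
  if (cov < coverage) {
    trunc_pos <- if (s0 > 1L) 1L else s1 + 1L
    out_lesions <- rbind(out_lesions,
                         data.frame(pos = trunc_pos, type = "truncation"))
  }
  if (!nrow(out_lesions))
    return(list(status = "intact", cause = "none", lesions = out_lesions))
  prec <- c(frameshift = 1L, premature_stop = 2L, truncation = 3L)
  out_lesions <- out_lesions[order(out_lesions$pos, prec[out_lesions$type]), ,
                             drop = FALSE]
  list(status = "pseudogene", cause = out_lesions$type[1],
       lesions = out_lesions)
}

#' Label transferred regions as ancestral or lineage-specific
#'
#' A region is ancestral when its sequence is found (at the detection
#' thresholds) in every other mitogenome supplied; otherwise
#' lineage-specific.
#'
#' @param summary `transfer_summary` for one species
#' @param mt own mitogenome the summary refers to
#' @param other_mts named list of the other species' mitogenomes
#' @param min_identity,min_len detection thresholds
#' @param min_coverage fraction of the region that must be recovered in
#'   another genome to count as present
#' @return character vector, one of `"ancestral"`/`"lineage_specific"`
#'   per region
#' @export
classify_idt_sharing <- function(summary, mt, other_mts,
                                 min_identity = 0.85, min_len = 90,
                                 min_coverage = 0.5) {
  mt_seq <- as_seq(mt)
  regs <- summary$regions
  if (!nrow(regs)) return(character())
  seqs <- setNames(substring(mt_seq, regs$mt_start, regs$mt_end),
                   paste0("region", regs$region))
  present <- matrix(FALSE, nrow(regs), length(other_mts))
  for (j in seq_along(other_mts)) {
    h <- local_search(seqs, as_seq(other_mts[[j]]),
                      min_identity = min_identity, min_hit_len = min_len,
                      circular_subject = TRUE, keep_alignment = FALSE)
    for (i in seq_len(nrow(regs))) {
      hh <- h[h$qseqid == paste0("region", regs$region[i]), , drop = FALSE]
      covered <- if (nrow(hh))
        sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(hh$qstart, hh$qend)))) else 0L
      present[i, j] <- covered / nchar(seqs[i]) >= min_coverage
    }
  }
  ifelse(apply(present, 1, all), "ancestral", "lineage_specific")
}

#' Export transferred regions as a link table
#'
#' One row per region: mitochondrial and chloroplast intervals and
#' identity, 1-based inclusive; suitable for circular-diagram tooling.
#'
#' @param summary `transfer_summary` (or its `regions` data.frame)
#' @param path output path
#' @export
export_links <- function(summary, path) {
  regs <- if (is(summary, "transfer_summary")) summary$regions else summary
  df <- regs[, c("mt_start", "mt_end", "cp_start", "cp_end", "identity")]
  df$identity <- sprintf("%.4f", df$identity)
  write_tsv(df, path, comments = "chloroplast-derived region links")
}
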