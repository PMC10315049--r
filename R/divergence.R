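#' Tabulate substitutions and indels from collinear blocks
#'
#' Walks the gapped base-level alignments of every anchor hit in the
#' chained blocks. Every mismatch column yields one substitution record
#' (position on the anchor/query genome, bases, transition/transversion
#' class, genomic context, and for CDS context the codon effect); every
#' gap run yields one indel with its length and context. Query positions
#' are visited at most once across overlapping anchors.
#'
#' @param blocks `collinear_blocks` built from hits with alignments kept
#' @param genome the anchor (query) `annotated_genome`; its `CDS` (and
#'   optional `intron`) features define context and reading frames
#' @return list: `substitutions` (data.frame: `pos`, `ref`, `alt`,
#'   `class`, `context`, `codon_effect`, `gene`), `indels` (data.frame:
#'   `pos`, `length`, `type`, `context`)
#' @export
tabulate_differences <- function(blocks, genome) {
  hits <- attr(blocks, "hits")
  members <- attr(blocks, "members")
  if (is.null(hits$qseq))
    stop("blocks were built from hits without alignments; ",
         "rerun local_search with keep_alignment = TRUE")
  feats <- if (is(genome, "annotated_genome")) genome$features else
    data.frame(type = character(), start = integer(), end = integer(),
               strand = character(), name = character())
  gseq <- as_seq(genome)
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (nrow(cds) && any((cds$end - cds$start + 1L) %% 3L != 0L))
    stop("annotation error: CDS length not divisible by 3 for ",
         paste(cds$name[(cds$end - cds$start + 1L) %% 3L != 0L],
               collapse = ", "))
  introns <- feats[feats$type == "intron", , drop = FALSE]
  ctx_of <- function(pos) {
    ci <- which(cds$start <= pos & cds$end >= pos)
    if (length(ci)) return(c("CDS", ci[1]))
    if (nrow(introns) && any(introns$start <= pos & introns$end >= pos))
      return(c("intron", NA))
    c("intergenic", NA)
  }
  codon_effect <- function(pos, alt, ci) {
    g <- cds[ci, ]
    if (g$strand == "-") {
      off <- g$end - pos
    } else off <- pos - g$start
    idx <- off %/% 3L
    within <- off %% 3L
    if (g$strand == "-") {
      cod_start <- g$end - (idx * 3L + 2L)
      codon <- revcomp(substr(gseq, cod_start, cod_start + 2L))
      mut <- codon
      substr(mut, within + 1L, within + 1L) <- unname(.comp[alt])
    } else {
      cod_start <- g$start + idx * 3L
      codon <- substr(gseq, cod_start, cod_start + 2L)
      mut <- codon
      substr(mut, within + 1L, within + 1L) <- alt
    }
    gc <- Biostrings::GENETIC_CODE
    if (is.na(gc[codon]) || is.na(gc[mut])) return("n/a")
    if (gc[[codon]] == gc[[mut]]) "synonymous" else "nonsynonymous"
  }
  is_transition <- function(a, b)
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))

  visited <- rep(FALSE, nchar(gseq))
  subs <- list(); indels <- list()
  for (bi in seq_len(nrow(blocks))) {
    for (hi in members[[bi]]) {
      h <- hits[hi, ]
      qc <- strsplit(h$qseq, "")[[1]]
      sc <- strsplit(h$sseq, "")[[1]]
      qpos <- h$qstart - 1L
      i <- 1L
      n <- length(qc)
      while (i <= n) {
        if (qc[i] != "-" && sc[i] != "-") {
          qpos <- qpos + 1L
          if (qc[i] != sc[i] && !visited[qpos] &&
              qc[i] %in% DNA_BASES && sc[i] %in% DNA_BASES) {
            visited[qpos] <- TRUE
            ctx <- ctx_of(qpos)
            eff <- if (ctx[1] == "CDS")
              codon_effect(qpos, sc[i], as.integer(ctx[2])) else "n/a"
            subs[[length(subs) + 1L]] <- data.frame(
              pos = qpos, ref = qc[i], alt = sc[i],
              class = if (is_transition(qc[i], sc[i])) "transition"
                      else "transversion",
              context = ctx[1], codon_effect = eff,
              gene = if (ctx[1] == "CDS") cds$name[as.integer(ctx[2])]
                     else NA_character_,
              stringsAsFactors = FALSE)
          } else if (!visited[qpos]) visited[qpos] <- TRUE
          i <- i + 1L
        } else {
          ## gap run: group consecutive gap columns of the same kind
          kind <- if (qc[i] == "-") "deletion" else "insertion"
          j <- i
          while (j <= n &&
                 ((kind == "deletion" && qc[j] == "-" && sc[j] != "-") ||
                  (kind == "insertion" && sc[j] == "-" && qc[j] != "-")))
            j <- j + 1L
          len <- j - i
          at <- qpos + 1L
          if (kind == "insertion") qpos <- qpos + len
          ctx <- ctx_of(min(at, nchar(gseq)))
          indels[[length(indels) + 1L]] <- data.frame(
            pos = at, length = len, type = kind, context = ctx[1],
            stringsAsFactors = FALSE)
          i <- j
        }
      }
    }
  }
  list(substitutions = if (length(subs)) do.call(rbind, subs) else
         data.frame(pos = integer(), ref = character(), alt = character(),
                    class = character(), context = character(),
                    codon_effect = character(), gene = character()),
       indels = if (length(indels)) do.call(rbind, indels) else
         data.frame(pos = integer(), length = integer(), type = character(),
                    context = character()))
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' observed transition and transversion proportions.
#'
#' @param P transition proportion
#' @param Q transversion proportion
#' @return corrected substitutions per site
#' @export
k2p_distance <- function(P, Q) {
  stopifnot(P >= 0, Q >= 0)
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0)
    stop("saturation error: Kimura two-parameter distance undefined for P=",
         P, ", Q=", Q)
  -0.5 * log(a) - 0.25 * log(b)
}

## weighted per-position synonymous site fraction of one codon
.codon_sites <- function(codon, w) {
  gc <- Biostrings::GENETIC_CODE
  if (is.na(gc[codon])) return(NA_real_)
  s <- 0
  for (j in 1:3) {
    cur <- substr(codon, j, j)
    tot <- 0; syn <- 0
    for (b in setdiff(DNA_BASES, cur)) {
      wt <- if (b == .transition_of[[cur]]) w else 1
      mut <- codon
      substr(mut, j, j) <- b
      tot <- tot + wt
      if (!is.na(gc[mut]) && gc[[mut]] != "*" && gc[[mut]] == gc[[codon]])
        syn <- syn + wt
    }
    s <- s + 3 * syn / tot   # scale so one position contributes <= 1 site
  }
  s / 3
}

## pathway-averaged differences between two codons: returns weighted
## counts c(syn_ts, syn_tv, nonsyn_ts, nonsyn_tv)
.codon_diffs <- function(c1, c2, w) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  out <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
  if (!length(pos)) return(out)
  paths <- if (length(pos) == 1) list(pos) else
    apply(.permutations(pos), 1, identity, simplify = FALSE)
  acc <- matrix(0, nrow = 0, ncol = 4)
  wts <- numeric()
  use <- function(skip_stops) {
    for (p in paths) {
      cur <- c1
      counts <- c(0, 0, 0, 0)
      wt <- 1
      ok <- TRUE
      for (j in p) {
        nxt <- cur
        substr(nxt, j, j) <- substr(c2, j, j)
        if (skip_stops && gc[[nxt]] == "*") { ok <- FALSE; break }
        ts <- substr(nxt, j, j) == .transition_of[[substr(cur, j, j)]]
        syn <- gc[[nxt]] != "*" && gc[[cur]] != "*" && gc[[nxt]] == gc[[cur]]
        k <- (if (syn) 0 else 2) + (if (ts) 1 else 2)
        counts[k] <- counts[k] + 1
        wt <- wt * if (ts) w else 1
        cur <- nxt
      }
      if (ok) { acc <<- rbind(acc, counts); wts <<- c(wts, wt) }
    }
  }
  use(TRUE)
  if (!nrow(acc)) use(FALSE)
  avg <- colSums(acc * wts / sum(wts))
  names(avg) <- names(out)
  avg
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

#' Synonymous and nonsynonymous distances for an aligned CDS pair
#'
#' Modified Nei-Gojobori counting: synonymous/nonsynonymous sites are
#' counted with a transition/transversion weighting (`ts_weight`, the
#' weight of the single transition against 1 for each transversion) and
#' differences are averaged over all shortest substitution pathways
#' (pathways through stop codons are excluded when any stop-free pathway
#' exists; changes to stop codons count as nonsynonymous). Each class is
#' then corrected with the Kimura two-parameter formula using its own
#' transition and transversion proportions.
#'
#' @param seq1,seq2 aligned, gap-stripped coding sequences (equal length,
#'   multiple of 3, no internal stops)
#' @param ts_weight transition weighting (default 1)
#' @return list: `Ks`, `Ka`, `S_sites`, `N_sites`, `S_diffs`, `N_diffs`,
#'   `n_codons`
#' @export
ks_ka <- function(seq1, seq2, ts_weight = 1) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned (equal length)")
  if (nchar(s1) %% 3 != 0) stop("aligned length must be a multiple of 3")
  n_cod <- nchar(s1) / 3
  gc <- Biostrings::GENETIC_CODE
  S1 <- 0; S2 <- 0
  D <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
  used <- 0L
  for (i in seq_len(n_cod)) {
    c1 <- substr(s1, 3 * i - 2, 3 * i)
    c2 <- substr(s2, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") {
      if (i == n_cod) next    # terminal stop codon: ignored
      stop("internal stop codon in input at codon ", i)
    }
    used <- used + 1L
    S1 <- S1 + .codon_sites(c1, ts_weight)
    S2 <- S2 + .codon_sites(c2, ts_weight)
    D <- D + .codon_diffs(c1, c2, ts_weight)
  }
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  if (S <= 0) stop("undefined Ks: zero synonymous sites")
  Ks <- k2p_distance(D["syn_ts"] / S, D["syn_tv"] / S)
  Ka <- k2p_distance(D["nonsyn_ts"] / N, D["nonsyn_tv"] / N)
  list(Ks = unname(Ks), Ka = unname(Ka), S_sites = S, N_sites = N,
       S_diffs = unname(D["syn_ts"] + D["syn_tv"]),
       N_diffs = unname(D["nonsyn_ts"] + D["nonsyn_tv"]), n_codons = used)
}

#' Polarise substitutions on the tree ((1,2),outgroup)
#'
#' For each aligned column where the two ingroup sequences differ, the
#' substitution is assigned to the ingroup lineage whose base differs
#' from the state shared by the outgroup and the other ingroup; columns
#' with three states, ambiguity or an outgroup gap are unpolarised.
#'
#' @param aln 3-row aligned input: character matrix, `DNAStringSet` of
#'   three equal-width sequences, or character vector of three strings.
#'   Rows are ingroup 1, ingroup 2, outgroup.
#' @return list of class `polarized_subs`: `records` (column, bases,
#'   lineage), `counts` (`lineage1`, `lineage2`, `unpolarized`, `total`)
#' @export
polarize <- function(aln) {
  if (is(aln, "DNAStringSet")) aln <- as.character(aln)
  if (is.character(aln)) {
    stopifnot(length(aln) == 3, length(unique(nchar(aln))) == 1)
    m <- do.call(rbind, strsplit(toupper(aln), ""))
  } else m <- toupper(aln)
  stopifnot(nrow(m) == 3)
  diffs <- which(m[1, ] != m[2, ])
  recs <- list()
  for (j in diffs) {
    b1 <- m[1, j]; b2 <- m[2, j]; bo <- m[3, j]
    lineage <-
      if (!all(c(b1, b2, bo) %in% DNA_BASES)) "unpolarized"
      else if (b2 == bo) "lineage1"
      else if (b1 == bo) "lineage2"
      else "unpolarized"
    recs[[length(recs) + 1L]] <- data.frame(
      column = j, base1 = b1, base2 = b2, outgroup = bo, lineage = lineage,
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(column = integer(), base1 = character(),
               base2 = character(), outgroup = character(),
               lineage = character())
  counts <- c(lineage1 = sum(records$lineage == "lineage1"),
              lineage2 = sum(records$lineage == "lineage2"),
              unpolarized = sum(records$lineage == "unpolarized"),
              total = nrow(records))
  structure(list(records = records, counts = counts),
            class = "polarized_subs")
}

#' @export
print.polarized_subs <- function(x, ...) {
  cat(sprintf(paste0("<polarized_subs> %d substitutions: %d in lineage 1, ",
                     "%d in lineage 2, %d unpolarised\n"),
              x$counts["total"], x$counts["lineage1"], x$counts["lineage2"],
              x$counts["unpolarized"]))
  invisible(x)
}

#' Calibrated molecular-clock arithmetic
#'
#' The substitution rate is the calibration distance divided by the
#' calibration time, and the estimated divergence time is the query
#' distance divided by that rate (pairwise distance over pairwise time;
#' no factor two). `per_lineage = TRUE` halves the rate, reporting it per
#' lineage rather than per pair; the estimated time is unchanged.
#'
#' @param query_distance substitutions/site for the pair to be dated
#' @param calibration_distance substitutions/site of the calibration pair
#' @param calibration_time age of the calibration split (years)
#' @param per_lineage report the rate per lineage (distance / 2T)
#' @return list: `rate` (per site per year), `time` (years)
#' @export
clock <- function(query_distance, calibration_distance, calibration_time,
                  per_lineage = FALSE) {
  stopifnot(query_distance > 0, calibration_distance > 0,
            calibration_time > 0)
  rate <- calibration_distance / calibration_time / (1 + per_lineage)
  list(rate = rate,
       time = query_distance * calibration_time / calibration_distance)
}

#' Substitution rate from a distance and a known divergence time
#'
#' @param distance substitutions/site
#' @param time divergence time (years)
#' @param per_lineage divide by 2T instead of T
#' @return rate per site per year
#' @export
clock_rate <- function(distance, time, per_lineage = FALSE) {
  stopifnot(distance > 0, time > 0)
  distance / time / (1 + per_lineage)
}
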