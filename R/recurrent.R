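#' Build a region alignment set for chimera scanning
#'
#' Holds the aligned sequences of one transferred region: the
#' mitochondrial copies from several species, at least one corresponding
#' chloroplast sequence, and the query individual's copy. Diagnostic
#' columns are those where the chloroplast state differs from the
#' mitochondrial consensus (majority over the non-query mitochondrial
#' sequences); columns containing gaps are excluded from diagnostics and
#' reported separately.
#'
#' @param query the query individual's sequence (string or `DNAString`)
#' @param mts aligned mitochondrial region copies (`DNAStringSet`, named
#'   character vector, or list), excluding the query
#' @param cps corresponding chloroplast sequence(s), aligned to the same
#'   columns
#' @param region_offset optional genome coordinate of column 1, used to
#'   project the boundary onto the genome
#' @return object of class `region_alignment_set`
#' @export
region_alignment_set <- function(query, mts, cps, region_offset = NA) {
  to_chr <- function(x) {
    if (is(x, "DNAStringSet") || is(x, "DNAString")) x <- as.character(x)
    toupper(unlist(x))
  }
  query <- to_chr(query); mts <- to_chr(mts); cps <- to_chr(cps)
  if (is.null(names(mts))) names(mts) <- paste0("mt", seq_along(mts))
  if (is.null(names(cps))) names(cps) <- paste0("cp", seq_along(cps))
  widths <- nchar(c(query, mts, cps))
  if (length(unique(widths)) != 1)
    stop("all sequences must be aligned to the same number of columns")
  nc <- widths[1]
  M <- do.call(rbind, strsplit(mts, ""))
  Cp <- do.call(rbind, strsplit(cps, ""))
  qv <- strsplit(query, "")[[1]]
  consensus <- apply(M, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    nm <- names(tb[tb == tb[1]])
    sort(nm)[1]
  })
  cp_state <- apply(Cp, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    sort(names(tb[tb == tb[1]]))[1]
  })
  has_gap <- qv == "-" | apply(M == "-", 2, any) | apply(Cp == "-", 2, any)
  diagnostic <- which(!has_gap & !is.na(consensus) & !is.na(cp_state) &
                        consensus != cp_state)
  structure(list(query = qv, mts = M, cps = Cp, consensus = consensus,
                 cp_state = cp_state, diagnostic = diagnostic,
                 indel_columns = which(has_gap), n_col = nc,
                 region_offset = region_offset,
                 names = list(query = "query", mts = names(mts),
                              cps = names(cps))),
            class = "region_alignment_set")
}

#' @export
print.region_alignment_set <- function(x, ...) {
  cat(sprintf(paste0("<region_alignment_set> %d columns, %d mt + %d cp ",
                     "sequences, %d diagnostic sites, %d indel columns\n"),
              x$n_col, nrow(x$mts), nrow(x$cps), length(x$diagnostic),
              length(x$indel_columns)))
  invisible(x)
}

#' Scan for a chimeric breakpoint in a transferred region
#'
#' Evaluates every inter-column boundary and both orientations: the score
#' of a boundary is the number of diagnostic sites on the
#' chloroplast-like side where the query matches the chloroplast state,
#' plus the number on the mitochondrial side where it matches the
#' mitochondrial consensus. Returns the maximising boundary (leftmost on
#' ties); when no two-segment split beats the best single-segment
#' explanation (all-chloroplast or all-mitochondrial), a no-chimera
#' verdict is returned.
#'
#' @param set a [region_alignment_set()]
#' @return object of class `breakpoint_call`: `verdict` (`"chimera"`,
#'   `"all_mt"`, `"all_cp"`), `boundary` (column; NA for no-chimera),
#'   `genome_coordinate`, `orientation` (`"cp_left"`/`"cp_right"`),
#'   `support_left`, `support_right`, `score`, `segment_lengths`,
#'   `one_segment_score`
#' @export
scan_breakpoint <- function(set) {
  stopifnot(is(set, "region_alignment_set"))
  d <- set$diagnostic
  if (!length(d))
    stop("insufficient signal: zero diagnostic columns")
  nc <- set$n_col
  cp_col <- mt_col <- numeric(nc)
  cp_col[d] <- as.numeric(set$query[d] == set$cp_state[d])
  mt_col[d] <- as.numeric(set$query[d] == set$consensus[d])
  cum_cp <- c(0, cumsum(cp_col))   # cum_*[b+1] = sites in columns 1..b
  cum_mt <- c(0, cumsum(mt_col))
  tot_cp <- cum_cp[nc + 1]; tot_mt <- cum_mt[nc + 1]
  b <- 0:nc
  s_cpleft <- cum_cp[b + 1] + (tot_mt - cum_mt[b + 1])
  s_cpright <- cum_mt[b + 1] + (tot_cp - cum_cp[b + 1])
  one_seg <- max(tot_cp, tot_mt)
  best2 <- max(s_cpleft[-c(1, nc + 1)], s_cpright[-c(1, nc + 1)])
  if (best2 <= one_seg) {
    verdict <- if (tot_mt >= tot_cp) "all_mt" else "all_cp"
    return(structure(list(verdict = verdict, boundary = NA_integer_,
                          genome_coordinate = NA, orientation = NA,
                          support_left = NA, support_right = NA,
                          score = one_seg, one_segment_score = one_seg,
                          segment_lengths = c(NA, NA),
                          n_diagnostic = length(d)),
                     class = "breakpoint_call"))
  }
  ## leftmost best boundary; cp_left preferred on orientation ties
  cand <- rbind(data.frame(b = b, s = s_cpleft, orient = "cp_left"),
                data.frame(b = b, s = s_cpright, orient = "cp_right"))
  cand <- cand[cand$b > 0 & cand$b < nc, ]
  cand <- cand[order(-cand$s, cand$b, cand$orient), ]
  top <- cand[1, ]
  bnd <- top$b
  if (top$orient == "cp_left") {
    sl <- cum_cp[bnd + 1]; sr <- tot_mt - cum_mt[bnd + 1]
  } else {
    sl <- cum_mt[bnd + 1]; sr <- tot_cp - cum_cp[bnd + 1]
  }
  nongap_q <- set$query != "-"
  structure(list(verdict = "chimera", boundary = bnd,
                 genome_coordinate = if (is.na(set$region_offset)) NA else
                   set$region_offset + bnd - 1L,
                 orientation = top$orient, support_left = sl,
                 support_right = sr, score = top$s,
                 one_segment_score = one_seg,
                 segment_lengths = c(sum(nongap_q[seq_len(bnd)]),
                                     sum(nongap_q[(bnd + 1):nc])),
                 n_diagnostic = length(d)),
            class = "breakpoint_call")
}

#' @export
print.breakpoint_call <- function(x, ...) {
  if (x$verdict == "chimera") {
    cat(sprintf(paste0("<breakpoint_call> chimera at column %d (%s): ",
                       "support %d + %d of %d diagnostic sites; segments ",
                       "%d / %d bp\n"),
                x$boundary, x$orientation, x$support_left, x$support_right,
                x$n_diagnostic, x$segment_lengths[1], x$segment_lengths[2]))
  } else {
    cat(sprintf("<breakpoint_call> no chimera (%s; score %d of %d)\n",
                x$verdict, x$score, x$n_diagnostic))
  }
  invisible(x)
}

#' Neighbor-joining trees for the two partitions of a chimeric region
#'
#' Splits the alignment at the called boundary and builds a
#' neighbor-joining tree on Kimura two-parameter distances for each
#' partition, with nonparametric bootstrap. Reports whether the query
#' clusters with the chloroplast sequences in each partition.
#'
#' @param set a [region_alignment_set()]
#' @param call a `breakpoint_call` with a chimera verdict
#' @param bootstrap bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return list of class `partition_trees`: per partition the `phylo`
#'   tree, its newick string, bootstrap support of the query+chloroplast
#'   grouping (NA when not monophyletic), and `query_with_cp` logicals
#' @export
partition_trees <- function(set, call, bootstrap = 1000, seed = 1) {
  stopifnot(is(set, "region_alignment_set"), is(call, "breakpoint_call"))
  if (call$verdict != "chimera")
    stop("partition_trees requires a chimera breakpoint call")
  b <- call$boundary
  if (b < 50 || set$n_col - b < 50)
    stop("partition too short: need at least 50 columns on each side")
  mat <- rbind(query = set$query, set$mts, set$cps)
  rownames(mat) <- c("query", set$names$mts, set$names$cps)
  if (nrow(mat) < 4) stop("need at least 4 sequences per partition")
  one <- function(cols) {
    m <- mat[, cols, drop = FALSE]
    bin <- ape::as.DNAbin(apply(m, c(1, 2), tolower))
    phy <- ape::nj(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
    set.seed(seed)
    bp <- ape::boot.phylo(phy, bin, function(x)
      ape::nj(ape::dist.dna(x, model = "K80", pairwise.deletion = TRUE)),
      B = bootstrap, quiet = TRUE)
    clade <- c("query", set$names$cps)
    mono <- ape::is.monophyletic(phy, clade)
    supp <- NA_real_
    if (mono && length(clade) < nrow(mat) - 1) {
      node <- ape::getMRCA(phy, clade)
      if (!is.null(node) && node > ape::Ntip(phy))
        supp <- 100 * bp[node - ape::Ntip(phy)] / bootstrap
    }
    list(tree = phy, newick = ape::write.tree(phy), query_with_cp = mono,
         support = supp)
  }
  left <- one(seq_len(b))
  right <- one((b + 1):set$n_col)
  structure(list(left = left, right = right, boundary = b,
                 orientation = call$orientation, bootstrap = bootstrap),
            class = "partition_trees")
}

#' @export
print.partition_trees <- function(x, ...) {
  cat(sprintf(paste0("<partition_trees> boundary %d (%s); query with cp: ",
                     "left=%s (support %s), right=%s (support %s)\n"),
              x$boundary, x$orientation,
              x$left$query_with_cp,
              ifelse(is.na(x$left$support), ".",
                     sprintf("%.0f%%", x$left$support)),
              x$right$query_with_cp,
              ifelse(is.na(x$right$support), ".",
                     sprintf("%.0f%%", x$right$support))))
  invisible(x)
}

#' Survey recurrent-transfer carriers across populations
#'
#' Scans each individual's region copy with [scan_breakpoint()] against
#' the species panel; an individual is a carrier when it receives a
#' chimera verdict whose boundary lies within `tolerance` diagnostic
#' sites of the template boundary. Reports per-population carrier counts
#' and fixation flags.
#'
#' @param individuals_by_pop named list (one element per population) of
#'   aligned individual sequences (`DNAStringSet`, character vector or
#'   list)
#' @param mts,cps species panel, as for [region_alignment_set()]
#' @param template_boundary the template breakpoint column (e.g. from the
#'   discovery individual's `breakpoint_call`)
#' @param tolerance carrier window, in diagnostic sites around the
#'   template boundary
#' @return data.frame of class `fixation_survey`: `population`, `n`,
#'   `carriers`, `non_carriers`, `fixed`; attribute `species_fixed`
#' @export
fixation_survey <- function(individuals_by_pop, mts, cps,
                            template_boundary, tolerance = 5) {
  stopifnot(length(individuals_by_pop) >= 1,
            !is.null(names(individuals_by_pop)))
  rows <- list()
  for (pop in names(individuals_by_pop)) {
    inds <- individuals_by_pop[[pop]]
    if (is(inds, "DNAStringSet")) inds <- as.character(inds)
    if (length(inds) < 1) stop("population ", pop, " has no individuals")
    carrier <- vapply(inds, function(s) {
      set <- region_alignment_set(s, mts, cps)
      call <- tryCatch(scan_breakpoint(set), error = function(e) NULL)
      if (is.null(call) || call$verdict != "chimera") return(FALSE)
      ## distance in diagnostic sites between called and template boundary
      dwin <- sum(set$diagnostic > min(call$boundary, template_boundary) &
                    set$diagnostic <= max(call$boundary, template_boundary))
      dwin <= tolerance
    }, NA)
    rows[[pop]] <- data.frame(population = pop, n = length(inds),
                              carriers = sum(carrier),
                              non_carriers = sum(!carrier),
                              fixed = all(carrier),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "species_fixed") <- all(out$fixed)
  attr(out, "present") <- any(out$carriers > 0)
  class(out) <- c("fixation_survey", "data.frame")
  out
}

#' @export
print.fixation_survey <- function(x, ...) {
  cat("<fixation_survey>\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("species-wide fixed: %s; event present: %s\n",
              attr(x, "species_fixed"), attr(x, "present")))
  invisible(x)
}
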