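#' Assemble a reference panel for origin classification
#'
#' @param mts named list of the three mitogenomes (`annotated_genome`s)
#' @param cp own chloroplast genome, or NULL to disable the CP arm
#' @param nuclear own nuclear genome, or NULL to disable the NU arm
#' @param external `DNAStringSet` of external mitochondrial sequences, or
#'   NULL to disable the PH arm
#' @param external_meta data.frame with `id`, `taxon`, `relatedness`
#'   (`"close"`/`"distant"`) matching `external`
#' @return object of class `reference_panel`
#' @export
reference_panel <- function(mts, cp = NULL, nuclear = NULL,
                            external = NULL, external_meta = NULL) {
  stopifnot(length(mts) >= 3, !is.null(names(mts)))
  if (!is.null(external)) {
    stopifnot(!is.null(external_meta),
              all(c("id", "taxon", "relatedness") %in% names(external_meta)),
              !anyDuplicated(external_meta$taxon),
              all(external_meta$relatedness %in% c("close", "distant")))
  }
  structure(list(mts = mts, cp = cp, nuclear = nuclear,
                 external = external, external_meta = external_meta),
            class = "reference_panel")
}

## per-base maximum hit coverage count and best score over a region of
## length L, from an alignment_hits table (query = the region)
.base_cover <- function(hits, L, count = TRUE) {
  cnt <- integer(L); sc <- numeric(L)
  for (i in seq_len(nrow(hits))) {
    idx <- hits$qstart[i]:hits$qend[i]
    cnt[idx] <- cnt[idx] + 1L
    sc[idx] <- pmax(sc[idx], hits$score[i])
  }
  list(count = cnt, score = sc)
}

## contiguous runs of a logical vector as a data.frame of intervals
.runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Classify the origin of a non-alignable region
#'
#' Attributes every base of a non-alignable region to one of six origins
#' by a fixed-precedence decision cascade: (CP) hits to the own
#' chloroplast genome; (ID) more qualifying copies in the own mitogenome
#' than in the pair partner's; (GL) absent in the partner but present in
#' the third mitogenome (gain/loss); (PH) best external-collection hit to
#' a distant-taxon mitochondrial sequence outscoring close-taxon hits by
#' `ph_margin`; (NU) hits to the own nuclear genome; (ND) the residue.
#' Category bp sum to the region length exactly.
#'
#' @param region one-row data.frame from [nonalignable_regions()] (`code`,
#'   `genome`, `start`, `end`)
#' @param panel a [reference_panel()]; the region's genome and the pair
#'   partner must be among `panel$mts`
#' @param pair character vector of the two compared genome ids (the
#'   region's genome first or second, either way)
#' @param min_identity,min_len hit thresholds
#' @param ph_margin distant-over-close score margin to call PH
#' @return object of class `origin_call`: `code`, `genome`, `pair`,
#'   `length`, `bp` (named CP/ID/GL/PH/NU/ND, summing to length), `pct`,
#'   `evidence` (attributed sub-intervals with best hit support)
#' @export
classify_region <- function(region, panel, pair, min_identity = 0.85,
                            min_len = 90, ph_margin = 1.1) {
  stopifnot(is(panel, "reference_panel"), region$genome %in% pair,
            all(pair %in% names(panel$mts)))
  g <- panel$mts[[region$genome]]
  L <- region$end - region$start + 1L
  if (region$start < 1 || region$end > nchar(as_seq(g)))
    stop("region ", region$code, " not extractable: coordinates outside ",
         region$genome)
  seqs <- setNames(substr(as_seq(g), region$start, region$end), "region")
  other <- setdiff(pair, region$genome)
  third <- setdiff(names(panel$mts), pair)[1]
  search <- function(subject, circular = FALSE) {
    local_search(seqs, as_seq(subject), min_identity = min_identity,
                 min_hit_len = min_len, circular_subject = circular,
                 keep_alignment = FALSE)
  }
  cat_vec <- rep("ND", L)
  evidence <- data.frame(category = character(), start = integer(),
                         end = integer(), target = character(),
                         identity = numeric(), length = integer(),
                         stringsAsFactors = FALSE)
  note <- character()
  add_ev <- function(mask, category, hits, target) {
    runs <- .runs_of(mask)
    if (!nrow(runs)) return()
    best <- if (nrow(hits)) hits[which.max(hits$score), ] else NULL
    evidence <<- rbind(evidence, data.frame(
      category = category,
      start = region$start + runs$start - 1L,
      end = region$start + runs$end - 1L,
      target = target,
      identity = if (is.null(best)) NA_real_ else best$identity,
      length = if (is.null(best)) NA_integer_ else best$length,
      stringsAsFactors = FALSE))
  }

  ## (1) chloroplast-derived
  if (!is.null(panel$cp)) {
    h_cp <- search(panel$cp)
    cp_mask <- .base_cover(h_cp, L)$count > 0 & cat_vec == "ND"
    cat_vec[cp_mask] <- "CP"
    add_ev(cp_mask, "CP", h_cp, "cp")
  }

  ## copy counts across the three mitogenomes
  h_own <- search(g, circular = TRUE)
  n_own <- .base_cover(h_own, L)$count
  h_other <- search(panel$mts[[other]], circular = TRUE)
  n_other <- .base_cover(h_other, L)$count
  h_third <- search(panel$mts[[third]], circular = TRUE)
  n_third <- .base_cover(h_third, L)$count

  ## (2) intragenomic duplication: more copies here than in the partner
  id_mask <- cat_vec == "ND" & n_own >= 2L & n_own > n_other
  cat_vec[id_mask] <- "ID"
  add_ev(id_mask, "ID", h_own, region$genome)

  ## (3) gain/loss: absent in the partner, present in the third species
  gl_mask <- cat_vec == "ND" & n_other == 0L & n_third >= 1L
  cat_vec[gl_mask] <- "GL"
  add_ev(gl_mask, "GL", h_third, third)

  ## (4) external mitochondrial collection and own nuclear genome
  sc_close <- numeric(L); sc_dist <- numeric(L)
  best_dist_taxon <- NA_character_
  if (!is.null(panel$external)) {
    best_dist_score <- -Inf
    for (i in seq_along(panel$external)) {
      m <- panel$external_meta[i, ]
      h <- search(as.character(panel$external[[i]]))
      sc <- .base_cover(h, L)$score
      if (m$relatedness == "distant") {
        sc_dist <- pmax(sc_dist, sc)
        if (nrow(h) && max(h$score) > best_dist_score) {
          best_dist_score <- max(h$score)
          best_dist_taxon <- m$taxon
        }
      } else sc_close <- pmax(sc_close, sc)
    }
  }
  nu_cover <- if (!is.null(panel$nuclear))
    .base_cover(search(panel$nuclear), L)$count else integer(L)

  ph_mask <- cat_vec == "ND" & sc_dist > 0 & sc_dist > ph_margin * sc_close
  cat_vec[ph_mask] <- "PH"
  if (any(ph_mask))
    evidence <- rbind(evidence, {
      runs <- .runs_of(ph_mask)
      data.frame(category = "PH", start = region$start + runs$start - 1L,
                 end = region$start + runs$end - 1L,
                 target = best_dist_taxon, identity = NA_real_,
                 length = NA_integer_, stringsAsFactors = FALSE)
    })
  nu_mask <- cat_vec == "ND" & nu_cover > 0
  cat_vec[nu_mask] <- "NU"
  if (any(nu_mask)) {
    note <- c(note, "NU bases also hit mitochondrial sequence: probable mt-to-nuclear transfer direction")
    runs <- .runs_of(nu_mask)
    evidence <- rbind(evidence, data.frame(
      category = "NU", start = region$start + runs$start - 1L,
      end = region$start + runs$end - 1L, target = "nuclear",
      identity = NA_real_, length = NA_integer_, stringsAsFactors = FALSE))
  }

  cats <- c("CP", "ID", "GL", "PH", "NU", "ND")
  bp <- vapply(cats, function(k) sum(cat_vec == k), 0L)
  stopifnot(sum(bp) == L)   # exact conservation, asserted on every call
  structure(list(code = region$code, genome = region$genome,
                 pair = paste(sort(pair), collapse = "-"), length = L,
                 bp = bp, pct = 100 * bp / L, evidence = evidence,
                 note = note), class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> %s (%s, pair %s): %d bp\n", x$code, x$genome,
              x$pair, x$length))
  nz <- x$bp[x$bp > 0]
  cat(paste(sprintf("  %s %d bp (%.2f%%)", names(nz), nz,
                    100 * nz / x$length), collapse = "\n"), "\n")
  invisible(x)
}

#' Classify every region of a pairwise comparison
#'
#' @param regions data.frame of regions for one genome (one side of a
#'   pair), as returned by [nonalignable_regions()]
#' @param panel a [reference_panel()]
#' @param pair the two compared genome ids
#' @param ... passed to [classify_region()]
#' @return list of `origin_call`s
#' @export
classify_regions <- function(regions, panel, pair, ...) {
  lapply(seq_len(nrow(regions)), function(i)
    classify_region(regions[i, ], panel, pair, ...))
}

#' Summarise origin calls for one species pair
#'
#' Per-genome totals in the style of a published origin-accounting table:
#' region count, per-category bp and percentage of the genome's total
#' non-alignable bp, formatted as `"N bp (P.PP%)"`.
#'
#' @param calls list of `origin_call`s from one genome pair (both sides
#'   may be mixed; they are grouped by genome)
#' @return list of class `pair_summary`: `long` (genome, category, bp,
#'   pct), `table` (formatted wide table), `pair`
#' @export
summarize_pair <- function(calls) {
  pairs <- unique(vapply(calls, `[[`, "", "pair"))
  if (length(pairs) != 1)
    stop("origin calls from mixed pairs: ", paste(pairs, collapse = ", "))
  cats <- c("CP", "ID", "GL", "PH", "NU", "ND")
  genomes <- unique(vapply(calls, `[[`, "", "genome"))
  long <- NULL; wide <- NULL
  for (g in genomes) {
    sub <- calls[vapply(calls, `[[`, "", "genome") == g]
    bp <- Reduce(`+`, lapply(sub, `[[`, "bp"))
    tot <- sum(bp)
    long <- rbind(long, data.frame(genome = g, category = cats,
                                   bp = as.integer(bp),
                                   pct = 100 * as.numeric(bp) / tot))
    fmt <- sprintf("%d bp (%.2f%%)", bp, 100 * bp / tot)
    fmt[bp == 0] <- "0"
    wide <- rbind(wide, data.frame(
      genome = g, n_regions = length(sub),
      rbind(setNames(fmt, cats)),
      total = sprintf("%d bp (100%%)", tot),
      stringsAsFactors = FALSE))
  }
  structure(list(long = long, table = wide, pair = pairs),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("<pair_summary> pair", x$pair, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Polarise presence/absence of a region on the tree ((C,S),D)
#'
#' Exhaustive minimal-event (two-state parsimony) assignment of a
#' presence/absence pattern over all internal-state configurations of the
#' fixed rooted topology; ties between optimal reconstructions give
#' `"ambiguous"`.
#'
#' @param presence named logical of length 3 (`C`, `S`, `D`)
#' @return list: `call` (`"gain_in"`, `"loss_in"`, `"ambiguous"`,
#'   `"none"`), `where` (branch: `"C"`, `"S"`, `"D"` or `"CS"`),
#'   `events` (minimal event count), `n_optimal`
#' @export
parsimony_polarity <- function(presence) {
  stopifnot(all(c("C", "S", "D") %in% names(presence)))
  p <- as.integer(presence[c("C", "S", "D")])
  best <- Inf; opts <- list()
  for (root in 0:1) for (cs in 0:1) {
    changes <- list()
    if (root != cs) changes <- c(changes, list(c("CS", root, cs)))
    if (cs != p[1]) changes <- c(changes, list(c("C", cs, p[1])))
    if (cs != p[2]) changes <- c(changes, list(c("S", cs, p[2])))
    if (root != p[3]) changes <- c(changes, list(c("D", root, p[3])))
    n <- length(changes)
    if (n < best) { best <- n; opts <- list(changes) }
    else if (n == best) opts <- c(opts, list(changes))
  }
  if (best == 0)
    return(list(call = "none", where = NA_character_, events = 0L,
                n_optimal = length(opts)))
  descr <- unique(vapply(opts, function(ch) {
    if (length(ch) != 1) return("multi")
    c1 <- ch[[1]]
    paste0(if (c1[3] == "1") "gain_in" else "loss_in", ":", c1[1])
  }, ""))
  if (length(descr) == 1 && descr != "multi") {
    parts <- strsplit(descr, ":")[[1]]
    return(list(call = parts[1], where = parts[2], events = best,
                n_optimal = length(opts)))
  }
  list(call = "ambiguous", where = NA_character_, events = best,
       n_optimal = length(opts))
}
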