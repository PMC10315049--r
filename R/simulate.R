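## ---- internal simulator machinery ------------------------------------
## A lineage state is a mutable-by-copy list:
##   seq      character vector of single bases
##   features data.frame(type,start,end,strand,name)           (genes)
##   events   data.frame(event_id,kind,start,end,strand,branch,
##                       donor,donor_start,donor_end,deleted,inserted_seq)
##   subs     data.frame(sub_id,pos,from,to,branch)
## All planted intervals are tracked through every later edit, so ledger
## coordinates always refer to the final emitted sequence.

.empty_events <- function() {
  data.frame(event_id = character(), kind = character(), start = integer(),
             end = integer(), strand = character(), branch = character(),
             donor = character(), donor_start = integer(),
             donor_end = integer(), deleted = logical(),
             inserted_seq = character(), stringsAsFactors = FALSE)
}

.empty_subs <- function() {
  data.frame(sub_id = integer(), pos = integer(), from = character(),
             to = character(), branch = character(), stringsAsFactors = FALSE)
}

.state_len <- function(state) length(state$seq)

## intervals that later edits must not split: live events + genes
.tracked <- function(state, with_cds = TRUE) {
  ev <- state$events[!state$events$deleted, c("start", "end"), drop = FALSE]
  if (with_cds && nrow(state$features))
    ev <- rbind(ev, state$features[, c("start", "end"), drop = FALSE])
  ev
}

## sample an interval of width `len` wholly inside the complement of the
## avoid set (exact placement: no rejection loop can fail spuriously)
.sample_interval <- function(state, len, extra_avoid = NULL, what = "event") {
  L <- .state_len(state)
  avoid <- .tracked(state)
  if (!is.null(extra_avoid)) avoid <- rbind(avoid, extra_avoid)
  free <- if (nrow(avoid)) interval_complement(as_iranges(avoid), L)
          else data.frame(start = 1L, end = L)
  free <- free[free$end - free$start + 1L >= len + 2L, , drop = FALSE]
  if (!nrow(free))
    stop("cannot place ", what, " of ", len,
         " bp without overlapping existing intervals")
  w <- free$end - free$start - len
  run <- free[sample.int(nrow(free), 1L, prob = w / sum(w)), ]
  start <- run$start + sample.int(run$end - run$start + 1L - len - 1L, 1L)
  c(start, start + len - 1L)
}

## a point at which an insertion will not split any tracked interval
.sample_point <- function(state, extra_avoid = NULL) {
  L <- .state_len(state)
  avoid <- .tracked(state)
  if (!is.null(extra_avoid)) avoid <- rbind(avoid, extra_avoid)
  if (nrow(avoid)) {
    blocked <- IRanges::reduce(IRanges::IRanges(avoid$start + 1L, avoid$end))
    free <- interval_complement(blocked, L)
  } else free <- data.frame(start = 1L, end = L)
  free <- free[free$start >= 2L | free$end >= 2L, , drop = FALSE]
  free$start <- pmax(free$start, 2L)
  free <- free[free$end >= free$start, , drop = FALSE]
  w <- free$end - free$start + 1L
  run <- free[sample.int(nrow(free), 1L, prob = w / sum(w)), ]
  run$start + sample.int(run$end - run$start + 1L, 1L) - 1L
}

## an interval of roughly `len` bp whose boundaries split no tracked
## interval; tracked intervals wholly inside are allowed (inversion use)
.sample_spanning_interval <- function(state, len, tol = 0.2,
                                      what = "inversion") {
  L <- .state_len(state)
  free <- rep(TRUE, L)
  tr <- .tracked(state)
  for (i in seq_len(nrow(tr))) free[tr$start[i]:tr$end[i]] <- FALSE
  pts <- which(free)
  ## the rotation locus must stay outside: rotating the emitted genome at
  ## a point inside the inversion would split the ledger interval
  marker <- state$events$start[state$events$kind == "origin_marker"]
  starts <- pts[pts <= L - ceiling((1 - tol) * len)]
  if (!length(starts))
    stop("cannot place ", what, " of ~", len, " bp")
  for (a in sample(starts, min(100L, length(starts)))) {
    target <- a + len - 1L
    cand <- pts[pts >= a + floor((1 - tol) * len) &
                  pts <= min(L, a + ceiling((1 + tol) * len))]
    for (b in cand[order(abs(cand - target))]) {
      if (length(marker) && any(marker >= a & marker <= b)) next
      return(c(a, b))
    }
  }
  stop("cannot place ", what, " of ~", len, " bp after bounded attempts")
}

.remap_all <- function(state, fn) {
  for (tab in c("features", "events")) {
    df <- state[[tab]]
    if (nrow(df)) {
      m <- fn(df$start, df$end, df$strand)
      df$start <- m$start; df$end <- m$end
      if (!is.null(m$strand)) df$strand <- m$strand
      state[[tab]] <- df
    }
  }
  if (nrow(state$subs)) {
    m <- fn(state$subs$pos, state$subs$pos, NULL)
    state$subs$pos <- m$start
    if (!is.null(m$flip) && any(m$flip)) {
      state$subs$from[m$flip] <- unname(.comp[state$subs$from[m$flip]])
      state$subs$to[m$flip] <- unname(.comp[state$subs$to[m$flip]])
    }
  }
  state
}

## insert `bases` so that they occupy positions at..at+k-1
.apply_insertion <- function(state, at, bases) {
  k <- length(bases)
  state$seq <- append(state$seq, bases, after = at - 1L)
  .remap_all(state, function(s, e, str) {
    list(start = ifelse(s >= at, s + k, s), end = ifelse(e >= at, e + k, e),
         strand = str)
  })
}

.apply_deletion <- function(state, a, b) {
  k <- b - a + 1L
  state$seq <- state$seq[-(a:b)]
  .remap_all(state, function(s, e, str) {
    list(start = ifelse(s > b, s - k, s), end = ifelse(e > b, e - k, e),
         strand = str)
  })
}

.apply_inversion <- function(state, a, b) {
  state$seq[a:b] <- revcomp_vec(state$seq[a:b])
  .remap_all(state, function(s, e, str) {
    inside <- s >= a & e <= b
    ns <- ifelse(inside, a + b - e, s)
    ne <- ifelse(inside, a + b - s, e)
    nstr <- str
    if (!is.null(str))
      nstr <- ifelse(inside & str %in% c("+", "-"),
                     ifelse(str == "+", "-", "+"), str)
    list(start = ns, end = ne, strand = nstr, flip = inside)
  })
}

## point substitutions along a branch; returns updated state
.mutate_branch <- function(state, t, config, branch, counter) {
  if (t <= 0) return(state)
  L <- .state_len(state)
  coding <- rep(FALSE, L)
  if (nrow(state$features)) {
    cds <- state$features[state$features$type == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(cds))) coding[cds$start[i]:cds$end[i]] <- TRUE
  }
  ## loss targets are excluded so their content is identical across
  ## retaining lineages and ledger substitution arithmetic stays exact
  excl <- rep(FALSE, L)
  lt <- state$events[state$events$kind == "loss_target" &
                       !state$events$deleted, , drop = FALSE]
  for (i in seq_len(nrow(lt))) excl[lt$start[i]:lt$end[i]] <- TRUE
  p <- ifelse(coding, t * config$coding_rate_factor, t)
  p[excl] <- 0
  hit <- which(runif(L) < p)
  if (!length(hit)) return(state)
  from <- state$seq[hit]
  to <- vapply(from, .draw_base, "", w = config$ts_weight)
  state$seq[hit] <- to
  ids <- counter$next_ids(length(hit))
  state$subs <- rbind(state$subs, data.frame(
    sub_id = ids, pos = hit, from = from, to = to, branch = branch,
    stringsAsFactors = FALSE))
  state
}

## draw a substitute base: transition weight w vs 1 per transversion
.transition_of <- c(A = "G", G = "A", C = "T", T = "C")
.draw_base <- function(from, w) {
  tv <- setdiff(DNA_BASES, c(from, .transition_of[[from]]))
  sample(c(.transition_of[[from]], tv), 1L, prob = c(w, 1, 1))
}

## small indels along a branch (noncoding, outside tracked intervals)
.apply_indels <- function(state, t, config, branch) {
  if (t <= 0 || config$indel_rate <= 0) return(state)
  n <- rpois(1L, config$indel_rate * t * .state_len(state))
  rng <- config$indel_size_range
  for (i in seq_len(n)) {
    k <- sample(rng[1]:rng[2], 1L)
    sub_pts <- if (nrow(state$subs))
      data.frame(start = state$subs$pos, end = state$subs$pos) else NULL
    if (runif(1) < 0.5) {
      at <- .sample_point(state, extra_avoid = sub_pts)
      bases <- sample(DNA_BASES, k, replace = TRUE)
      state <- .apply_insertion(state, at, bases)
      state$indels <- rbind(state$indels, data.frame(
        pos = at, len = k, type = "insertion", branch = branch))
    } else {
      iv <- .sample_interval(state, k, extra_avoid = sub_pts,
                             what = "deletion")
      state <- .apply_deletion(state, iv[1], iv[2])
      state$indels <- rbind(state$indels, data.frame(
        pos = iv[1], len = k, type = "deletion", branch = branch))
    }
  }
  state
}

## copy a donor segment (character vector), apply divergence d, insert
.insert_event <- function(state, kind, donor_name, donor_seq, d_start, d_end,
                          divergence, branch, counter) {
  seg <- donor_seq[d_start:d_end]
  if (divergence > 0) {
    hit <- which(runif(length(seg)) < divergence)
    seg[hit] <- vapply(seg[hit], .draw_base, "", w = 1)
  }
  at <- .sample_point(state)
  state <- .apply_insertion(state, at, seg)
  state$events <- rbind(state$events, data.frame(
    event_id = counter$next_event(kind), kind = kind, start = at,
    end = at + length(seg) - 1L, strand = "+", branch = branch,
    donor = donor_name, donor_start = d_start, donor_end = d_end,
    deleted = FALSE, inserted_seq = paste(seg, collapse = ""),
    stringsAsFactors = FALSE))
  state
}

.make_counter <- function() {
  env <- new.env()
  env$sub <- 0L; env$ev <- 0L
  env$next_ids <- function(n) {
    out <- env$sub + seq_len(n); env$sub <- env$sub + n; out
  }
  env$next_event <- function(kind) {
    env$ev <- env$ev + 1L
    sprintf("%s_%03d", kind, env$ev)
  }
  env
}

## an open reading frame of len bp (multiple of 3): ATG + sense codons + stop
.make_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  stops <- c("TAA", "TAG", "TGA")
  n_mid <- len / 3 - 2L
  codons <- character(n_mid)
  for (i in seq_len(n_mid)) {
    repeat {
      cd <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1L))
}

## ---- public simulator -------------------------------------------------

#' Simulate a three-lineage mitogenome trio with full ground truth
#'
#' Evolves one simulated ancestral mitogenome down the rooted tree
#' ((C,S),D): ancestral chloroplast transfers and dispersed repeats are
#' planted at the root, lineage-restricted events (younger transfer,
#' duplication, gains, losses, foreign-donor insertion, nuclear-homologous
#' segment, one large inversion) on their configured branches, then
#' branch-length-scaled substitutions (coding sites at
#' `coding_rate_factor` times the noncoding rate) and 1-8 bp indels.
#' Genomes are emitted linearised at a shared randomly chosen rotation
#' locus (recorded in the ledger). Every planted interval, substitution
#' and indel is tracked through all later edits, so ledger coordinates
#' refer to the emitted sequences.
#'
#' @param config a [sim_config()]
#' @return object of class `mito_sim`: `genomes` (named list of three
#'   `annotated_genome`s C, S, D), `cp`, `nuclear`, `external` (foreign
#'   donor and close-relative mitochondrial sequences with a metadata
#'   table), and `ledger` (class `sim_ledger`: `events`, `substitutions`,
#'   `indels`, `rotations`, `recurrent`, per-genome tables in final
#'   coordinates)
#' @export
simulate_genomes <- function(config = sim_config()) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  cnt <- config$event_counts
  sz <- config$event_sizes
  br <- config$event_branches
  counter <- .make_counter()

  ## chloroplast reference with gene features inside the donor intervals
  cp_seq <- strsplit(random_dna(config$cp_len), "")[[1]]
  cp_features <- data.frame(type = character(), start = integer(),
                            end = integer(), strand = character(),
                            name = character(), stringsAsFactors = FALSE)
  place_cp_genes <- function(d_start, offsets, names_) {
    for (i in seq_along(offsets)) {
      orf <- strsplit(.make_orf(300L), "")[[1]]
      a <- d_start + offsets[i]
      cp_seq[a:(a + 299L)] <<- orf
      cp_features <<- rbind(cp_features, data.frame(
        type = "CDS", start = a, end = a + 299L, strand = "+",
        name = names_[i], stringsAsFactors = FALSE))
    }
  }
  donor_anc <- donor_lin <- NULL
  if (cnt["idt_ancestral"] > 0) {
    d0 <- sample.int(config$cp_len - sz["idt_ancestral"] - 1L, 1L)
    donor_anc <- c(d0, d0 + sz["idt_ancestral"] - 1L)
    offs <- c(200L, 1200L, 2200L, min(3600L, sz["idt_ancestral"] - 400L))
    offs <- unique(offs[offs + 300L < sz["idt_ancestral"]])
    place_cp_genes(d0, offs, paste0("cpg", seq_along(offs)))
  }
  if (cnt["idt_lineage"] > 0) {
    repeat {
      d0 <- sample.int(config$cp_len - sz["idt_lineage"] - 1L, 1L)
      donor_lin <- c(d0, d0 + sz["idt_lineage"] - 1L)
      if (is.null(donor_anc) || donor_lin[1] > donor_anc[2] ||
          donor_lin[2] < donor_anc[1]) break
    }
    offs <- c(500L, 1500L, 2500L)
    offs <- offs[offs + 300L < sz["idt_lineage"]]
    place_cp_genes(d0, offs, paste0("cpL", seq_along(offs)))
  }
  cp <- annotated_genome("cp", paste(cp_seq, collapse = ""), "circular",
                         cp_features)

  foreign_seq <- strsplit(random_dna(config$foreign_len), "")[[1]]

  ## ancestral mitogenome with protein-coding genes
  anc <- list(seq = strsplit(random_dna(config$mt_ancestor_len), "")[[1]],
              features = data.frame(type = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    name = character(),
                                    stringsAsFactors = FALSE),
              events = .empty_events(), subs = .empty_subs(),
              indels = data.frame(pos = integer(), len = integer(),
                                  type = character(), branch = character()))
  for (i in seq_len(config$n_genes)) {
    iv <- .sample_interval(anc, config$gene_len, what = "gene")
    anc$seq[iv[1]:iv[2]] <- strsplit(.make_orf(config$gene_len), "")[[1]]
    anc$features <- rbind(anc$features, data.frame(
      type = "CDS", start = iv[1], end = iv[2], strand = "+",
      name = paste0("mtg", i), stringsAsFactors = FALSE))
  }

  ## shared rotation locus, tracked like any event
  rot_at <- .sample_point(anc)
  anc$events <- rbind(anc$events, data.frame(
    event_id = "origin_marker", kind = "origin_marker", start = rot_at,
    end = rot_at, strand = "+", branch = "root", donor = NA,
    donor_start = NA, donor_end = NA, deleted = FALSE, inserted_seq = NA,
    stringsAsFactors = FALSE))

  ## root events -------------------------------------------------------
  for (i in seq_len(cnt["idt_ancestral"])) {
    d <- if (i == 1L) donor_anc else {
      d0 <- sample.int(config$cp_len - sz["idt_ancestral"] - 1L, 1L)
      c(d0, d0 + sz["idt_ancestral"] - 1L)
    }
    anc <- .insert_event(anc, "idt_ancestral", "cp", cp_seq, d[1], d[2],
                         config$idt_divergence, "root", counter)
  }
  for (i in seq_len(cnt["repeat_pair"])) {
    src <- .sample_interval(anc, sz["repeat_pair"], what = "repeat_pair")
    seg <- anc$seq[src[1]:src[2]]
    at <- .sample_point(anc)
    anc <- .apply_insertion(anc, at, seg)
    src2 <- if (src[1] >= at) src + sz["repeat_pair"] else src
    eid <- counter$next_event("repeat_pair")
    anc$events <- rbind(anc$events,
      data.frame(event_id = c(eid, paste0(eid, "_src")),
                 kind = "repeat_pair",
                 start = c(at, src2[1]), end = c(at + length(seg) - 1L, src2[2]),
                 strand = "+", branch = "root", donor = "self",
                 donor_start = src2[1], donor_end = src2[2], deleted = FALSE,
                 inserted_seq = paste(seg, collapse = ""),
                 stringsAsFactors = FALSE))
  }
  loss_branches <- rep(c("C", "S"), length.out = cnt["loss"])
  for (i in seq_len(cnt["loss"])) {
    iv <- .sample_interval(anc, sz["loss"], what = "loss")
    anc$events <- rbind(anc$events, data.frame(
      event_id = counter$next_event("loss_target"), kind = "loss_target",
      start = iv[1], end = iv[2], strand = "+", branch = loss_branches[i],
      donor = NA, donor_start = NA, donor_end = NA, deleted = FALSE,
      inserted_seq = paste(anc$seq[iv[1]:iv[2]], collapse = ""),
      stringsAsFactors = FALSE))
  }
  recurrent <- NULL
  if (cnt["recurrent_idt"] > 0) {
    host <- anc$events[anc$events$kind == "idt_ancestral", ][1, ]
    recurrent <- list(host_event = host$event_id,
                      overwrite_len = unname(sz["recurrent_idt"]),
                      donor_start = host$donor_start,
                      donor_end = host$donor_end)
  }

  ## helper to run one branch: structural events, indels, substitutions
  run_branch <- function(state, branch, t) {
    for (kind in names(br)) {
      if (br[[kind]] != branch) next
      for (i in seq_len(cnt[kind])) {
        state <- switch(kind,
          idt_lineage = .insert_event(state, "idt_lineage", "cp", cp_seq,
                                      donor_lin[1], donor_lin[2],
                                      config$idt_lineage_divergence, branch,
                                      counter),
          hdt = {
            d0 <- sample.int(config$foreign_len - sz["hdt"] - 1L, 1L)
            .insert_event(state, "hdt", "foreign", foreign_seq, d0,
                          d0 + sz["hdt"] - 1L, config$hdt_divergence,
                          branch, counter)
          },
          gain = {
            seg <- strsplit(random_dna(sz["gain"]), "")[[1]]
            at <- .sample_point(state)
            st <- .apply_insertion(state, at, seg)
            st$events <- rbind(st$events, data.frame(
              event_id = counter$next_event("gain"), kind = "gain",
              start = at, end = at + length(seg) - 1L, strand = "+",
              branch = branch, donor = "novel", donor_start = NA,
              donor_end = NA, deleted = FALSE,
              inserted_seq = paste(seg, collapse = ""),
              stringsAsFactors = FALSE))
            st
          },
          duplication = {
            src <- .sample_interval(state, sz["duplication"],
                                    what = "duplication source")
            seg <- state$seq[src[1]:src[2]]
            at <- .sample_point(state)
            st <- .apply_insertion(state, at, seg)
            src2 <- if (src[1] >= at) src + length(seg) else src
            st$events <- rbind(st$events, data.frame(
              event_id = counter$next_event("duplication"),
              kind = "duplication", start = at,
              end = at + length(seg) - 1L, strand = "+", branch = branch,
              donor = "self", donor_start = src2[1], donor_end = src2[2],
              deleted = FALSE, inserted_seq = paste(seg, collapse = ""),
              stringsAsFactors = FALSE))
            st
          },
          nuclear_homolog = {
            seg <- strsplit(random_dna(sz["nuclear_homolog"]), "")[[1]]
            at <- .sample_point(state)
            st <- .apply_insertion(state, at, seg)
            st$events <- rbind(st$events, data.frame(
              event_id = counter$next_event("nuclear_homolog"),
              kind = "nuclear_homolog", start = at,
              end = at + length(seg) - 1L, strand = "+", branch = branch,
              donor = "nuclear", donor_start = NA, donor_end = NA,
              deleted = FALSE, inserted_seq = paste(seg, collapse = ""),
              stringsAsFactors = FALSE))
            st
          },
          inversion = {
            iv <- .sample_spanning_interval(state, sz["inversion"],
                                            what = "inversion")
            st <- state
            st$events <- rbind(st$events, data.frame(
              event_id = counter$next_event("inversion"),
              kind = "inversion", start = iv[1], end = iv[2], strand = "+",
              branch = branch, donor = NA, donor_start = NA,
              donor_end = NA, deleted = FALSE, inserted_seq = NA,
              stringsAsFactors = FALSE))
            .apply_inversion(st, iv[1], iv[2])
          },
          state)
      }
    }
    ## branch-designated losses
    lt <- which(state$events$kind == "loss_target" &
                  state$events$branch == branch & !state$events$deleted)
    for (j in lt) {
      a <- state$events$start[j]; b <- state$events$end[j]
      state$events$deleted[j] <- TRUE
      state$events$start[j] <- a; state$events$end[j] <- a - 1L
      state <- .apply_deletion(state, a, b)
    }
    state <- .apply_indels(state, t, config, branch)
    .mutate_branch(state, t, config, branch, counter)
  }

  bl <- config$branch_lengths
  node_cs <- run_branch(anc, "CS", bl["CS"])
  g_C <- run_branch(node_cs, "C", bl["C"])
  g_S <- run_branch(node_cs, "S", bl["S"])
  g_D <- run_branch(anc, "D", bl["D"])

  ## nuclear reference: backbone plus any nuclear-homologous segments
  nuc_seq <- random_dna(config$nuclear_len)
  nuc_features <- data.frame(type = character(), start = integer(),
                             end = integer(), strand = character(),
                             name = character(), stringsAsFactors = FALSE)
  for (st in list(g_C, g_S, g_D)) {
    nh <- st$events[st$events$kind == "nuclear_homolog" &
                      !st$events$deleted, , drop = FALSE]
    for (i in seq_len(nrow(nh))) {
      at <- sample.int(nchar(nuc_seq) - 1L, 1L)
      nuc_seq <- paste0(substr(nuc_seq, 1, at), nh$inserted_seq[i],
                        substr(nuc_seq, at + 1L, nchar(nuc_seq)))
      nuc_features <- rbind(nuc_features, data.frame(
        type = "mt_homolog", start = at + 1L,
        end = at + nchar(nh$inserted_seq[i]), strand = "+",
        name = nh$event_id[i], stringsAsFactors = FALSE))
    }
  }

  ## close-relative external mitochondrial sequence: the root genome
  ## (ancestral transfers included) at 1% divergence
  rel <- anc$seq
  hit <- which(runif(length(rel)) < 0.01)
  rel[hit] <- vapply(rel[hit], .draw_base, "", w = 1)
  external <- Biostrings::DNAStringSet(c(
    relative_mt = paste(rel, collapse = ""),
    foreign_mt = paste(foreign_seq, collapse = "")))
  external_meta <- data.frame(
    id = c("relative_mt", "foreign_mt"),
    taxon = c("congener", "distant_plant"),
    relatedness = c("close", "distant"), stringsAsFactors = FALSE)

  ## rotate each genome at the shared (tracked) origin marker
  finalize <- function(state, id) {
    L <- .state_len(state)
    off <- 1L
    if (config$rotate) {
      off <- state$events$start[state$events$event_id == "origin_marker"]
      rot <- function(s, e, str)
        list(start = rotate_pos(s, off, L), end = rotate_pos(e, off, L),
             strand = str)
      state$seq <- c(state$seq[off:L], if (off > 1L) state$seq[1:(off - 1L)])
      state <- .remap_all(state, rot)
      if (nrow(state$indels))
        state$indels$pos <- rotate_pos(state$indels$pos, off, L)
    }
    state$rotation <- off
    state$id <- id
    state
  }
  g_C <- finalize(g_C, "C"); g_S <- finalize(g_S, "S")
  g_D <- finalize(g_D, "D")

  to_genome <- function(st) {
    ev <- st$events[!st$events$deleted &
                      st$events$kind != "origin_marker", , drop = FALSE]
    feats <- rbind(st$features,
                   data.frame(type = ev$kind, start = ev$start,
                              end = ev$end, strand = ev$strand,
                              name = ev$event_id, stringsAsFactors = FALSE))
    annotated_genome(st$id, paste(st$seq, collapse = ""), "circular", feats)
  }

  states <- list(C = g_C, S = g_S, D = g_D)
  bind_with_genome <- function(field) {
    do.call(rbind, lapply(names(states), function(g) {
      df <- states[[g]][[field]]
      if (!nrow(df)) return(NULL)
      cbind(genome = g, df, stringsAsFactors = FALSE)
    }))
  }
  events <- bind_with_genome("events")
  if (!is.null(events))
    events <- events[events$kind != "origin_marker", , drop = FALSE]
  subs <- bind_with_genome("subs")
  indels <- bind_with_genome("indels")

  if (!is.null(recurrent)) {
    host <- g_C$events[g_C$events$event_id == recurrent$host_event, ]
    recurrent$genome <- "C"
    recurrent$region_start <- host$start
    recurrent$region_end <- host$end
    recurrent$strand <- host$strand
    ## overwritten prefix is measured on the event's forward strand
    recurrent$breakpoint <- host$start + recurrent$overwrite_len
  }

  ledger <- structure(list(
    events = events %||% .empty_events(),
    substitutions = subs %||% .empty_subs(),
    indels = indels,
    rotations = c(C = g_C$rotation, S = g_S$rotation, D = g_D$rotation),
    recurrent = recurrent,
    seed = config$seed), class = "sim_ledger")

  structure(list(
    genomes = lapply(states, to_genome),
    cp = cp,
    nuclear = annotated_genome("nuclear", nuc_seq, "linear", nuc_features),
    external = external, external_meta = external_meta,
    ledger = ledger, config = config,
    states = states), class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  lens <- vapply(x$genomes, function(g) nchar(g$seq), 0)
  cat(sprintf(paste0("<mito_sim> seed=%d; genomes C=%d S=%d D=%d bp; ",
                     "%d ledgered events, %d substitutions, %d indels\n"),
              x$config$seed, lens["C"], lens["S"], lens["D"],
              length(unique(x$ledger$events$event_id)),
              length(unique(x$ledger$substitutions$sub_id)),
              if (is.null(x$ledger$indels)) 0L else nrow(x$ledger$indels)))
  invisible(x)
}

#' @export
print.sim_ledger <- function(x, ...) {
  cat(sprintf("<sim_ledger> %d event rows, %d substitution rows, seed %d\n",
              nrow(x$events), nrow(x$substitutions), x$seed))
  invisible(x)
}

#' Expected origin category of each planted event for one species pair
#'
#' Maps the truth ledger onto the six-way origin classification for the
#' regions of a given genome pair: chloroplast transfers unique to one
#' side are CP, duplications ID, segments retained from the ancestor but
#' lost in the partner (or gained on the shared stem) GL, foreign-donor
#' insertions PH and nuclear-homologous segments NU.
#'
#' @param sim a `mito_sim`
#' @param pair character vector of two genome ids, e.g. `c("C","D")`
#' @return data.frame: `genome`, `event_id`, `kind`, `start`, `end`,
#'   `expected`
#' @export
ledger_expected_origins <- function(sim, pair) {
  stopifnot(length(pair) == 2, all(pair %in% c("C", "S", "D")))
  ev <- sim$ledger$events
  third <- setdiff(c("C", "S", "D"), pair)
  out <- NULL
  lineage_of <- function(g) if (g %in% c("C", "S")) c(g, "CS") else g
  for (g in pair) {
    other <- setdiff(pair, g)
    e <- ev[ev$genome == g & !ev$deleted, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      kind <- e$kind[i]; branch <- e$branch[i]
      expected <- NULL
      if (kind %in% c("idt_lineage") && !branch %in% lineage_of(other)) {
        expected <- "CP"
      } else if (kind == "duplication" && branch %in% lineage_of(g) &&
                 !branch %in% lineage_of(other)) {
        expected <- "ID"
      } else if (kind == "gain" && branch %in% lineage_of(g) &&
                 !branch %in% lineage_of(other) &&
                 branch %in% lineage_of(third)) {
        expected <- "GL"
      } else if (kind == "loss_target") {
        lost_other <- any(ev$genome == other & ev$event_id == e$event_id[i] &
                            ev$deleted)
        lost_third <- any(ev$genome == third & ev$event_id == e$event_id[i] &
                            ev$deleted)
        if (lost_other && !lost_third) expected <- "GL"
      } else if (kind == "hdt" && !branch %in% lineage_of(other)) {
        expected <- "PH"
      } else if (kind == "nuclear_homolog" && !branch %in% lineage_of(other)) {
        expected <- "NU"
      }
      if (!is.null(expected))
        out <- rbind(out, data.frame(genome = g, event_id = e$event_id[i],
                                     kind = kind, start = e$start[i],
                                     end = e$end[i], expected = expected,
                                     stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(genome = character(), event_id = character(),
                      kind = character(), start = integer(),
                      end = integer(), expected = character())
}

#' Simulate a population sample of the recurrent-transfer region
#'
#' Draws per-individual sequences of the ledgered ancestral-transfer
#' region: carriers (exactly `round(n_individuals * carrier_fraction)` of
#' them, chosen at random) are chimeric, matching the chloroplast donor on
#' one side of the ledger breakpoint and the mitochondrial lineage on the
#' other; non-carriers carry the plain mitochondrial copy.
#'
#' @param sim a `mito_sim` whose config planted a `recurrent_idt` event
#' @param n_individuals number of individuals (>= 1)
#' @param carrier_fraction proportion of carriers; defaults to the
#'   config's `recurrent_idt_carrier_fraction`
#' @param seed optional seed (defaults to the simulation seed + 1)
#' @return list of class `sim_population`: `sequences` (`DNAStringSet`,
#'   one per individual), `carrier` (logical), `breakpoint` (1-based
#'   offset within the region: columns up to it are chloroplast-derived
#'   in carriers), `region` (ledger template)
#' @export
simulate_population <- function(sim, n_individuals,
                                carrier_fraction =
                                  sim$config$recurrent_idt_carrier_fraction,
                                seed = sim$config$seed + 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  tmpl <- sim$ledger$recurrent
  if (is.null(tmpl))
    stop("simulation has no recurrent_idt event; nothing to sample")
  set.seed(seed)
  g <- sim$genomes[[tmpl$genome]]
  mt_seq <- substr(g$seq, tmpl$region_start, tmpl$region_end)
  cp_seq <- substr(sim$cp$seq, tmpl$donor_start, tmpl$donor_end)
  stopifnot(nchar(mt_seq) == nchar(cp_seq))
  k <- nchar(mt_seq)
  bp <- tmpl$overwrite_len
  chimera <- paste0(substr(cp_seq, 1, bp), substr(mt_seq, bp + 1L, k))
  n_car <- round(n_individuals * carrier_fraction)
  carrier <- rep(FALSE, n_individuals)
  if (n_car > 0) carrier[sample.int(n_individuals, n_car)] <- TRUE
  seqs <- ifelse(carrier, chimera, mt_seq)
  names(seqs) <- sprintf("ind%02d", seq_len(n_individuals))
  list2 <- list(sequences = Biostrings::DNAStringSet(seqs),
                carrier = carrier, breakpoint = bp, region = tmpl)
  structure(list2, class = "sim_population")
}

#' Simulate long reads, optionally with recombinant conformations
#'
#' Reads are drawn uniformly from the (circular) genome with
#' normally distributed lengths and a uniform per-base error rate; half
#' are reverse-complemented. For each supplied repeat pair, a fraction
#' `recombinant_read_fraction` of the reads that span one repeat copy plus
#' `flank` bp on both sides is rewritten to a recombinant flank
#' combination before errors are applied. Truth labels are returned per
#' read.
#'
#' @param genome `annotated_genome` or string
#' @param repeat_pairs data.frame of repeat pairs (`start1`, `end1`,
#'   `start2`, `end2`, `relation`) or NULL
#' @param config a [sim_config()] (read length, error and recombinant
#'   fractions are taken from it)
#' @param n_reads number of reads
#' @param flank spanning-read flank requirement (bp)
#' @param seed seed (defaults to the config seed + 2)
#' @param start_window optional interval restricting read start positions
#'   (e.g. around a repeat of interest for a targeted assay)
#' @return list of class `sim_reads`: `reads` (`DNAStringSet`), `truth`
#'   (data.frame: `read`, `start`, `length`, `strand`, `repeat_idx`,
#'   `conformation`)
#' @export
simulate_long_reads <- function(genome, repeat_pairs = NULL,
                                config = sim_config(), n_reads = 500,
                                flank = 100, seed = config$seed + 2L,
                                start_window = NULL) {
  s <- as_seq(genome)
  L <- nchar(s)
  circular <- !is(genome, "annotated_genome") ||
    genome$topology == "circular"
  if (!is.null(repeat_pairs) && nrow(repeat_pairs)) {
    short <- repeat_pairs$end1 - repeat_pairs$start1 + 1L <= 100L
    if (any(short))
      stop("recombination assay repeats must be > 100 bp")
    if (!circular &&
        any(repeat_pairs$start1 - flank < 1 | repeat_pairs$end2 + flank > L))
      stop("repeat too close to sequence end on a linear genome")
  }
  set.seed(seed)
  lens <- pmax(100L, round(rnorm(n_reads, config$read_len_mean,
                                 config$read_len_sd)))
  lens <- pmin(lens, L)
  starts <- if (is.null(start_window))
    sample.int(if (circular) L else max(1L, L - max(lens)), n_reads,
               replace = TRUE)
  else
    sample(start_window[1]:start_window[2], n_reads, replace = TRUE)
  SS <- if (circular) paste0(s, s) else s
  reads <- substring(SS, starts, starts + lens - 1L)
  truth <- data.frame(read = sprintf("read%05d", seq_len(n_reads)),
                      start = starts, length = lens,
                      strand = rep("+", n_reads),
                      repeat_idx = NA_integer_,
                      conformation = NA_character_,
                      stringsAsFactors = FALSE)
  ## rewrite a fraction of repeat-spanning reads to recombinant form
  if (!is.null(repeat_pairs) && nrow(repeat_pairs) &&
      config$recombinant_read_fraction > 0) {
    for (ri in seq_len(nrow(repeat_pairs))) {
      rp <- repeat_pairs[ri, ]
      spans <- which(starts <= rp$start1 - flank &
                       starts + lens - 1L >= rp$end1 + flank)
      if (!length(spans)) next
      truth$repeat_idx[spans] <- ri
      truth$conformation[spans] <- "parental"
      rec <- spans[runif(length(spans)) < config$recombinant_read_fraction]
      for (i in rec) {
        rs <- starts[i]; re <- starts[i] + lens[i] - 1L
        keep_right <- runif(1) < 0.5
        if (rp$relation %||% "direct" == "direct") {
          if (keep_right) {
            ## left flank of copy1 + repeat + right flank of copy2
            tail_len <- re - rp$end1
            reads[i] <- paste0(substring(SS, rs, rp$end1),
                               substr_circ(s, ((rp$end2) %% L) + 1L,
                                           rp$end2 + tail_len))
            truth$conformation[i] <- "recombinant_1"
          } else {
            head_len <- rp$start1 - rs
            reads[i] <- paste0(
              substr_circ(s, rp$start2 - head_len, rp$start2 - 1L),
              substring(SS, rp$start1, re))
            truth$conformation[i] <- "recombinant_2"
          }
        } else {
          if (keep_right) {
            tail_len <- re - rp$end1
            reads[i] <- paste0(substring(SS, rs, rp$end1),
                               revcomp(substr_circ(s, rp$start2 - tail_len,
                                                   rp$start2 - 1L)))
            truth$conformation[i] <- "recombinant_1"
          } else {
            head_len <- rp$start1 - rs
            reads[i] <- paste0(
              revcomp(substr_circ(s, rp$end2 + 1L, rp$end2 + head_len)),
              substring(SS, rp$start1, re))
            truth$conformation[i] <- "recombinant_2"
          }
        }
      }
    }
  }
  ## uniform sequencing error
  if (config$read_error_rate > 0) {
    reads <- vapply(reads, function(rd) {
      v <- strsplit(rd, "")[[1]]
      hit <- which(runif(length(v)) < config$read_error_rate)
      if (length(hit))
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  ## half the reads on the minus strand
  rc <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  reads[rc] <- vapply(reads[rc], revcomp, "", USE.NAMES = FALSE)
  truth$strand[rc] <- "-"
  out <- Biostrings::DNAStringSet(setNames(reads, truth$read))
  structure(list(reads = out, truth = truth), class = "sim_reads")
}

#' Write simulated reads as FASTQ
#' @param reads `sim_reads` or `DNAStringSet`
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  if (is(reads, "sim_reads")) reads <- reads$reads
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                        function(w)
                                          paste(rep("I", w), collapse = ""),
                                        ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Write a simulation to disk
#'
#' Emits per-genome FASTA and GFF3 (planted features, event id in column
#' 9), the chloroplast/nuclear/external references, and the truth ledger
#' and configuration as JSON.
#'
#' @param sim `mito_sim`
#' @param outdir output directory (created if needed)
#' @return invisibly, the manifest of written files
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in names(sim$genomes)) {
    fa <- file.path(outdir, paste0("mt_", g, ".fasta"))
    write_fasta(sim$genomes[[g]], fa)
    gff <- file.path(outdir, paste0("mt_", g, ".gff3"))
    feats <- sim$genomes[[g]]$features
    feats$seqid <- g
    feats$attributes <- paste0("ID=", ifelse(is.na(feats$name), ".",
                                             feats$name))
    write_gff3(feats, gff, seqid = g)
    paths <- c(paths, fa, gff)
  }
  fa_cp <- file.path(outdir, "cp.fasta"); write_fasta(sim$cp, fa_cp)
  fa_nu <- file.path(outdir, "nuclear.fasta")
  write_fasta(sim$nuclear, fa_nu)
  fa_ex <- file.path(outdir, "external.fasta")
  write_fasta(sim$external, fa_ex)
  lj <- file.path(outdir, "ledger.json")
  ledger <- sim$ledger
  jsonlite::write_json(
    list(events = ledger$events, substitutions = ledger$substitutions,
         indels = ledger$indels, rotations = as.list(ledger$rotations),
         recurrent = ledger$recurrent, seed = ledger$seed),
    lj, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  cj <- file.path(outdir, "config.json")
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg), cj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, fa_cp, fa_nu, fa_ex, lj, cj))
}
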