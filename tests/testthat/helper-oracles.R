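# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

mutate_seq <- function(s, n_sub) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), n_sub)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# one default-scale simulation shared by several test files (lazy, cached)
.sim_cache <- new.env()
shared_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_genomes(sim_config(seed = 42))
  .sim_cache$sim
}

# reduced-scale simulation config for repeated (multi-seed) properties;
# structural events stay larger than the default chaining gap so they
# interrupt collinear blocks, as at full scale
small_sim_config <- function(seed) {
  sim_config(
    seed = seed, mt_ancestor_len = 25000, cp_len = 9000,
    nuclear_len = 6000, foreign_len = 5000,
    n_genes = 6, gene_len = 600,
    event_sizes = c(idt_ancestral = 2200, idt_lineage = 1600,
                    duplication = 1200, gain = 1300, loss = 1200,
                    hdt = 1200, nuclear_homolog = 1100, inversion = 4000,
                    repeat_pair = 200, recurrent_idt = 900))
}

# quadratic dynamic-programming local-alignment oracle (independent of
# the blastn-backed implementation): best local alignment by
# Smith-Waterman as implemented in Biostrings
sw_oracle <- function(query, subject) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") query else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    if (is.null(best) || Biostrings::score(pa) > best$score) {
      qr <- c(Biostrings::start(Biostrings::pattern(pa)),
              Biostrings::end(Biostrings::pattern(pa)))
      if (strand == "-") qr <- nchar(query) - rev(qr) + 1
      best <- list(score = Biostrings::score(pa),
                   q_start = qr[1], q_end = qr[2],
                   s_start = Biostrings::start(Biostrings::subject(pa)),
                   s_end = Biostrings::end(Biostrings::subject(pa)),
                   strand = strand,
                   identity = Biostrings::nmatch(pa) /
                     nchar(as.character(Biostrings::alignedPattern(pa))))
    }
  }
  best
}

# quadratic per-diagonal maximal-repeat oracle: scans every diagonal of
# the (self x self) and (self x revcomp) comparison with rle
repeat_oracle <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  out <- list()
  for (d in seq_len(L - 1)) {
    m <- v[1:(L - d)] == v[(1 + d):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= k)) {
      if (starts[i] + d > starts[i] + r$lengths[i] - 1)  # non-overlapping
        out[[length(out) + 1]] <- data.frame(
          start1 = starts[i], start2 = starts[i] + d,
          len = r$lengths[i], relation = "direct")
    }
  }
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), "")[[1]]
  seen <- character()
  for (d in -(L - 1):(L - 1)) {
    i1 <- max(1, 1 + d):min(L, L + d)
    i2 <- i1 - d
    m <- v[i1] == rc[i2]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= k)) {
      a <- i1[starts[i]]
      len <- r$lengths[i]
      b_rc <- i2[starts[i]]
      b <- L - (b_rc + len - 1) + 1          # genome-forward coordinate
      lo <- min(a, b); hi <- max(a, b)
      if (lo + len - 1 >= hi) next           # overlapping copies / palindrome
      key <- paste(lo, hi, len)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- data.frame(start1 = lo, start2 = hi,
                                           len = len, relation = "inverted")
    }
  }
  if (!length(out)) return(data.frame(start1 = integer(),
                                      start2 = integer(), len = integer(),
                                      relation = character()))
  df <- do.call(rbind, out)
  df[order(df$relation, df$start1, df$start2), ]
}

# exhaustive two-state parsimony oracle on ((C,S),D), coded differently
# from the implementation: enumerates every internal-state assignment and
# derives the classification from the multiset of optimal event lists
parsimony_oracle <- function(presence) {
  p <- as.integer(presence[c("C", "S", "D")])
  assn <- expand.grid(root = 0:1, cs = 0:1)
  evs <- lapply(seq_len(nrow(assn)), function(i) {
    r <- assn$root[i]; m <- assn$cs[i]
    e <- character()
    if (r != m) e <- c(e, paste0(if (m) "gain" else "loss", "@CS"))
    if (m != p[1]) e <- c(e, paste0(if (p[1]) "gain" else "loss", "@C"))
    if (m != p[2]) e <- c(e, paste0(if (p[2]) "gain" else "loss", "@S"))
    if (r != p[3]) e <- c(e, paste0(if (p[3]) "gain" else "loss", "@D"))
    e
  })
  n <- vapply(evs, length, 0L)
  best <- evs[n == min(n)]
  if (min(n) == 0) return(list(call = "none", events = 0L))
  single <- unique(vapply(best, function(e)
    if (length(e) == 1) e else "multi", ""))
  if (length(single) == 1 && single != "multi") {
    parts <- strsplit(single, "@")[[1]]
    return(list(call = paste0(parts[1], "_in"), where = parts[2],
                events = min(n)))
  }
  list(call = "ambiguous", events = min(n))
}

# brute-force per-codon pathway oracle for Ks/Ka counting: straight
# recursive enumeration, no precomputation shared with the implementation
codon_pathway_oracle <- function(c1, c2, w = 1) {
  gc <- Biostrings::GENETIC_CODE
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  enum <- function(cur, remaining) {
    if (!length(remaining))
      return(list(list(syn = 0, nonsyn = 0, w = 1, stop = FALSE)))
    res <- list()
    for (j in remaining) {
      nxt <- cur
      substr(nxt, j, j) <- substr(c2, j, j)
      step_ts <- substr(nxt, j, j) == ts[[substr(cur, j, j)]]
      syn_step <- gc[[nxt]] != "*" && gc[[cur]] != "*" &&
        gc[[nxt]] == gc[[cur]]
      for (tail in enum(nxt, setdiff(remaining, j))) {
        res[[length(res) + 1]] <- list(
          syn = tail$syn + as.integer(syn_step),
          nonsyn = tail$nonsyn + as.integer(!syn_step),
          w = tail$w * (if (step_ts) w else 1),
          stop = tail$stop || gc[[nxt]] == "*")
      }
    }
    res
  }
  paths <- enum(c1, pos)
  ok <- Filter(function(p) !p$stop, paths)
  if (!length(ok)) ok <- paths
  wt <- vapply(ok, `[[`, 0, "w")
  c(syn = sum(vapply(ok, `[[`, 0, "syn") * wt) / sum(wt),
    nonsyn = sum(vapply(ok, `[[`, 0, "nonsyn") * wt) / sum(wt))
}

# exhaustive breakpoint-scan oracle: explicit double loop over every
# boundary and orientation, summing matches directly
breakpoint_oracle <- function(set) {
  d <- set$diagnostic
  nc <- set$n_col
  q_cp <- set$query[d] == set$cp_state[d]
  q_mt <- set$query[d] == set$consensus[d]
  best <- list(score = -Inf)
  for (orient in c("cp_left", "cp_right")) for (b in 1:(nc - 1)) {
    left <- d <= b
    s <- if (orient == "cp_left") sum(q_cp[left]) + sum(q_mt[!left])
         else sum(q_mt[left]) + sum(q_cp[!left])
    if (s > best$score) best <- list(score = s, boundary = b,
                                     orientation = orient)
  }
  one_seg <- max(sum(q_cp), sum(q_mt))
  if (best$score <= one_seg)
    return(list(verdict = if (sum(q_mt) >= sum(q_cp)) "all_mt" else "all_cp",
                score = one_seg))
  c(best, list(verdict = "chimera"))
}

# evolve a codon sequence under proportional acceptance of nonsynonymous
# changes (omega), used for Ks/Ka recovery checks
simulate_codon_pair <- function(n_codons, n_events, omega, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  codons <- names(gc)[gc != "*"]
  s1 <- sample(codons, n_codons, replace = TRUE)
  s2 <- s1
  done <- 0
  while (done < n_events) {
    i <- sample(n_codons, 1)
    j <- sample(3, 1)
    cur <- s2[i]
    base <- substr(cur, j, j)
    nxt <- cur
    substr(nxt, j, j) <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    if (gc[[nxt]] == "*") next
    syn <- gc[[nxt]] == gc[[cur]]
    if (!syn && runif(1) > omega) next
    s2[i] <- nxt
    done <- done + 1
  }
  list(s1 = paste(s1, collapse = ""), s2 = paste(s2, collapse = ""))
}
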