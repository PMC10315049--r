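#' Simulation configuration for the three-lineage organelle generator
#'
#' Defines the study conditions for [simulate_genomes()]: a rooted
#' three-taxon tree ((C,S),D) with branch lengths on the noncoding
#' substitutions/site scale, a coding/noncoding rate ratio, indel and
#' structural-event inventories, and long-read parameters. Defaults mirror
#' a trio of closely related plant mitogenomes: terminal C and S branches
#' of 1.55e-4 each (about 3.1e-4 pairwise noncoding divergence), a C-D
#' noncoding distance near 4.45e-3, a coding rate three-fold lower than
#' noncoding, indels of 1-8 bp at about half the substitution rate, a
#' 5.1 kb ancestral chloroplast transfer about 2.4% diverged from its
#' donor, an additional ~8 kb lineage-specific transfer on the D branch,
#' and a recurrent-transfer template overwriting the first 3.3 kb of the
#' ancestral transfer, carried by one third of sampled individuals.
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs
#' @param mt_ancestor_len ancestral mitogenome length (bp)
#' @param cp_len,nuclear_len,foreign_len reference sequence lengths (bp)
#' @param branch_lengths named numeric: `C`, `S`, `CS` (stem), `D`,
#'   noncoding substitutions/site
#' @param coding_rate_factor ratio of coding to noncoding substitution rate
#' @param ts_weight relative weight of the transition against each of the
#'   two transversions; 1 gives one third transitions
#' @param indel_rate indel events per site per unit branch length
#' @param indel_size_range integer pair, bp (default 1-8)
#' @param event_counts named integer: events per kind (`idt_ancestral`,
#'   `idt_lineage`, `duplication`, `gain`, `loss`, `hdt`,
#'   `nuclear_homolog`, `inversion`, `repeat_pair`, `recurrent_idt`)
#' @param event_sizes named integer: segment size per kind (bp);
#'   `recurrent_idt` is the overwritten prefix of the ancestral transfer
#' @param event_branches named character: branch carrying each
#'   lineage-restricted event kind
#' @param idt_divergence divergence applied to the ancestral transfer copy
#'   at insertion (donor-vs-copy distance)
#' @param idt_lineage_divergence same for the younger lineage transfer
#' @param hdt_divergence donor-vs-copy divergence of the foreign insertion
#' @param recurrent_idt_carrier_fraction proportion of sampled individuals
#'   carrying the recurrent-transfer chimera
#' @param n_genes,gene_len mitochondrial protein-coding gene inventory
#' @param read_len_mean,read_len_sd,read_error_rate long-read model
#' @param recombinant_read_fraction per repeat pair, fraction of
#'   repeat-spanning reads given a recombinant flank combination
#' @param rotate emit genomes linearised at a (ledgered) random rotation
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       mt_ancestor_len = 60000L,
                       cp_len = 25000L,
                       nuclear_len = 20000L,
                       foreign_len = 12000L,
                       branch_lengths = c(C = 1.55e-4, S = 1.55e-4,
                                          CS = 1.0e-3, D = 3.3e-3),
                       coding_rate_factor = 1 / 3,
                       ts_weight = 1,
                       indel_rate = 0.5,
                       indel_size_range = c(1L, 8L),
                       event_counts = c(idt_ancestral = 1L, idt_lineage = 1L,
                                        duplication = 1L, gain = 1L,
                                        loss = 2L, hdt = 1L,
                                        nuclear_homolog = 1L, inversion = 1L,
                                        repeat_pair = 2L, recurrent_idt = 1L),
                       event_sizes = c(idt_ancestral = 5100L,
                                       idt_lineage = 8000L,
                                       duplication = 2000L, gain = 2700L,
                                       loss = 2000L, hdt = 1500L,
                                       nuclear_homolog = 1200L,
                                       inversion = 15000L,
                                       repeat_pair = 300L,
                                       recurrent_idt = 3300L),
                       event_branches = c(idt_lineage = "D",
                                          duplication = "C", gain = "CS",
                                          hdt = "D", nuclear_homolog = "D",
                                          inversion = "S"),
                       idt_divergence = 0.024,
                       idt_lineage_divergence = 0.002,
                       hdt_divergence = 0.05,
                       recurrent_idt_carrier_fraction = 1 / 3,
                       n_genes = 10L, gene_len = 900L,
                       read_len_mean = 2000L, read_len_sd = 200L,
                       read_error_rate = 0.05,
                       recombinant_read_fraction = 0,
                       rotate = TRUE) {
  kinds <- c("idt_ancestral", "idt_lineage", "duplication", "gain", "loss",
             "hdt", "nuclear_homolog", "inversion", "repeat_pair",
             "recurrent_idt")
  counts <- setNames(rep(0L, length(kinds)), kinds)
  counts[names(event_counts)] <- as.integer(event_counts)
  sizes <- eval(formals(sim_config)$event_sizes)
  sizes[names(event_sizes)] <- as.integer(event_sizes)
  stopifnot(
    length(indel_size_range) == 2L,
    indel_size_range[1] >= 1L, indel_size_range[1] <= indel_size_range[2],
    all(branch_lengths >= 0), indel_rate >= 0,
    coding_rate_factor >= 0, ts_weight >= 0,
    recurrent_idt_carrier_fraction >= 0,
    recurrent_idt_carrier_fraction <= 1,
    read_error_rate >= 0, read_error_rate < 1,
    recombinant_read_fraction >= 0, recombinant_read_fraction <= 1,
    all(counts >= 0), all(sizes >= 1),
    all(c("C", "S", "CS", "D") %in% names(branch_lengths)))
  if (counts["recurrent_idt"] > 0 && counts["idt_ancestral"] == 0)
    stop("recurrent_idt requires at least one idt_ancestral event")
  if (sizes["recurrent_idt"] >= sizes["idt_ancestral"] &&
      counts["recurrent_idt"] > 0)
    stop("recurrent_idt overwrite must be shorter than the ancestral transfer")
  structure(list(
    seed = as.integer(seed), mt_ancestor_len = as.integer(mt_ancestor_len),
    cp_len = as.integer(cp_len), nuclear_len = as.integer(nuclear_len),
    foreign_len = as.integer(foreign_len),
    branch_lengths = branch_lengths[c("C", "S", "CS", "D")],
    coding_rate_factor = coding_rate_factor, ts_weight = ts_weight,
    indel_rate = indel_rate,
    indel_size_range = as.integer(indel_size_range),
    event_counts = counts, event_sizes = sizes,
    event_branches = event_branches,
    idt_divergence = idt_divergence,
    idt_lineage_divergence = idt_lineage_divergence,
    hdt_divergence = hdt_divergence,
    recurrent_idt_carrier_fraction = recurrent_idt_carrier_fraction,
    n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
    read_len_mean = as.integer(read_len_mean),
    read_len_sd = as.integer(read_len_sd),
    read_error_rate = read_error_rate,
    recombinant_read_fraction = recombinant_read_fraction,
    rotate = isTRUE(rotate)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed=%d ancestor=%d bp cp=%d bp; ",
                     "branches C=%g S=%g CS=%g D=%g; %d planted events\n"),
              x$seed, x$mt_ancestor_len, x$cp_len,
              x$branch_lengths["C"], x$branch_lengths["S"],
              x$branch_lengths["CS"], x$branch_lengths["D"],
              sum(x$event_counts)))
  invisible(x)
}
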