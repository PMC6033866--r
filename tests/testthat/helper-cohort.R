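# Draw a cohort of per-sample epiallele count vectors from per-area
# mixtures (molecule level only -- the inference layer's study condition;
# read-level fidelity is covered by the round-trip tests).
draw_cohort <- function(mixtures, n_per_area, n_molecules, seed, reference) {
  areas <- rep(names(mixtures), each = n_per_area)
  pats <- sort(unique(unlist(lapply(mixtures, names))))
  counts <- matrix(0L, length(areas), length(pats),
                   dimnames = list(sprintf("%s_%02d", areas, seq_along(areas)),
                                   pats))
  for (i in seq_along(areas)) {
    spec <- epiallele_mixture_spec(reference$locus_name, mixtures[[areas[i]]],
                                   n_reads = n_molecules,
                                   seed = (seed * 1000L + i) %% .Machine$integer.max)
    mol <- sample_epialleles(spec, reference)
    tb <- table(mol$patterns)
    counts[i, names(tb)] <- as.integer(tb)
  }
  tab <- epiallele_count_table(counts, locus_name = reference$locus_name,
                               rarefaction_depth = n_molecules,
                               seed = seed)
  list(table = tab, areas = areas,
       class_freq = class_distribution(tab)$frequencies)
}
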