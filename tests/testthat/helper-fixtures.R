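# fixture builders shared across test files; everything is generated in
# code so the suite has no binary data dependencies

aln_from_strings <- function(strs, breed = NULL, region = "",
                             metapopulation = "") {
  if (is.null(names(strs))) names(strs) <- paste0("s", seq_along(strs))
  m <- do.call(rbind, strsplit(strs, ""))
  rownames(m) <- names(strs)
  if (is.null(breed)) breed <- rep("pop1", length(strs))
  mt_alignment(m, data.frame(sample_id = names(strs), breed = breed,
                             region = region,
                             metapopulation = metapopulation))
}

# closely related sequences (each `nmut` mutations from a shared base),
# so model-based distances stay far from saturation
related_aln <- function(n, L, nmut, seed, breed = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  base <- sample(bases, L, replace = TRUE)
  m <- matrix(rep(base, each = n), n, L)
  for (i in seq_len(n)) {
    at <- sample.int(L, nmut)
    for (j in at) m[i, j] <- sample(setdiff(bases, m[i, j]), 1)
  }
  rownames(m) <- paste0("s", seq_len(n))
  if (is.null(breed)) breed <- rep("pop1", n)
  mt_alignment(m, data.frame(sample_id = rownames(m), breed = breed,
                             region = "", metapopulation = ""))
}

random_aln <- function(n, L, seed, breed = NULL) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  if (is.null(breed)) breed <- rep("pop1", n)
  mt_alignment(m, data.frame(sample_id = rownames(m), breed = breed,
                             region = "", metapopulation = ""))
}

# write an alignment to temp FASTA/TSV, returning the two paths
write_temp_alignment <- function(a) {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_alignment(a, fa, tsv)
  c(fasta = fa, metadata = tsv)
}

# independent brute-force pairwise difference count (test oracle)
oracle_pairdiff <- function(seqs, i, j) {
  ok <- seqs[i, ] %in% c("A", "C", "G", "T") &
    seqs[j, ] %in% c("A", "C", "G", "T")
  sum(seqs[i, ok] != seqs[j, ok])
}

# small reference table built directly (no simulation) for white-box
# tests of the regression machinery
manual_reftable <- function(scenario_ids, params, stats, priors,
                            scenarios = NULL, pops = c("ME", "MP", "IS"),
                            samples = c(ME = 20L, MP = 20L, IS = 20L),
                            L = 600L) {
  structure(list(scenario = factor(scenario_ids, levels = unique(scenario_ids)),
                 params = as.data.frame(params), stats = as.matrix(stats),
                 scenarios = scenarios, priors = priors, samples = samples,
                 L = L, pops = pops, seed = NA_integer_),
            class = "mt_reftable")
}
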