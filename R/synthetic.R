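#' Configuration for the multi-breed synthetic data generator
#'
#' Describes the statistical structure the generator emulates: a few
#' deeply divergent mtDNA lineages; star-like expansion within each
#' lineage (recent growth from a small ancestral size); unequal lineage
#' frequencies across breeds (most breeds fixed or nearly fixed for the
#' dominant lineage, one outlier breed dominated by the minor lineage);
#' singleton-rich haplotype spectra.
#'
#' The default mixture puts lineage B at 79% in one outlier breed and
#' at a few percent or absent elsewhere, giving an overall minor-
#' lineage share under 10% across ~360 samples — the typical situation
#' in South Asian sheep breed surveys.
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed scalar or vector of per-breed sample sizes.
#' @param L locus length (bp).
#' @param n_lineages number of divergent lineages (2-3 typical).
#' @param divergence expected mutation count between lineage founders.
#' @param theta_within expected within-lineage mean pairwise
#'   differences (drives haplotype diversity).
#' @param expansion ratio of current to ancestral effective size for
#'   the within-lineage expansion (large = star-like).
#' @param weights breed x lineage mixture matrix (rows sum to 1);
#'   `NULL` installs the default outlier-breed pattern.
#' @param kappa,basefreq HKY mutation model.
#' @param seed RNG seed.
#' @return `mt_gencfg` list.
#' @export
generator_config <- function(n_breeds = 13L, samples_per_breed = 28L,
                             L = 612L, n_lineages = 2L, divergence = 30,
                             theta_within = 3, expansion = 100,
                             weights = NULL, kappa = 10,
                             basefreq = c(0.33, 0.26, 0.13, 0.28),
                             seed = 1L) {
  if (length(samples_per_breed) == 1L)
    samples_per_breed <- rep(samples_per_breed, n_breeds)
  stopifnot(length(samples_per_breed) == n_breeds,
            all(samples_per_breed > 0), n_lineages >= 1L, L > 0)
  if (is.null(weights)) {
    weights <- matrix(0, n_breeds, n_lineages)
    weights[, 1] <- 1
    if (n_lineages >= 2L && n_breeds >= 2L) {
      outlier <- min(6L, n_breeds)      # the "Mandya-like" breed
      weights[outlier, ] <- 0
      weights[outlier, 2] <- 0.79
      weights[outlier, 1] <- 0.21
      minor <- setdiff(seq_len(min(4L, n_breeds)), outlier)
      weights[minor, 2] <- 0.03
      weights[minor, 1] <- 0.97
    }
  }
  stopifnot(nrow(weights) == n_breeds, ncol(weights) == n_lineages,
            all(abs(rowSums(weights) - 1) < 1e-9), all(weights >= 0))
  structure(list(n_breeds = n_breeds,
                 samples_per_breed = as.integer(samples_per_breed),
                 L = as.integer(L), n_lineages = as.integer(n_lineages),
                 divergence = divergence, theta_within = theta_within,
                 expansion = expansion, weights = weights,
                 kappa = kappa, basefreq = basefreq, seed = seed),
            class = "mt_gencfg")
}

.bases <- c("A", "C", "G", "T")

.mutate_seq <- function(seq, n_mut, kappa, basefreq, sites = NULL) {
  L <- length(seq)
  if (is.null(sites)) sites <- sample.int(L, n_mut)
  for (s in sites) {
    cur <- match(seq[s], .bases)
    trans <- c(3L, 4L, 1L, 2L)[cur]
    w <- basefreq
    w[cur] <- 0
    w[trans] <- w[trans] * kappa
    seq[s] <- .bases[sample.int(4L, 1L, prob = w)]
  }
  seq
}

#' Generate a multi-breed synthetic alignment with known truth
#'
#' Lineage founders are placed `divergence` expected mutations apart;
#' within-lineage samples come from an expansion coalescent (large
#' current size, small ancestral size, recent growth), which yields
#' star-like networks and unimodal mismatch distributions; breed labels
#' are drawn from the configured mixture weights.  The truth record
#' tracks every sample's lineage by bookkeeping, so truth proportions
#' equal realized proportions exactly.
#'
#' @param cfg an `mt_gencfg` from [generator_config()].
#' @return List: `alignment` (an [mt_alignment()]), `truth` (list with
#'   per-sample `lineage`, `founders` alignment usable as references
#'   for [assign_lineage()], realized founder distances, and an
#'   `overlap_flag` raised when founders are < 3 mutations apart).
#' @export
generate_breeds <- function(cfg) {
  stopifnot(inherits(cfg, "mt_gencfg"))
  set.seed(cfg$seed)
  L <- cfg$L
  anc <- sample(.bases, L, replace = TRUE, prob = cfg$basefreq)
  lin_names <- LETTERS[seq_len(cfg$n_lineages)]
  founders <- matrix("", cfg$n_lineages, L,
                     dimnames = list(paste0("ref_", lin_names), NULL))
  for (l in seq_len(cfg$n_lineages)) {
    nm <- stats::rpois(1L, cfg$divergence / 2)
    founders[l, ] <- .mutate_seq(anc, nm, cfg$kappa, cfg$basefreq)
  }
  fd <- .hamming_mat(founders)
  overlap <- cfg$n_lineages > 1L && min(fd[upper.tri(fd)]) < 3
  ## per-sample lineage draws (breed mixture weights)
  breeds <- sprintf("Breed%02d", seq_len(cfg$n_breeds))
  breed_of <- rep(breeds, cfg$samples_per_breed)
  lineage_of <- character(length(breed_of))
  k <- 0L
  for (b in seq_len(cfg$n_breeds)) {
    nb <- cfg$samples_per_breed[b]
    lineage_of[k + seq_len(nb)] <-
      lin_names[sample.int(cfg$n_lineages, nb, replace = TRUE,
                           prob = cfg$weights[b, ])]
    k <- k + nb
  }
  ## within-lineage expansion coalescent: in a star-like genealogy of
  ## depth T, pairs differ by ~2*T*mu*L, so the growth time is set from
  ## theta_within; the current size is `expansion` times that depth
  ## (larger = fewer pre-expansion coalescences = more star-like), and
  ## the ancestral size is small so deeper history adds little
  mu <- 5e-8
  t_exp <- cfg$theta_within / (2 * mu * L)
  seqs <- matrix("", length(breed_of), L)
  scn <- scenario("expansion", c("cur", "anc"),
                  c(cur = "Ncur", anc = "Nanc"),
                  data.frame(derived = "cur", source = "anc", time = "texp"))
  for (l in seq_len(cfg$n_lineages)) {
    at <- which(lineage_of == lin_names[l])
    if (!length(at)) next
    base <- founders[l, ]
    if (length(at) == 1L) { seqs[at, ] <- base; next }
    pars <- list(Ncur = cfg$expansion * t_exp, Nanc = max(t_exp / 20, 1),
                 texp = t_exp, mu = mu, kappa = cfg$kappa)
    sim <- simulate_dataset(scn, pars,
                            c(cur = length(at), anc = 0L), L,
                            basefreq = cfg$basefreq, as_alignment = FALSE,
                            root_seq = base)
    m <- matrix(rep(base, each = length(at)), nrow = length(at))
    if (length(sim$positions))
      m[, sim$positions] <- .bases[sim$seqs]
    seqs[at, ] <- m
  }
  ids <- paste0(breed_of, "_",
                stats::ave(seq_along(breed_of), breed_of, FUN = seq_along))
  rownames(seqs) <- ids
  region <- ifelse(match(breed_of, breeds) <= ceiling(cfg$n_breeds / 2),
                   "south", "north")
  aln <- mt_alignment(seqs, data.frame(
    sample_id = ids, breed = breed_of, region = region,
    metapopulation = "IS"))
  ref_aln <- mt_alignment(founders, data.frame(
    sample_id = rownames(founders), breed = lin_names,
    region = "", metapopulation = ""))
  list(alignment = aln,
       truth = list(lineage = stats::setNames(lineage_of, ids),
                    proportions = table(lineage_of) / length(lineage_of),
                    founders = ref_aln,
                    founder_distances = fd,
                    overlap_flag = overlap))
}

#' Labelled reference haplotypes for the five mtDNA lineages
#'
#' Five synthetic reference haplotypes (lineages A-E) on a 612-site
#' window, constructed so that every pair differs at >= 15 sites
#' (disjoint 15-mutation blocks per lineage).  These are stand-ins for
#' curated GenBank reference sequences and are labelled via the `breed`
#' metadata column, the convention [assign_lineage()] reads by default.
#'
#' @param L window length.
#' @param n_mut mutations per lineage block.
#' @param seed RNG seed.
#' @return An [mt_alignment()] of 5 labelled references.
#' @export
generate_reference_fixture <- function(L = 612L, n_mut = 15L, seed = 42L) {
  set.seed(seed)
  anc <- sample(.bases, L, replace = TRUE)
  lin <- LETTERS[1:5]
  stopifnot(L >= 5L * n_mut)
  blocks <- split(seq_len(5L * n_mut), rep(1:5, each = n_mut))
  seqs <- matrix("", 5L, L, dimnames = list(paste0("ref_", lin), NULL))
  for (l in 1:5) {
    s <- anc
    for (j in blocks[[l]]) {
      alt <- setdiff(.bases, s[j])
      s[j] <- alt[sample.int(3L, 1L)]
    }
    seqs[l, ] <- s
  }
  mt_alignment(seqs, data.frame(sample_id = rownames(seqs), breed = lin,
                                region = "", metapopulation = ""))
}
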