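#' Simulate one dataset under a demographic scenario
#'
#' Single-locus haploid coalescent under the scenario's event program
#' (constant effective size per population, instantaneous splits),
#' with mutations placed as a Poisson process (rate `mu` per site per
#' generation) along branches and resolved with an HKY jump chain.
#'
#' @param s an `mt_scenario`.
#' @param params named list of drawn values as from [draw_params()]
#'   (sizes, times, `mu`, `kappa`).
#' @param samples named integer vector: samples per extant population.
#' @param L locus length in bp.
#' @param basefreq equilibrium base frequencies (A, C, G, T).
#' @param as_alignment if `TRUE` return an [mt_alignment()] of full
#'   length-`L` sequences; otherwise a light internal record (integer
#'   matrix of mutated sites only) used by the reference-table loop.
#' @param root_seq optional character vector of length `L` fixing the
#'   ancestral sequence; `NULL` draws ancestral states from `basefreq`.
#' @return An [mt_alignment()] (population written to the
#'   `metapopulation` and `breed` metadata columns) or internal record.
#' @export
simulate_dataset <- function(s, params, samples, L = 600L,
                             basefreq = c(0.33, 0.26, 0.13, 0.28),
                             as_alignment = TRUE, root_seq = NULL) {
  stopifnot(inherits(s, "mt_scenario"))
  if (!all(s$pops %in% names(samples)))
    stop("`samples` must name every population of the scenario", call. = FALSE)
  bad <- .check_constraints(s, params)
  if (!is.null(bad))
    stop("params violate constraint ", paste(bad, collapse = " "),
         call. = FALSE)
  samples <- samples[s$pops]
  if (sum(samples) < 1L) stop("zero sample total", call. = FALSE)
  ne <- vapply(s$pops, function(p) params[[s$ne[[p]]]], numeric(1))
  ev_t <- vapply(s$events$time, function(sym) params[[sym]], numeric(1))
  ord <- order(ev_t)
  root_int <- if (is.null(root_seq)) integer(0)
              else as.integer(match(root_seq, c("A", "C", "G", "T")))
  sim <- sim_coal_cpp(as.integer(samples), ne,
                      ev_t[ord],
                      as.integer(match(s$events$derived[ord], s$pops) - 1L),
                      as.integer(match(s$events$source[ord], s$pops) - 1L),
                      params$mu, as.integer(L), params$kappa, basefreq,
                      root_int)
  if (!as_alignment)
    return(structure(list(seqs = sim$seqs, positions = sim$positions,
                          pop = s$pops[sim$pop + 1L], pops = s$pops,
                          L = L, tmrca = sim$tmrca),
                     class = "mt_simdata"))
  bases <- c("A", "C", "G", "T")
  n <- nrow(sim$seqs)
  root <- if (is.null(root_seq))
    sample(bases, L, replace = TRUE, prob = basefreq) else root_seq
  m <- matrix(rep(root, each = n), nrow = n)
  if (length(sim$positions))
    m[, sim$positions] <- bases[sim$seqs]
  pop <- s$pops[sim$pop + 1L]
  ids <- paste0(pop, "_", stats::ave(seq_len(n), pop, FUN = seq_along))
  rownames(m) <- ids
  mt_alignment(m, data.frame(sample_id = ids, breed = pop, region = pop,
                             metapopulation = pop))
}

#' DIYABC-style summary statistics of an alignment
#'
#' Per population: mean pairwise differences; mean and variance of the
#' rarest-nucleotide count over the population's segregating sites (the
#' number of gene copies carrying the least frequent base at the site;
#' ties take the minimum).  Per population pair: mean pairwise
#' differences between populations (the uncorrected "(B)" statistic)
#' and Phi_ST.  Statistic order is fixed by `pops`.
#'
#' Populations with no segregating site report 0 for the
#' rarest-nucleotide statistics and are recorded in the `flags`
#' attribute.
#'
#' @param a an [mt_alignment()] or the light record from
#'   [simulate_dataset()].
#' @param pops population names fixing the statistic order; default
#'   sorted unique labels.
#' @param pop_level metadata column holding population labels.
#' @return Named numeric vector with attribute `flags`.
#' @export
summary_stats <- function(a, pops = NULL, pop_level = "metapopulation") {
  if (inherits(a, "mt_simdata")) {
    X <- a$seqs
    labs <- a$pop
    if (is.null(pops)) pops <- a$pops
  } else {
    stopifnot(inherits(a, "mt_alignment"))
    X0 <- .encode(a$seqs)
    X0 <- X0[, colSums(is.na(X0)) == 0L, drop = FALSE]
    ## keep polymorphic columns only (constant sites contribute nothing)
    X <- X0[, apply(X0, 2L, function(v) length(unique(v)) > 1L), drop = FALSE]
    labs <- a$labels[[pop_level]]
    if (is.null(pops)) pops <- sort(unique(labs))
  }
  if (!all(labs %in% pops))
    stop("population label(s) absent from `pops`: ",
         paste(setdiff(labs, pops), collapse = ", "), call. = FALSE)
  if (!all(pops %in% labs))
    stop("population absent from data: ",
         paste(setdiff(pops, labs), collapse = ", "), call. = FALSE)
  pop_idx <- as.integer(match(labs, pops) - 1L)
  v <- sumstats_cpp(X, pop_idx, length(pops))
  nm <- c(t(outer(pops, c("pi", "mean_rare", "var_rare"),
                  function(p, s) paste0(s, ".", p))))
  if (length(pops) > 1L) {
    prs <- utils::combn(pops, 2L)
    nm <- c(nm, c(rbind(paste0("piB.", prs[1, ], ".", prs[2, ]),
                        paste0("fst.", prs[1, ], ".", prs[2, ]))))
  }
  names(v) <- nm
  flags <- pops[vapply(seq_along(pops), function(i) {
    sub <- X[pop_idx == i - 1L, , drop = FALSE]
    ncol(sub) == 0L ||
      !any(apply(sub, 2L, function(col) length(unique(col)) > 1L))
  }, TRUE)]
  attr(v, "flags") <- flags
  v
}
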