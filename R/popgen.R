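## ---- internal distance machinery ------------------------------------------

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

## integer-encode an alignment: ACGT -> 1..4, everything else -> NA
.encode <- function(seqs) {
  m <- matrix(.base_codes[seqs], nrow = nrow(seqs),
              dimnames = dimnames(seqs))
  m
}

#' Pairwise difference matrix (Hamming counts)
#'
#' Number of differing sites for every pair of samples, over the sites
#' retained by `missing_policy`.  Under `exclude_site`, columns with any
#' gap/N/ambiguity are dropped for everyone (complete deletion); under
#' `pairwise`, each pair is compared over the sites where both samples
#' carry an unambiguous base.
#'
#' @inheritParams polymorphic_sites
#' @return Symmetric numeric matrix of counts, zero diagonal.
#' @export
pairwise_diff_matrix <- function(a, missing_policy = c("exclude_site", "pairwise")) {
  stopifnot(inherits(a, "mt_alignment"))
  missing_policy <- match.arg(missing_policy)
  X <- .encode(a$seqs)
  if (missing_policy == "exclude_site") {
    keep <- which(colSums(is.na(X)) == 0L)
    X <- X[, keep, drop = FALSE]
    V <- matrix(1, nrow(X), ncol(X))
  } else {
    V <- 1 - is.na(X)
  }
  Xv <- X; Xv[is.na(Xv)] <- 0L
  matches <- matrix(0, nrow(X), nrow(X))
  for (b in 1:4) {
    Ib <- (Xv == b) * 1
    matches <- matches + tcrossprod(Ib)
  }
  valid <- tcrossprod(V)
  d <- valid - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(a$seqs), rownames(a$seqs))
  d
}

.pop_vector <- function(a, pop_level) a$labels[[pop_level]]

## ---- haplotype diversity ---------------------------------------------------

#' Nei's haplotype (gene) diversity with standard error
#'
#' \eqn{h = \frac{n}{n-1}(1 - \sum p_i^2)} with sampling variance
#' \eqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#' (\sum p_i^2)^2\right] + \sum p_i^2 - (\sum p_i^2)^2\right\}}.
#'
#' @param counts vector of haplotype counts (one entry per distinct
#'   haplotype).
#' @param n total sample size; defaults to `sum(counts)`.
#' @return A list of class `mt_diversity` with `n`, `k` (number of
#'   haplotypes), `h` and `se_h`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- as.numeric(counts[counts > 0])
  if (abs(n - sum(counts)) > 1e-9)
    stop("n must equal sum(counts)", call. = FALSE)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  v <- max(v, 0)
  structure(list(n = n, k = length(counts), h = h, se_h = sqrt(v)),
            class = "mt_diversity")
}

#' @export
print.mt_diversity <- function(x, ...) {
  cat(sprintf("n = %d, k = %d, h = %.4f +/- %.4f\n", x$n, x$k, x$h, x$se_h))
  invisible(x)
}

#' Per-population diversity table
#'
#' Collapses haplotypes at `pop_level` and reports, per population,
#' sample size, haplotype count and Nei's diversity with its SE —
#' the layout of a classic "genetic diversity indices" table.
#'
#' @inheritParams collapse_haplotypes
#' @return data.frame with columns `population`, `n`, `k`, `h`, `se_h`.
#' @export
diversity_table <- function(a, missing_policy = "exclude_site",
                            pop_level = "breed") {
  h <- collapse_haplotypes(a, missing_policy, pop_level)
  out <- lapply(colnames(h$counts), function(p) {
    cnt <- h$counts[, p]
    cnt <- cnt[cnt > 0]
    n <- sum(cnt)
    if (n < 2) {
      data.frame(population = p, n = n, k = length(cnt), h = NA_real_,
                 se_h = NA_real_)
    } else {
      d <- haplotype_diversity(cnt)
      data.frame(population = p, n = d$n, k = d$k, h = d$h, se_h = d$se_h)
    }
  })
  do.call(rbind, out)
}

## ---- pairwise differences & mismatch --------------------------------------

#' Mean pairwise differences within or between populations
#'
#' Average Hamming distance over all unordered pairs within one
#' population, or over all cross pairs between two populations (the
#' uncorrected "(B)" two-sample statistic — not net of within-population
#' diversity).
#'
#' @inheritParams polymorphic_sites
#' @param within a single population name, or a character vector of two
#'   names for the between-population variant.
#' @param pop_level population level of `within`.
#' @export
mean_pairwise_differences <- function(a, within, pop_level = "breed",
                                      missing_policy = "exclude_site") {
  stopifnot(inherits(a, "mt_alignment"))
  pops <- .pop_vector(a, pop_level)
  d <- pairwise_diff_matrix(a, missing_policy)
  if (length(within) == 1L) {
    i <- which(pops == within)
    if (length(i) < 2L)
      stop("need >= 2 sequences in population '", within, "'", call. = FALSE)
    sub <- d[i, i]
    mean(sub[upper.tri(sub)])
  } else if (length(within) == 2L) {
    i <- which(pops == within[1]); j <- which(pops == within[2])
    if (length(i) < 1L || length(j) < 1L)
      stop("need >= 1 sequence in each population", call. = FALSE)
    mean(d[i, j, drop = FALSE])
  } else stop("`within` must name one or two populations", call. = FALSE)
}

#' Mismatch distribution
#'
#' Histogram of the pairwise difference counts among the sequences of
#' one population.  Unimodal mismatch distributions are the classic
#' signature of demographic expansion.
#'
#' @inheritParams mean_pairwise_differences
#' @param population population name; `NULL` uses all samples.
#' @return Named integer vector: frequency of each observed difference
#'   count; frequencies sum to `n(n-1)/2`.
#' @export
mismatch_distribution <- function(a, population = NULL, pop_level = "breed",
                                  missing_policy = "exclude_site") {
  stopifnot(inherits(a, "mt_alignment"))
  if (!is.null(population)) {
    keep <- .pop_vector(a, pop_level) == population
    a <- a[keep]
  }
  n <- length(a$sample_ids)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  d <- pairwise_diff_matrix(a, missing_policy)
  v <- d[upper.tri(d)]
  tab <- table(factor(v, levels = sort(unique(v))))
  stats::setNames(as.integer(tab), names(tab))
}

## ---- AMOVA -----------------------------------------------------------------

## sum over unordered pairs inside index set (treating d as squared distance)
.ssd <- function(d, idx) {
  if (length(idx) < 2L) return(0)
  sub <- d[idx, idx]
  sum(sub[upper.tri(sub)]) / length(idx)
}

.amova_components <- function(d, pops, groups = NULL) {
  N <- length(pops)
  pop_names <- unique(pops)
  P <- length(pop_names)
  ss_total <- sum(d[upper.tri(d)]) / N
  ss_wp <- sum(vapply(pop_names, function(p) .ssd(d, which(pops == p)),
                      numeric(1)))
  if (is.null(groups)) {
    df_ap <- P - 1L; df_wp <- N - P
    ms_wp <- ss_wp / df_wp
    ss_ap <- ss_total - ss_wp
    ms_ap <- ss_ap / df_ap
    n_sizes <- as.numeric(table(pops)[pop_names])
    n_c <- (N - sum(n_sizes^2) / N) / df_ap
    sigma_w <- ms_wp
    sigma_a <- (ms_ap - ms_wp) / n_c
    comp <- data.frame(
      source = c("among_populations", "within_populations", "total"),
      df = c(df_ap, df_wp, N - 1L),
      SS = c(ss_ap, ss_wp, ss_total),
      sigma2 = c(sigma_a, sigma_w, NA_real_))
    sig <- pmax(c(sigma_a, sigma_w), 0)
    tot <- sum(sig)
    comp$pct <- c(if (tot > 0) 100 * sig / tot else c(0, 100), NA)
    phi <- c(Phi_ST = if (tot > 0) sig[1] / tot else 0)
    list(components = comp, phi = phi)
  } else {
    grp_of_pop <- vapply(pop_names, function(p) groups[match(p, pops)], "")
    grp_names <- unique(groups)
    G <- length(grp_names)
    if (G < 2L) stop("need >= 2 groups for a two-level AMOVA", call. = FALSE)
    ss_g <- sum(vapply(grp_names, function(g) .ssd(d, which(groups == g)),
                       numeric(1)))
    ss_ag <- ss_total - ss_g          # among groups
    ss_apwg <- ss_g - ss_wp           # among populations within groups
    df_ag <- G - 1L; df_apwg <- P - G; df_wp <- N - P
    ms_wp <- ss_wp / df_wp
    ms_apwg <- ss_apwg / df_apwg
    ms_ag <- ss_ag / df_ag
    n_sizes <- as.numeric(table(pops)[pop_names])
    g_sizes <- as.numeric(table(groups)[grp_names])
    sum_np2_over_ng <- sum(vapply(grp_names, function(g) {
      p_in_g <- pop_names[grp_of_pop == g]
      sum((n_sizes[match(p_in_g, pop_names)])^2) / sum(pops %in% p_in_g)
    }, numeric(1)))
    a_coef <- (N - sum_np2_over_ng) / df_apwg
    b_coef <- (sum_np2_over_ng - sum(n_sizes^2) / N) / df_ag
    c_coef <- (N - sum(g_sizes^2) / N) / df_ag
    sigma_c <- ms_wp
    sigma_b <- (ms_apwg - sigma_c) / a_coef
    sigma_a <- (ms_ag - sigma_c - b_coef * sigma_b) / c_coef
    comp <- data.frame(
      source = c("among_groups", "among_populations_within_groups",
                 "within_populations", "total"),
      df = c(df_ag, df_apwg, df_wp, N - 1L),
      SS = c(ss_ag, ss_apwg, ss_wp, ss_total),
      sigma2 = c(sigma_a, sigma_b, sigma_c, NA_real_))
    sig <- pmax(c(sigma_a, sigma_b, sigma_c), 0)
    tot <- sum(sig)
    comp$pct <- c(if (tot > 0) 100 * sig / tot else c(0, 0, 100), NA)
    phi <- c(
      Phi_ST = if (tot > 0) (sig[1] + sig[2]) / tot else 0,
      Phi_CT = if (tot > 0) sig[1] / tot else 0,
      Phi_SC = if (sig[2] + sig[3] > 0) sig[2] / (sig[2] + sig[3]) else 0)
    list(components = comp, phi = phi)
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Nested decomposition of pairwise sequence distances into variance
#' components, following the sums-of-squared-deviations formulation on a
#' pairwise distance matrix.  With one grouping level the decomposition
#' is among/within populations (Phi_ST); with two levels it is among
#' groups / among populations within groups / within populations
#' (Phi_CT, Phi_SC, Phi_ST).
#'
#' Negative variance component estimates are reported as-is in
#' `components$sigma2`, but percentages and Phi statistics are computed
#' with negative components floored at zero — the presentation
#' convention of the standard software.
#'
#' @inheritParams polymorphic_sites
#' @param pop_level population level for the lower stratum.
#' @param group_level optional second level (e.g. `"region"`) nesting
#'   populations into groups; `NULL` for a one-level AMOVA.
#' @param n_perm number of label permutations for p-values (0 = skip).
#' @param distance `"pairwise_difference"` (counts of differing retained
#'   sites, Arlequin's default for sequence data) or
#'   `"haplotype_identity"` (0/1 distance).
#' @param seed RNG seed for the permutation test.
#' @return `mt_amova`: list with `components` (data.frame: source, df,
#'   SS, sigma2, pct), `phi`, and `p_values` when permuted.
#' @export
amova <- function(a, pop_level = "breed", group_level = NULL,
                  n_perm = 0L,
                  distance = c("pairwise_difference", "haplotype_identity"),
                  missing_policy = "exclude_site", seed = 1L) {
  stopifnot(inherits(a, "mt_alignment"))
  distance <- match.arg(distance)
  pops <- .pop_vector(a, pop_level)
  if (length(unique(pops)) < 2L)
    stop("AMOVA needs >= 2 populations", call. = FALSE)
  d <- pairwise_diff_matrix(a, missing_policy)
  if (distance == "haplotype_identity") d <- (d > 0) * 1
  groups <- if (!is.null(group_level)) .pop_vector(a, group_level) else NULL
  res <- .amova_components(d, pops, groups)
  res$distance <- distance
  if (n_perm > 0L) {
    set.seed(seed)
    obs <- res$phi
    hits <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      perm <- sample(length(pops))
      r <- tryCatch(
        .amova_components(d, pops[perm],
                          if (!is.null(groups)) groups[perm] else NULL),
        error = function(e) NULL)
      if (!is.null(r)) hits <- hits + (r$phi >= obs - 1e-12)
    }
    res$p_values <- stats::setNames((hits + 1) / (n_perm + 1), names(obs))
  }
  class(res) <- "mt_amova"
  res
}

#' @export
print.mt_amova <- function(x, ...) {
  cat("AMOVA (", x$distance, " distance)\n", sep = "")
  print(x$components, row.names = FALSE, digits = 4)
  cat("Phi: ", paste(sprintf("%s = %.4f", names(x$phi), x$phi),
                     collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("permutation p: ",
        paste(sprintf("%s %.4g", names(x$p_values), x$p_values),
              collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Phi_ST matrix
#'
#' Each cell is the two-population AMOVA Phi_ST.  Populations with fewer
#' than two samples are still computed but flagged.
#'
#' @inheritParams amova
#' @return `mt_fst`: list with `populations`, `fst` (symmetric matrix,
#'   zero diagonal), `p_values` (matrix or NULL), `flagged` (populations
#'   with n < 2).
#' @export
pairwise_fst <- function(a, pop_level = "breed", n_perm = 0L,
                         missing_policy = "exclude_site", seed = 1L) {
  stopifnot(inherits(a, "mt_alignment"))
  pops <- .pop_vector(a, pop_level)
  pop_names <- unique(pops)
  P <- length(pop_names)
  if (P < 2L) stop("need >= 2 populations", call. = FALSE)
  d <- pairwise_diff_matrix(a, missing_policy)
  fst <- matrix(0, P, P, dimnames = list(pop_names, pop_names))
  pv <- if (n_perm > 0L) matrix(NA_real_, P, P,
                                dimnames = list(pop_names, pop_names)) else NULL
  set.seed(seed)
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    idx <- which(pops %in% pop_names[c(i, j)])
    sub <- d[idx, idx]
    labs <- pops[idx]
    val <- .amova_components(sub, labs)$phi[["Phi_ST"]]
    fst[i, j] <- fst[j, i] <- val
    if (n_perm > 0L) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        r <- .amova_components(sub, labs[sample(length(labs))])
        if (r$phi[["Phi_ST"]] >= val - 1e-12) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  flagged <- pop_names[table(pops)[pop_names] < 2L]
  structure(list(populations = pop_names, fst = fst, p_values = pv,
                 flagged = flagged),
            class = "mt_fst")
}

#' @export
print.mt_fst <- function(x, ...) {
  cat("pairwise Phi_ST for", length(x$populations), "populations\n")
  print(round(x$fst, 4))
  if (length(x$flagged))
    cat("flagged (n < 2):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Export a Phi_ST matrix as a square TSV
#' @param f an `mt_fst`.
#' @param path output path.
#' @export
write_fst_matrix <- function(f, path) {
  stopifnot(inherits(f, "mt_fst"))
  utils::write.table(cbind(population = rownames(f$fst), as.data.frame(f$fst)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
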