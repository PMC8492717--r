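## per-pair substitution tallies: P1 = A<->G transitions, P2 = C<->T,
## Q = transversions, n = compared sites; vectorized over pairs
.pair_counts <- function(X) {
  n <- nrow(X)
  is_ag <- X == 1L | X == 3L   # purines  (A=1, G=3)
  valid <- !is.na(X)
  Xv <- X; Xv[is.na(Xv)] <- 0L
  match_cnt <- matrix(0, n, n)
  for (b in 1:4) match_cnt <- match_cnt + tcrossprod((Xv == b) * 1)
  valid_cnt <- tcrossprod(valid * 1)
  ## purine in both & differing & both valid -> A<->G transition
  pur <- tcrossprod((is_ag & valid) * 1)
  pyr <- tcrossprod((!is_ag & valid) * 1)
  ag_match <- tcrossprod((Xv == 1L) * 1) + tcrossprod((Xv == 3L) * 1)
  ct_match <- tcrossprod((Xv == 2L) * 1) + tcrossprod((Xv == 4L) * 1)
  P1 <- pur - ag_match
  P2 <- pyr - ct_match
  Q <- valid_cnt - match_cnt - P1 - P2
  list(P1 = P1, P2 = P2, Q = Q, n = valid_cnt)
}

#' Pairwise genetic distance matrix
#'
#' Distances under `p` (proportion of differing sites), `K2P` (Kimura
#' two-parameter), `TN93` (Tamura-Nei, pair-specific base frequencies)
#' or `composite` — a TN93-form distance whose base frequencies are
#' estimated jointly from all sequences (the composite-likelihood style
#' used by common distance-tree software; exact numeric parity with any
#' particular program is not claimed).  Saturated pairs, where a
#' logarithm argument is non-positive, are set to `ceiling` and flagged
#' in the `saturated` attribute.
#'
#' @inheritParams polymorphic_sites
#' @param model `"p"`, `"K2P"`, `"TN93"` or `"composite"`.
#' @param ceiling distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with attributes `model` and
#'   `saturated` (logical matrix).
#' @export
distance_matrix <- function(a, model = c("p", "K2P", "TN93", "composite"),
                            missing_policy = c("exclude_site", "pairwise"),
                            ceiling = 5) {
  stopifnot(inherits(a, "mt_alignment"))
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  X <- .encode(a$seqs)
  if (missing_policy == "exclude_site")
    X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  if (ncol(X) == 0L) stop("no retained sites", call. = FALSE)
  if (nrow(X) < 2L) stop("need >= 2 sequences", call. = FALSE)
  cnt <- .pair_counts(X)
  nm <- rownames(a$seqs)
  sat <- matrix(FALSE, nrow(X), nrow(X), dimnames = list(nm, nm))
  safe_log <- function(w) { w[!is.na(w) & w <= 0] <- NA_real_; log(w) }
  with(cnt, {
    P1f <- P1 / pmax(n, 1); P2f <- P2 / pmax(n, 1); Qf <- Q / pmax(n, 1)
    d <- switch(model,
      p = P1f + P2f + Qf,
      K2P = {
        Pf <- P1f + P2f
        w1 <- safe_log(1 - 2 * Pf - Qf); w2 <- safe_log(1 - 2 * Qf)
        -0.5 * w1 - 0.25 * w2
      },
      TN93 = , composite = {
        if (model == "composite") {
          tab <- table(factor(X, levels = 1:4))
          pi_ <- as.numeric(tab) / sum(tab)
        } else pi_ <- NULL
        .tn93_dist(X, P1f, P2f, Qf, pi_, safe_log)
      })
    sat <<- is.na(d) & row(d) != col(d)
    d[is.na(d)] <- ceiling
    diag(d) <- 0
    d <- (d + t(d)) / 2
    dimnames(d) <- list(nm, nm)
    attr(d, "model") <- model
    attr(d, "saturated") <- sat
    d
  })
}

## TN93 distance; pi_ = NULL -> per-pair frequencies (classic TN93),
## pi_ given -> shared frequencies pooled over the whole alignment
.tn93_dist <- function(X, P1f, P2f, Qf, pi_, safe_log) {
  n <- nrow(X)
  if (is.null(pi_)) {
    ## per-pair base frequencies: average of the two sequences' freqs
    freq <- t(apply(X, 1L, function(r) {
      tab <- tabulate(r[!is.na(r)], 4L); tab / sum(tab)
    }))
    piA <- outer(freq[, 1], freq[, 1], "+") / 2
    piC <- outer(freq[, 2], freq[, 2], "+") / 2
    piG <- outer(freq[, 3], freq[, 3], "+") / 2
    piT <- outer(freq[, 4], freq[, 4], "+") / 2
  } else {
    piA <- matrix(pi_[1], n, n); piC <- matrix(pi_[2], n, n)
    piG <- matrix(pi_[3], n, n); piT <- matrix(pi_[4], n, n)
  }
  gR <- piA + piG; gY <- piC + piT
  k1 <- 2 * piA * piG / gR
  k2 <- 2 * piC * piT / gY
  k3 <- 2 * (gR * gY - piA * piG * gY / gR - piC * piT * gR / gY)
  w1 <- safe_log(1 - P1f / k1 - Qf / (2 * gR))
  w2 <- safe_log(1 - P2f / k2 - Qf / (2 * gY))
  w3 <- safe_log(1 - Qf / (2 * gR * gY))
  -k1 * w1 - k2 * w2 - k3 * w3
}
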