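#' Classical multidimensional scaling of a Phi_ST matrix
#'
#' Torgerson double-centering of the (clamped-at-zero) distance matrix
#' followed by an eigendecomposition; coordinates are taken on the top
#' `dims` positive-eigenvalue axes.  An iterative stress-majorization
#' (`"smacof"`) mode is available behind a flag for sensitivity checks;
#' it is seeded from the classical solution so it is deterministic.
#'
#' @param f an `mt_fst` object or a symmetric numeric matrix with zero
#'   diagonal.
#' @param dims number of output dimensions.
#' @param mode `"classical"` or `"smacof"`.
#' @param n_iter majorization iterations for `"smacof"`.
#' @return `mt_mds`: list with `populations`, `coords` (populations x
#'   dims, column-centered), `eigenvalues`, `stress` (Kruskal stress-1).
#' @export
mds_from_fst <- function(f, dims = 2L, mode = c("classical", "smacof"),
                         n_iter = 200L) {
  mode <- match.arg(mode)
  D <- if (inherits(f, "mt_fst")) f$fst else as.matrix(f)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  D <- pmax(D, 0)          # negative Phi_ST estimates clamped
  diag(D) <- 0
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- paste0("P", seq_len(n))
  dims <- min(dims, n - 1L)
  ## Torgerson: B = -1/2 J D^2 J
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  k <- min(dims, length(pos))
  if (k == 0L) {
    coords <- matrix(0, n, dims,
                     dimnames = list(rownames(D), paste0("Dim", seq_len(dims))))
    return(structure(list(populations = rownames(D), coords = coords,
                          eigenvalues = e$values, stress = 0),
                     class = "mt_mds"))
  }
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  if (k < dims) coords <- cbind(coords, matrix(0, n, dims - k))
  if (mode == "smacof") coords <- .smacof_refine(D, coords, n_iter)
  coords <- sweep(coords, 2L, colMeans(coords))
  dimnames(coords) <- list(rownames(D), paste0("Dim", seq_len(dims)))
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((D - dhat)[upper.tri(D)]^2)
  den <- sum(dhat[upper.tri(dhat)]^2)
  stress <- if (den > 0) sqrt(num / den) else 0
  structure(list(populations = rownames(D), coords = coords,
                 eigenvalues = e$values, stress = stress),
            class = "mt_mds")
}

## Guttman transform iterations (metric SMACOF)
.smacof_refine <- function(D, X, n_iter) {
  n <- nrow(D)
  for (it in seq_len(n_iter)) {
    dhat <- as.matrix(stats::dist(X))
    ratio <- ifelse(dhat > 1e-12, D / dhat, 0)
    Bz <- -ratio
    diag(Bz) <- 0
    diag(Bz) <- -rowSums(Bz)
    X_new <- Bz %*% X / n
    if (max(abs(X_new - X)) < 1e-12) { X <- X_new; break }
    X <- X_new
  }
  X
}

#' @export
print.mt_mds <- function(x, ...) {
  cat(sprintf("MDS of %d populations in %d dims (stress = %.4g)\n",
              length(x$populations), ncol(x$coords), x$stress))
  print(round(x$coords, 4))
  invisible(x)
}

#' Export MDS coordinates as TSV
#' @param m an `mt_mds`.
#' @param path output path.
#' @export
write_mds <- function(m, path) {
  stopifnot(inherits(m, "mt_mds"))
  utils::write.table(cbind(population = m$populations,
                           as.data.frame(m$coords)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
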