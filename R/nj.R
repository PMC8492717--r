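#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.  Ties
#' in Q are broken deterministically by choosing the candidate pair
#' whose (sorted) taxon-name pair is lexicographically smallest, so the
#' output is a pure function of the input matrix.  Negative branch
#' length estimates are clamped to zero in `edge.length`; the raw
#' estimates are kept in the `raw_edge_length` attribute.
#'
#' @param d symmetric distance matrix with taxon names, or the output of
#'   [distance_matrix()].
#' @return An [ape::as.phylo] `"phylo"` object (unrooted, basal
#'   trichotomy).
#' @export
nj_tree <- function(d) {
  D <- as.matrix(d)
  r <- nrow(D)
  if (r < 3L) stop("NJ needs >= 3 taxa", call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(r))
  tips <- rownames(D)
  n_tip <- r
  ## nodes carry a "representative name": for internal nodes, the
  ## lexicographically smallest descendant tip (used for tie-breaking)
  active_id <- seq_len(r)            # node ids
  active_nm <- tips
  next_id <- r + 1L
  edges <- matrix(0L, 0L, 2L); elen <- numeric(0)
  while (length(active_id) > 3L) {
    m <- length(active_id)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      nm <- sort(active_nm[ij]); paste(nm, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- D[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- dij - vi
    new_d <- (D[i, ] + D[j, ] - dij) / 2
    edges <- rbind(edges, c(next_id, active_id[i]), c(next_id, active_id[j]))
    elen <- c(elen, vi, vj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nm_new <- min(active_nm[c(i, j)])
    active_id <- c(active_id[keep], next_id)
    active_nm <- c(active_nm[keep], nm_new)
    rownames(D) <- colnames(D) <- active_nm
    next_id <- next_id + 1L
  }
  ## final trichotomy
  dij <- D
  v <- c((dij[1, 2] + dij[1, 3] - dij[2, 3]) / 2,
         (dij[1, 2] + dij[2, 3] - dij[1, 3]) / 2,
         (dij[1, 3] + dij[2, 3] - dij[1, 2]) / 2)
  root <- next_id
  edges <- rbind(edges, cbind(root, active_id))
  elen <- c(elen, v)
  .build_phylo(edges, elen, tips, n_tip, root)
}

## renumber an edge list into a valid "phylo": tips 1..n unchanged,
## internal ids compacted to n+1.. with the root first
.build_phylo <- function(edges, elen, tips, n_tip, root) {
  internal <- unique(edges[, 1L])
  internal <- c(root, setdiff(rev(internal), root))
  map <- integer(max(c(edges)))
  map[seq_len(n_tip)] <- seq_len(n_tip)
  map[internal] <- n_tip + seq_along(internal)
  tr <- structure(list(edge = cbind(map[edges[, 1L]], map[edges[, 2L]]),
                       edge.length = unname(pmax(elen, 0)),
                       tip.label = tips,
                       Nnode = length(internal)),
                  class = "phylo")
  ord <- ape::reorder.phylo(tr, "cladewise", index.only = TRUE)
  tr$edge <- tr$edge[ord, , drop = FALSE]
  tr$edge.length <- tr$edge.length[ord]
  attr(tr, "order") <- "cladewise"
  attr(tr, "raw_edge_length") <- unname(elen)[ord]
  tr
}

## canonical bipartition of each internal (non-root) node: the side of
## the split not containing tip 1, as a sorted index key
.bipartitions <- function(tr) {
  n <- length(tr$tip.label)
  desc <- .descendant_tips(tr)
  nodes <- (n + 2L):(n + tr$Nnode)   # skip the root
  if (tr$Nnode < 2L) return(list(keys = character(0), nodes = integer(0)))
  keys <- vapply(nodes, function(nd) {
    s <- desc[[nd]]
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    paste(sort(s), collapse = ",")
  }, "")
  keep <- vapply(nodes, function(nd) {
    k <- length(desc[[nd]]); k >= 2L && k <= n - 2L
  }, TRUE)
  list(keys = keys[keep], nodes = nodes[keep])
}

.descendant_tips <- function(tr) {
  n <- length(tr$tip.label)
  nnode <- n + tr$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  ## postorder: children before parents
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; c_ <- eo[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c_]])
  }
  desc
}

#' Bootstrap support on a neighbour-joining tree
#'
#' Resamples the retained alignment columns with replacement `B` times,
#' rebuilds the NJ tree for each replicate, and attaches to every
#' internal edge of the point-estimate tree the percentage of replicates
#' containing the same bipartition (stored as `node.label`).
#'
#' @inheritParams distance_matrix
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @return The point-estimate `"phylo"` tree with `node.label` holding
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(a, model = "K2P", B = 2000L, seed = 1L,
                              missing_policy = "exclude_site") {
  stopifnot(inherits(a, "mt_alignment"))
  if (B <= 0L) stop("B must be positive", call. = FALSE)
  if (length(a$sample_ids) < 4L) stop("need >= 4 taxa", call. = FALSE)
  keep <- .retained_sites(a$seqs, missing_policy)
  seqs <- a$seqs[, keep, drop = FALSE]
  point <- nj_tree(distance_matrix(a, model, missing_policy))
  bp <- .bipartitions(point)
  hits <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample(ncol(seqs), replace = TRUE)
    ab <- mt_alignment(seqs[, cols, drop = FALSE], a$labels)
    trb <- nj_tree(distance_matrix(ab, model, "pairwise"))
    kb <- .bipartitions(trb)$keys
    in_rep <- bp$keys %in% kb
    hits[in_rep] <- hits[in_rep] + 1
  }
  supp <- round(100 * hits / B, 1)
  labs <- character(point$Nnode)
  n <- length(point$tip.label)
  labs[bp$nodes - n] <- as.character(supp)
  point$node.label <- labs
  point
}

#' Assign samples to mtDNA lineages using labelled references
#'
#' Two methods: `"min_distance"` labels each sample with the lineage of
#' its nearest reference (p-distance over shared unambiguous sites) and
#' flags it ambiguous when the margin to the second-best lineage is
#' below `tolerance` differences; `"nj_clade"` builds a joint NJ tree of
#' samples plus references and assigns the lineage of the reference
#' clade the sample falls in, measured by patristic distance on the
#' tree (margins in approximate mutation units, `tolerance` applies).
#'
#' @param a samples, an [mt_alignment()].
#' @param refs reference haplotypes, an [mt_alignment()] of the same
#'   alignment length.
#' @param ref_lineages named character vector, reference sample id ->
#'   lineage label; defaults to the `breed` column of `refs`' metadata
#'   (the convention used by [generate_reference_fixture()]).
#' @param method `"min_distance"` or `"nj_clade"`.
#' @param tolerance minimum difference-count margin for an unambiguous
#'   `min_distance` call (1 = plain ties flagged).
#' @return `mt_lineage`: list with `assignment` (sample id -> label, or
#'   `NA` for ambiguous), `method`, `diagnostics` (data frame with the
#'   best/second-best lineages and margin).
#' @export
assign_lineage <- function(a, refs, ref_lineages = NULL,
                           method = c("min_distance", "nj_clade"),
                           tolerance = 1) {
  stopifnot(inherits(a, "mt_alignment"), inherits(refs, "mt_alignment"))
  method <- match.arg(method)
  if (a$L != refs$L)
    stop("samples and references must share the alignment length", call. = FALSE)
  if (is.null(ref_lineages))
    ref_lineages <- stats::setNames(refs$labels$breed, refs$sample_ids)
  ref_lineages <- ref_lineages[refs$sample_ids]
  if (anyNA(ref_lineages) || any(ref_lineages == ""))
    stop("every reference needs a lineage label", call. = FALSE)
  ## rename references internally so a sample may legitimately be one
  ## of the reference sequences itself
  ref_seqs <- refs$seqs
  ref_ids <- paste0("ref::", refs$sample_ids)
  rownames(ref_seqs) <- ref_ids
  ref_labels <- refs$labels
  ref_labels$sample_id <- ref_ids
  names(ref_lineages) <- ref_ids
  joint <- mt_alignment(
    rbind(a$seqs, ref_seqs),
    rbind(a$labels, ref_labels))
  if (method == "min_distance") {
    d <- pairwise_diff_matrix(joint, "pairwise")
    ds <- d[a$sample_ids, ref_ids, drop = FALSE]
    lins <- sort(unique(ref_lineages))
    per_lin <- sapply(lins, function(l)
      apply(ds[, ref_lineages == l, drop = FALSE], 1L, min))
    per_lin <- matrix(per_lin, nrow = length(a$sample_ids),
                      dimnames = list(a$sample_ids, lins))
    best <- apply(per_lin, 1L, which.min)
    ord2 <- apply(per_lin, 1L, function(r) sort(r)[2])
    margin <- ord2 - per_lin[cbind(seq_along(best), best)]
    lab <- lins[best]
    lab[margin < tolerance] <- NA_character_
    diag_df <- data.frame(sample_id = a$sample_ids, best = lins[best],
                          margin = margin, row.names = NULL)
  } else {
    ## clade membership on the joint NJ tree, operationalized as the
    ## patristic (through-tree) nearest reference: the long internal
    ## edges separating lineages dominate the path length, so a sample
    ## inherits the lineage of the reference clade it attaches within
    ## even when the clade itself is star-like
    tr <- nj_tree(distance_matrix(joint, "p", "pairwise"))
    pat <- ape::cophenetic.phylo(tr)
    ds <- pat[a$sample_ids, ref_ids, drop = FALSE] * joint$L
    lins <- sort(unique(ref_lineages))
    per_lin <- sapply(lins, function(l)
      apply(ds[, ref_lineages == l, drop = FALSE], 1L, min))
    per_lin <- matrix(per_lin, nrow = length(a$sample_ids),
                      dimnames = list(a$sample_ids, lins))
    best <- apply(per_lin, 1L, which.min)
    ord2 <- apply(per_lin, 1L, function(r) sort(r)[2])
    margin <- ord2 - per_lin[cbind(seq_along(best), best)]
    lab <- lins[best]
    lab[margin < tolerance] <- NA_character_
    diag_df <- data.frame(sample_id = a$sample_ids, best = lins[best],
                          margin = margin, row.names = NULL)
  }
  structure(list(assignment = stats::setNames(lab, a$sample_ids),
                 method = method, diagnostics = diag_df),
            class = "mt_lineage")
}

#' @export
print.mt_lineage <- function(x, ...) {
  tab <- table(x$assignment, useNA = "ifany")
  cat("lineage assignment (", x$method, "):\n", sep = "")
  print(tab)
  invisible(x)
}
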