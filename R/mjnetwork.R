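## ---- median-joining haplotype networks ------------------------------------

## union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
.uf_union <- function(uf, i, j) { uf[.uf_find(uf, i)] <- .uf_find(uf, j); uf }

.hamming_mat <- function(M) {
  ## M: node x site character matrix
  n <- nrow(M)
  d <- matrix(0L, n, n)
  if (ncol(M) == 0L || n < 2L) return(d)
  for (j in seq_len(ncol(M))) {
    cj <- M[, j]
    d <- d + (outer(cj, cj, "!=")) * 1L
  }
  d
}

## minimum-spanning network at tolerance epsilon: an edge (u,v) of
## weight w is feasible iff u and v are not already connected using only
## edges of weight < w - epsilon (epsilon = 0 gives the union of all
## minimum spanning trees)
.msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(cbind(from = integer(0), to = integer(0), weight = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  uf <- .uf_new(n)
  edges <- NULL
  for (lev in unique(w)) {
    at <- which(w == lev)
    ## components induced by edges with weight < lev - epsilon are
    ## frozen in `uf`; evaluate all pairs of this class against them
    sel <- at[vapply(at, function(k)
      .uf_find(uf, pairs[k, 1L]) != .uf_find(uf, pairs[k, 2L]), TRUE)]
    if (length(sel))
      edges <- rbind(edges, cbind(pairs[sel, , drop = FALSE], weight = w[sel]))
    ## merge components using every edge of weight <= lev - epsilon
    ## (for epsilon > 0 the freeze lags behind the current class)
    merge_at <- which(w <= lev - epsilon & w <= lev)
    for (k in merge_at) uf <- .uf_union(uf, pairs[k, 1L], pairs[k, 2L])
  }
  colnames(edges) <- c("from", "to", "weight")
  edges
}

## quasi-median candidates of a character triple: per-site majority;
## sites where all three states differ branch into all three choices
.triple_medians <- function(M3, max_branch_sites = 4L) {
  S <- ncol(M3)
  base <- character(S)
  branch <- integer(0)
  for (j in seq_len(S)) {
    u <- unique(M3[, j])
    if (length(u) == 1L) base[j] <- u[1]
    else if (length(u) == 2L) {
      tab <- table(M3[, j])
      base[j] <- names(tab)[which.max(tab)]
    } else branch <- c(branch, j)
  }
  if (length(branch) > max_branch_sites) return(NULL)
  if (length(branch) == 0L) return(matrix(base, nrow = 1L))
  combos <- expand.grid(rep(list(1:3), length(branch)))
  out <- matrix(rep(base, nrow(combos)), nrow = nrow(combos), byrow = TRUE)
  for (r in seq_len(nrow(combos)))
    for (bidx in seq_along(branch))
      out[r, branch[bidx]] <- M3[combos[r, bidx], branch[bidx]]
  out
}

#' Median-joining haplotype network
#'
#' The iterative median-joining procedure: build the minimum-spanning
#' network (all feasible links at tolerance `epsilon`), enumerate
#' quasi-median candidates over triples of nodes that are mutually close
#' in the current network, add the medians passing the connection-cost
#' criterion (cost within `epsilon` of the round's minimum), rebuild,
#' and repeat to a fixpoint; finally purge obsolete median vectors
#' (unlabelled nodes of degree <= 2).  All sites carry equal weight.
#'
#' @param h an `mt_haplotable` from [collapse_haplotypes()].
#' @param epsilon integer tolerance (0 = strict minimum-cost network).
#' @param max_median_rounds cap on median-addition rounds; hitting it
#'   sets the `converged` flag to `FALSE`.
#' @return `mt_network`: list with `node_seqs` (node x variable-site
#'   character matrix), `is_median` (logical), `counts` (node x
#'   population matrix, zero rows for medians), `edges` (data frame
#'   `from`, `to`, `weight`, `sites`), `converged`.
#' @export
median_joining <- function(h, epsilon = 0L, max_median_rounds = 10L) {
  stopifnot(inherits(h, "mt_haplotable"))
  if (length(h$haplotypes) < 2L) stop("need >= 2 haplotypes", call. = FALSE)
  full <- do.call(rbind, strsplit(h$haplotypes, ""))
  varsites <- which(apply(full, 2L, function(col) length(unique(col)) > 1L))
  M <- full[, varsites, drop = FALSE]
  ## canonical node order: observed haplotypes sorted by sequence string
  key0 <- apply(M, 1L, paste, collapse = "")
  ord <- order(key0)
  M <- M[ord, , drop = FALSE]
  obs_counts <- h$counts[ord, , drop = FALSE]
  n_obs <- nrow(M)
  is_median <- rep(FALSE, n_obs)
  converged <- TRUE
  for (round in seq_len(max_median_rounds)) {
    d <- .hamming_mat(M)
    ed <- .msn_edges(d, epsilon)
    adj <- matrix(FALSE, nrow(M), nrow(M))
    adj[ed[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    keys <- apply(M, 1L, paste, collapse = "")
    ## triples forming a connected path in the current network
    cand_list <- list(); cand_cost <- numeric(0)
    nn <- nrow(M)
    for (u in seq_len(nn)) {
      nb <- which(adj[u, ])
      if (length(nb) < 2L) next
      for (vi in seq_len(length(nb) - 1L)) for (wi in (vi + 1L):length(nb)) {
        v <- nb[vi]; w <- nb[wi]
        med <- .triple_medians(M[c(u, v, w), , drop = FALSE])
        if (is.null(med)) next
        for (r in seq_len(nrow(med))) {
          mk <- paste(med[r, ], collapse = "")
          if (mk %in% keys || mk %in% names(cand_list)) next
          cost <- sum(med[r, ] != M[u, ]) + sum(med[r, ] != M[v, ]) +
            sum(med[r, ] != M[w, ])
          cand_list[[mk]] <- med[r, ]
          cand_cost <- c(cand_cost, stats::setNames(cost, mk))
        }
      }
    }
    if (!length(cand_list)) break
    lambda <- min(cand_cost)
    accept <- names(cand_cost)[cand_cost <= lambda + epsilon]
    accept <- sort(accept)           # canonical tie-break
    if (!length(accept)) break
    add <- do.call(rbind, cand_list[accept])
    M <- rbind(M, add)
    obs_counts <- rbind(obs_counts,
                        matrix(0L, nrow(add), ncol(obs_counts)))
    is_median <- c(is_median, rep(TRUE, nrow(add)))
    if (round == max_median_rounds) converged <- FALSE
  }
  ## purge: unlabelled nodes of degree <= 2, iteratively, rebuilding the
  ## network after each sweep
  repeat {
    d <- .hamming_mat(M)
    ed <- .msn_edges(d, epsilon)
    deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = nrow(M))
    drop <- which(is_median & deg <= 2L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(M)), drop)
    M <- M[keep, , drop = FALSE]
    obs_counts <- obs_counts[keep, , drop = FALSE]
    is_median <- is_median[keep]
  }
  sites_str <- apply(ed, 1L, function(e) {
    diff <- which(M[e[1L], ] != M[e[2L], ])
    paste(varsites[diff] - 1L, collapse = ",")   # 0-based site indices
  })
  node_names <- ifelse(is_median,
                       paste0("mv", cumsum(is_median)),
                       paste0("H", cumsum(!is_median)))
  rownames(M) <- node_names
  rownames(obs_counts) <- node_names
  edges <- data.frame(from = node_names[ed[, 1L]],
                      to = node_names[ed[, 2L]],
                      weight = ed[, 3L], sites = sites_str,
                      stringsAsFactors = FALSE)
  structure(list(node_seqs = M, is_median = is_median,
                 counts = obs_counts, edges = edges,
                 var_sites = as.integer(varsites - 1L),
                 converged = converged),
            class = "mt_network")
}

#' @export
print.mt_network <- function(x, ...) {
  cat(sprintf("haplotype network: %d nodes (%d median vectors), %d edges%s\n",
              nrow(x$node_seqs), sum(x$is_median), nrow(x$edges),
              if (x$converged) "" else " [median search not converged]"))
  invisible(x)
}

#' Summarize a haplotype network
#'
#' @param net an `mt_network`.
#' @return List with `n_nodes`, `n_medians`, `n_singletons` (observed
#'   haplotypes of total count 1), `max_frequency`, and `star_index`
#'   (per node, the number of incident single-mutation edges — high for
#'   hubs of star-like expansions).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "mt_network"))
  tot <- rowSums(net$counts)
  nm <- rownames(net$node_seqs)
  star <- stats::setNames(numeric(length(nm)), nm)
  w1 <- net$edges[net$edges$weight == 1L, , drop = FALSE]
  for (e in seq_len(nrow(w1))) {
    star[w1$from[e]] <- star[w1$from[e]] + 1
    star[w1$to[e]] <- star[w1$to[e]] + 1
  }
  list(n_nodes = nrow(net$node_seqs),
       n_medians = sum(net$is_median),
       n_singletons = sum(!net$is_median & tot == 1),
       max_frequency = max(tot),
       star_index = star)
}

#' Export a network as a TSV edge list (+ node table)
#'
#' @param net an `mt_network`.
#' @param edge_path TSV path for `from to weight sites`.
#' @param node_path optional TSV for the per-population node counts
#'   (pie-chart ready).
#' @export
write_network <- function(net, edge_path, node_path = NULL) {
  stopifnot(inherits(net, "mt_network"))
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path)) {
    df <- data.frame(node = rownames(net$counts),
                     median = net$is_median, net$counts,
                     check.names = FALSE)
    utils::write.table(df, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}

#' Export a network as GML
#' @param net an `mt_network`.
#' @param path output path.
#' @export
write_network_gml <- function(net, path) {
  stopifnot(inherits(net, "mt_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = rownames(net$node_seqs),
                          median = net$is_median,
                          freq = rowSums(net$counts)))
  igraph::E(g)$weight <- net$edges$weight
  igraph::write_graph(g, path, format = "gml")
  invisible(net)
}
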