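#' Aligned sequence set with sample metadata
#'
#' An `mt_alignment` bundles an aligned character matrix (one row per
#' sample, one column per alignment site) with a metadata table mapping
#' each sample to a breed, a region and a metapopulation.  It is the
#' common input of every downstream analysis: diversity statistics,
#' AMOVA, trees, networks and ABC summary statistics.
#'
#' Sequences are stored upper-cased over the alphabet `A,C,G,T,-,N` plus
#' IUPAC ambiguity codes; ambiguity codes other than `N` are treated as
#' `N` by all site-filtering code.
#'
#' @param seqs character matrix of single characters, rows named by
#'   sample id, all rows the same length.
#' @param labels data frame with columns `sample_id`, `breed`, `region`,
#'   `metapopulation` (missing columns are filled with `""`); one row
#'   per sample.
#' @return An object of class `mt_alignment` with elements `sample_ids`,
#'   `labels`, `seqs` (character matrix) and `L` (alignment length).
#' @export
mt_alignment <- function(seqs, labels) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("`seqs` must be a character matrix", call. = FALSE)
  ids <- rownames(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("alignment error: rownames(seqs) must be unique sample ids",
         call. = FALSE)
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  for (col in c("breed", "region", "metapopulation"))
    if (is.null(labels[[col]])) labels[[col]] <- ""
  if (is.null(labels$sample_id))
    stop("metadata error: `labels` needs a sample_id column", call. = FALSE)
  miss <- setdiff(ids, labels$sample_id)
  if (length(miss))
    stop("metadata error: no metadata for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  labels <- labels[match(ids, labels$sample_id),
                   c("sample_id", "breed", "region", "metapopulation")]
  rownames(labels) <- NULL
  seqs[] <- toupper(seqs)
  structure(
    list(sample_ids = ids, labels = labels, seqs = seqs, L = ncol(seqs)),
    class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("mt_alignment: %d samples x %d bp; %d breed(s), %d metapopulation(s)\n",
              length(x$sample_ids), x$L,
              length(unique(x$labels$breed)),
              length(unique(x$labels$metapopulation))))
  invisible(x)
}

#' @export
`[.mt_alignment` <- function(x, i, ...) {
  sub <- x$seqs[i, , drop = FALSE]
  mt_alignment(sub, x$labels[x$labels$sample_id %in% rownames(sub), ])
}

#' Read an aligned FASTA plus sample metadata
#'
#' Records must all have the same length (the file is an alignment, not
#' raw reads).  Metadata is a tab-separated file with header
#' `sample_id  breed  region  metapopulation`; every FASTA id must have
#' a metadata row.  Bases are upper-cased on read.
#'
#' @param fasta_path path to the aligned FASTA.
#' @param metadata_path path to the metadata TSV.
#' @return An [mt_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("alignment error: empty FASTA", call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("alignment error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  m <- toupper(as.character(as.matrix(dna)))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  mt_alignment(m, meta)
}

#' Write an alignment as FASTA + metadata TSV
#'
#' @param a an [mt_alignment()].
#' @param fasta_path,metadata_path output paths.
#' @return `a`, invisibly.
#' @export
write_alignment <- function(a, fasta_path, metadata_path = NULL) {
  stopifnot(inherits(a, "mt_alignment"))
  lines <- character(2L * length(a$sample_ids))
  lines[c(TRUE, FALSE)] <- paste0(">", a$sample_ids)
  lines[c(FALSE, TRUE)] <- apply(a$seqs, 1L, paste, collapse = "")
  writeLines(lines, fasta_path)
  if (!is.null(metadata_path))
    utils::write.table(a$labels, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(a)
}

## sites free of gaps / N / ambiguity in every sample (0-based semantics
## live at the interface; internally R is 1-based)
.clean_sites <- function(seqs) {
  which(apply(seqs, 2L, function(col) all(col %in% c("A", "C", "G", "T"))))
}

.retained_sites <- function(seqs, missing_policy = c("exclude_site", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  if (missing_policy == "exclude_site") .clean_sites(seqs) else seq_len(ncol(seqs))
}

#' Locate polymorphic sites
#'
#' Returns the 0-based column indices at which at least two distinct
#' unambiguous bases occur.  Under `exclude_site` (the default policy),
#' any column containing `-`, `N` or an ambiguity code in any sample is
#' dropped before scanning; under `pairwise`, ambiguous characters are
#' ignored within each column but the column is kept.
#'
#' @param a an [mt_alignment()].
#' @param missing_policy `"exclude_site"` or `"pairwise"`.
#' @return Integer vector of 0-based site indices.
#' @export
polymorphic_sites <- function(a, missing_policy = c("exclude_site", "pairwise")) {
  stopifnot(inherits(a, "mt_alignment"))
  missing_policy <- match.arg(missing_policy)
  if (length(a$sample_ids) == 0L) stop("empty alignment", call. = FALSE)
  cols <- .retained_sites(a$seqs, missing_policy)
  poly <- cols[vapply(cols, function(j) {
    b <- a$seqs[, j]
    length(unique(b[b %in% c("A", "C", "G", "T")])) >= 2L
  }, logical(1))]
  as.integer(poly - 1L)
}

#' Collapse an alignment into a haplotype table
#'
#' Samples identical over the retained sites share a haplotype.  Counts
#' are tabulated at the requested population level.  The retained sites
#' are those surviving `missing_policy` (complete-deletion by default,
#' which is how published haplotype counts from Arlequin-style workflows
#' are produced).
#'
#' @inheritParams polymorphic_sites
#' @param pop_level `"breed"`, `"region"` or `"metapopulation"`.
#' @return An object of class `mt_haplotable`: list with `haplotypes`
#'   (character vector of retained-site strings), `counts` (haplotype x
#'   population integer matrix), `assignment` (named integer vector,
#'   sample id -> haplotype index), `retained_sites` (0-based).
#' @export
collapse_haplotypes <- function(a,
                                missing_policy = c("exclude_site", "pairwise"),
                                pop_level = c("breed", "region", "metapopulation")) {
  stopifnot(inherits(a, "mt_alignment"))
  missing_policy <- match.arg(missing_policy)
  pop_level <- match.arg(pop_level)
  if (length(a$sample_ids) < 1L) stop("empty alignment", call. = FALSE)
  keep <- .retained_sites(a$seqs, missing_policy)
  if (length(keep) == 0L)
    stop("all ", ncol(a$seqs), " sites removed by missing_policy='",
         missing_policy, "' (every column has a gap/N/ambiguity)",
         call. = FALSE)
  strs <- apply(a$seqs[, keep, drop = FALSE], 1L, paste, collapse = "")
  haps <- unique(strs)
  idx <- match(strs, haps)
  pops <- a$labels[[pop_level]]
  pop_names <- unique(pops)
  counts <- matrix(0L, nrow = length(haps), ncol = length(pop_names),
                   dimnames = list(paste0("H", seq_along(haps)), pop_names))
  for (i in seq_along(idx))
    counts[idx[i], pops[i]] <- counts[idx[i], pops[i]] + 1L
  structure(
    list(haplotypes = haps,
         counts = counts,
         assignment = stats::setNames(idx, a$sample_ids),
         retained_sites = as.integer(keep - 1L),
         pop_level = pop_level),
    class = "mt_haplotable")
}

#' @export
print.mt_haplotable <- function(x, ...) {
  cat(sprintf("mt_haplotable: %d haplotypes over %d retained sites; %d population(s) [%s]\n",
              length(x$haplotypes), length(x$retained_sites),
              ncol(x$counts), x$pop_level))
  invisible(x)
}

#' Export a haplotype table as TSV
#'
#' One row per haplotype with its per-population counts and total.
#'
#' @param h an `mt_haplotable`.
#' @param path output TSV path.
#' @export
write_haplotable <- function(h, path) {
  stopifnot(inherits(h, "mt_haplotable"))
  df <- data.frame(haplotype = rownames(h$counts), h$counts,
                   total = rowSums(h$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(h)
}

#' Extract an alignment window
#'
#' Coordinates are 0-based half-open, matching the internal convention.
#'
#' @param a an [mt_alignment()].
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @return A new [mt_alignment()] of length `end - start`.
#' @export
extract_window <- function(a, start, end) {
  stopifnot(inherits(a, "mt_alignment"))
  if (start < 0L || end > a$L || start >= end)
    stop("window [", start, ", ", end, ") out of range for alignment of length ",
         a$L, call. = FALSE)
  mt_alignment(a$seqs[, (start + 1L):end, drop = FALSE], a$labels)
}
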