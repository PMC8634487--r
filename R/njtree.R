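## njtree: distance-based neighbor-joining trees with bootstrap support and
## low-support collapsing.  Classical NJ and distances are delegated to ape
## behind this module surface; negative-branch clamping, seeded column
## bootstrap, bipartition support and support-based collapsing are added
## here.

aln_to_dnabin <- function(aln) {
  aln <- as_region_alignment(aln)
  m <- do.call(rbind, lapply(aln, function(s) dna_chars(tolower(s))))
  rownames(m) <- names(aln)
  ape::as.DNAbin(m)
}

#' Distance matrix for a region alignment
#'
#' p-distance (`"p"`) or Jukes-Cantor (`"JC"`), both with pairwise deletion
#' of gap-containing columns.
#'
#' @param aln region alignment.
#' @param distance `"p"` or `"JC"`.
#' @return a `dist` object.
#' @export
alignment_distances <- function(aln, distance = c("p", "JC")) {
  distance <- match.arg(distance)
  bin <- aln_to_dnabin(aln)
  model <- if (distance == "p") "raw" else "JC69"
  ape::dist.dna(bin, model = model, pairwise.deletion = TRUE)
}

## clamp negative NJ branch lengths to zero, transferring the deficit to the
## sibling edge so that path lengths are preserved where possible
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
    if (length(sib) > 0) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
    }
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ with negative branch lengths clamped to zero (deficit moved
#' to the sibling edge).
#'
#' @param d `dist` or symmetric matrix (>= 3 taxa).
#' @return an unrooted `phylo`.
#' @export
nj_from_distances <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  assert_that(attr(d, "Size") >= 3, "need at least 3 members for NJ")
  clamp_negative_branches(ape::nj(d))
}

#' Build a neighbor-joining tree from a region alignment
#'
#' @param aln region alignment (>= 3 members).
#' @param distance `"p"` or `"JC"` (pairwise gap deletion).
#' @return an unrooted `phylo` with non-negative branch lengths.
#' @export
build_nj_tree <- function(aln, distance = c("p", "JC")) {
  distance <- match.arg(distance)
  aln <- as_region_alignment(aln)
  assert_that(length(aln) >= 3, "need at least 3 members for NJ")
  nj_from_distances(alignment_distances(aln, distance))
}

#' Bootstrap support for a neighbor-joining tree, with collapsing
#'
#' Alignment columns are resampled with replacement `replicates` times; the
#' support of each internal edge is the percentage of replicate NJ trees
#' containing the same bipartition.  Internal edges with support below
#' `collapse_below` are collapsed into polytomies.  Fully seeded and
#' reproducible.
#'
#' @param aln region alignment (>= 4 members for meaningful bipartitions).
#' @param replicates bootstrap replicates (>= 1; the study setting is 500).
#' @param collapse_below collapse internal edges with support below this
#'   percentage (default 50; 0 collapses nothing).
#' @param seed integer seed.
#' @param distance `"p"` or `"JC"`.
#' @return a `phylo`; `node.label` holds the support percentages of the
#'   retained internal nodes (root NA).
#' @export
bootstrap_support <- function(aln, replicates = 500L, collapse_below = 50,
                              seed = 1L, distance = c("p", "JC")) {
  distance <- match.arg(distance)
  aln <- as_region_alignment(aln)
  assert_that(replicates >= 1, "replicates must be >= 1")
  ref <- build_nj_tree(aln, distance)
  ncol_aln <- nchar(aln[[1]])
  chars <- do.call(rbind, lapply(aln, dna_chars))
  rownames(chars) <- names(aln)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      res <- apply(chars[, idx, drop = FALSE], 1, paste, collapse = "")
      tryCatch(build_nj_tree(res, distance), error = function(e) NULL)
    })
  })
  boot_trees <- Filter(Negate(is.null), boot_trees)
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(boot_trees)
  support[1] <- NA_real_                       # root pseudo-node
  ref$node.label <- round(support, 1)
  collapse_low_support(ref, collapse_below)
}

## collapse internal edges whose child-node support is below `threshold`
collapse_low_support <- function(tree, threshold) {
  if (is.null(tree$node.label) || threshold <= 0) return(tree)
  support <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  internal_edge <- child > ntip
  node_support <- support[child[internal_edge] - ntip]
  to_collapse <- which(internal_edge)[!is.na(node_support) &
                                        node_support < threshold]
  if (length(to_collapse) == 0L) return(tree)
  marked <- tree
  marked$edge.length[to_collapse] <- -1
  out <- ape::di2multi(marked, tol = -0.5)
  out
}

#' Extract the bipartitions (splits) of an unrooted tree
#'
#' @param tree a `phylo`.
#' @return list of character vectors: for each internal edge, the smaller
#'   side of the split (taxa names, sorted).
#' @export
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- lapply(parts, function(p) sort(labs[p]))
  all_t <- sort(labs)
  norm <- lapply(out, function(side) {
    other <- setdiff(all_t, side)
    if (length(other) < length(side) ||
        (length(other) == length(side) &&
         paste(other, collapse = ",") < paste(side, collapse = ","))) {
      other
    } else side
  })
  unique(norm[vapply(norm, length, integer(1)) >= 2])
}

#' Test whether a tree contains a given bipartition
#'
#' @param tree a `phylo`.
#' @param group character vector of taxa forming one side of the split.
#' @return logical.
#' @export
has_bipartition <- function(tree, group) {
  group <- sort(group)
  all_t <- sort(tree$tip.label)
  other <- setdiff(all_t, group)
  target <- if (length(other) < length(group) ||
                (length(other) == length(group) &&
                 paste(other, collapse = ",") < paste(group, collapse = ","))) {
    other
  } else group
  any(vapply(tree_bipartitions(tree), identical, logical(1), y = target))
}
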