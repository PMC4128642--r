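#' Pairwise percent identity of aligned sequences
#'
#' `100 * matches / comparable`, where comparable columns are those in
#' which neither sequence has a gap (terminal gaps are treated like
#' internal gaps). The value is returned unrounded; round at the reporting
#' layer.
#'
#' @param a,b [aq_record()] objects of equal length
#' @return percent identity in `[0, 100]`
#' @examples
#' x <- aq_record("x", strrep("A", 251))
#' y <- aq_record("y", paste0(strrep("A", 250), "G"))
#' percent_identity(x, y)   # 99.6016
#' @export
percent_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb))
    stop("sequences differ in length (", length(ca), " vs ", length(cb),
         "); align them first")
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable))
    stop("no comparable (gap-free in both) columns between '", a$id,
         "' and '", b$id, "'")
  100 * sum(ca[comparable] == cb[comparable]) / sum(comparable)
}

#' Pairwise p-distance matrix of an aligned set
#'
#' `d(i, j) = 1 - identity_fraction(i, j)` over pairwise comparable
#' (gap-free in both) columns; symmetric with zero diagonal.
#'
#' @param records list of equal-length [aq_record()] objects, n >= 3
#' @return a symmetric numeric matrix with record ids as dimnames
#' @export
p_distance_matrix <- function(records) {
  n <- length(records)
  if (n < 3) stop("need at least 3 records for a distance matrix")
  ids <- vapply(records, `[[`, character(1), "id")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - percent_identity(records[[i]],
                                               records[[j]]) / 100
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero with a message. Optional bootstrap: the
#' alignment columns are resampled `bootstrap` times, a tree is rebuilt
#' from each resampled p-distance matrix, and per-split support
#' percentages are attached as node labels.
#'
#' @param d symmetric distance matrix (e.g. [p_distance_matrix()])
#' @param records the aligned records; required when `bootstrap > 0`
#' @param bootstrap number of bootstrap replicates (0 = none)
#' @param seed integer seed for the bootstrap resampling
#' @return an \pkg{ape} `phylo` object (write with [tree_newick()])
#' @export
nj_tree <- function(d, records = NULL, bootstrap = 0, seed = NULL) {
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative branch length(s) clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (bootstrap > 0) {
    if (is.null(records))
      stop("'records' are required for bootstrap resampling")
    if (!is.null(seed)) set.seed(seed)
    mats <- lapply(records, seq_chars)
    len <- unique(vapply(mats, length, integer(1)))
    if (length(len) != 1) stop("records must be aligned to equal length")
    ids <- vapply(records, `[[`, character(1), "id")
    boot_trees <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(len, len, replace = TRUE)
      res <- mapply(function(ch, id)
        aq_record(id, paste(ch[cols], collapse = ""), aligned = TRUE),
        mats, ids, SIMPLIFY = FALSE)
      boot_trees[[b]] <- ape::nj(as.dist(p_distance_matrix(res)))
    }
    support <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    support[is.na(support)] <- 0
    tree$node.label <- round(100 * support / bootstrap)
  }
  tree
}

#' Newick string of a tree
#' @param tree a `phylo` object
#' @return single Newick string
#' @export
tree_newick <- function(tree) ape::write.tree(tree)
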