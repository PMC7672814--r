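#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `(m-2) d_ij - r_i - r_j` is merged, with deterministic
#' tie-breaking (the lexicographically smallest index pair), and the merged
#' node's distances follow the standard reduction.  Negative estimated
#' branch lengths are clamped to 0 with the deficit transferred to the
#' sibling edge, so the pair's path length is preserved.  The result is an
#' unrooted tree stored with a trifurcating root, as `phylip`-style tools
#' expect.
#'
#' @param m an `acs_dist` (or a symmetric numeric matrix with dimnames) over
#'   `n >= 3` taxa; asymmetry beyond `1e-9` is an error.
#' @return an [ape::phylo] tree with branch lengths.
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(m) {
  if (is.matrix(m)) m <- new_acs_dist(rownames(m), m)
  stopifnot(inherits(m, "acs_dist"))
  D <- m$values
  labs <- quote_newick_label(m$names)
  n <- length(labs)
  if (n < 3) stop("phylo: neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9)
    stop("phylo: distance matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  D <- (D + t(D)) / 2
  frag <- labs
  while (length(frag) > 3) {
    mact <- length(frag)
    r <- rowSums(D)
    best <- c(NA, NA); bestq <- Inf
    for (i in 1:(mact - 1)) {
      for (j in (i + 1):mact) {
        q <- (mact - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (mact - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(mact), c(i, j))
    D2 <- matrix(0, mact - 1, mact - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
    D2[mact - 1, seq_along(keep)] <- dk[keep]
    D2[seq_along(keep), mact - 1] <- dk[keep]
    D <- D2
    frag <- c(frag[keep], newfrag)
  }
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], b1, frag[2], b2,
                 frag[3], b3)
  read_newick(nwk)
}

quote_newick_label <- function(x) {
  needs <- grepl("[][ ,:;()']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", substr(x[quoted], 2, nchar(x[quoted]) - 1))
  x
}

#' Serialize a tree as a Newick string
#'
#' Labels containing Newick metacharacters (spaces, commas, ...) are
#' single-quoted.  Branch lengths survive a round trip to 6 decimals and
#' the string is semicolon-terminated.
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file to write the string to.
#' @return the Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  rec <- function(node) {
    edges <- kids[[as.character(node)]]
    if (is.null(edges)) return(quote_newick_label(tree$tip.label[node]))
    parts <- vapply(edges, function(e) {
      sub <- rec(tree$edge[e, 2])
      if (is.null(bl)) sub else sprintf("%s:%.10g", sub, bl[e])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick tree
#'
#' @param x a file path or a Newick string.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(x) {
  tr <- tryCatch({
    if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) ape::read.tree(x)
    else ape::read.tree(text = x)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("phylo: malformed Newick input", call. = FALSE)
  tr$tip.label <- unquote_newick_label(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("phylo: duplicate leaf label '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1]), call. = FALSE)
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference between the nontrivial bipartition sets
#' of two trees over the same leaves (the `treedist` convention: raw count,
#' not normalized, not halved).  0 means the topologies match exactly.
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf label sets.
#' @return integer RF distance.
#' @examples
#' a <- read_newick("((A,B),(C,D),E);")
#' b <- read_newick("((A,C),(B,D),E);")
#' robinson_foulds(a, b)  # 4
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) > 0 || length(only2) > 0)
    stop(sprintf("phylo: leaf sets differ (only in first: %s; only in second: %s)",
                 paste(only1, collapse = ","), paste(only2, collapse = ",")),
         call. = FALSE)
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}
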