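## Distances, neighbor-joining, bootstrap support, newick, tree comparison.
## Trees are ape "phylo" objects; gapped columns are deleted pairwise (not
## list-wise) when computing distances, since these elements differ mostly by
## indel-rich acquired regions.

#' p-distance of an aligned pair
#'
#' Proportion of differing residues over gap-free columns
#' (1 - [identity_excluding_indels()]).
#'
#' @param pair An `aligned_pair` (or gapped row with `b_row`).
#' @param b_row Second row when `pair` is a string.
#' @return Fraction in \[0, 1\].
#' @export
p_distance <- function(pair, b_row = NULL) {
  1 - identity_excluding_indels(pair, b_row)
}

#' Tamura-Nei (1993) distance of an aligned pair
#'
#' Closed-form TN93 distance from the proportions of purine transitions,
#' pyrimidine transitions and transversions over gap-free columns, with base
#' frequencies estimated from the pair. Saturated pairs (a logarithm of a
#' non-positive argument) raise an error.
#'
#' @inheritParams p_distance
#' @return Non-negative distance in substitutions per site.
#' @export
tn93_distance <- function(pair, b_row = NULL) {
  if (inherits(pair, "aligned_pair")) { ra <- pair$a_row; rb <- pair$b_row }
  else { ra <- toupper(pair); rb <- toupper(b_row) }
  if (nchar(ra) != nchar(rb)) stop("rows differ in length")
  ca <- strsplit(ra, "", fixed = TRUE)[[1]]
  cb <- strsplit(rb, "", fixed = TRUE)[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable columns")
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  f <- table(factor(c(ca, cb), levels = c("A", "C", "G", "T"))) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  P1 <- mean((ca == "A" & cb == "G") | (ca == "G" & cb == "A"))  # purine ts
  P2 <- mean((ca == "C" & cb == "T") | (ca == "T" & cb == "C"))  # pyrimidine ts
  Q <- mean(diff) - P1 - P2                                       # transversions
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("saturated: TN93 distance undefined for this pair")
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  max(d, 0)
}

#' Distance matrix from a multiple alignment
#'
#' Pairwise deletion of gapped columns; `model = "p"` gives raw proportion
#' distances, `model = "tn93"` the Tamura-Nei correction.
#'
#' @param msa An `msa` object.
#' @param model `"p"` or `"tn93"`.
#' @return Symmetric matrix with the alignment ids as dimnames.
#' @export
msa_distance_matrix <- function(msa, model = c("p", "tn93")) {
  model <- match.arg(model)
  rows <- strsplit(unname(msa$rows), "", fixed = TRUE)
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ra <- rows[[i]]; rb <- rows[[j]]
    D[i, j] <- D[j, i] <- if (model == "p") {
      keep <- ra != "-" & rb != "-"
      if (!any(keep)) stop("no gap-free columns between ",
                           msa$ids[i], " and ", msa$ids[j])
      mean(ra[keep] != rb[keep])
    } else {
      tn93_distance(paste(ra, collapse = ""), paste(rb, collapse = ""))
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Negative branch
#' lengths are clamped to zero with the deficit moved to the sister edge.
#' Ties in the Q matrix break deterministically by label order. Recovers any
#' additive distance matrix exactly.
#'
#' @param D Symmetric distance matrix with labelled dimnames (n >= 3).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- colnames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix not symmetric")
  nodes <- as.list(labels)      # newick fragment per active cluster
  d <- D
  act <- seq_len(n)
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(d)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * d[i, j] - r[i] - r[j]
      if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newdist <- (d[i, ] + d[j, ] - d[i, j]) / 2
    frag <- sprintf("(%s:%.17g,%s:%.17g)", nodes[[i]], li, nodes[[j]], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nodes <- c(nodes[keep], frag)
    act <- act[-1]               # bookkeeping of the active count only
  }
  ## final three clusters joined at an unrooted trifurcation
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 nodes[[1]], la, nodes[[2]], lb, nodes[[3]], lc)
  ape::read.tree(text = nwk)
}

## Canonical non-trivial bipartitions of an unrooted phylo tree, as
## "|"-joined sorted label strings of the side not containing the reference
## (alphabetically first) label.
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- tree$tip.label[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement `n_reps` times;
#' each replicate alignment is converted to a distance matrix and a tree by
#' `tree_builder`. The support of each internal bipartition of the
#' point-estimate tree is the percentage of replicate trees containing it.
#'
#' @param msa An `msa` object.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the run is reproducible for a fixed seed.
#' @param model Distance model, see [msa_distance_matrix()].
#' @param tree_builder Function from distance matrix to `phylo`
#'   (default [neighbor_joining()]).
#' @return The point-estimate `phylo` with a numeric `bootstrap` attribute
#'   (support per internal bipartition) and `node.label` carrying supports.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L, model = "p",
                              tree_builder = neighbor_joining) {
  stopifnot(inherits(msa, "msa"))
  point <- tree_builder(msa_distance_matrix(msa, model))
  splits <- bipartitions(point)
  counts <- stats::setNames(numeric(length(splits)), splits)
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  rownames(mat) <- msa$ids
  L <- ncol(mat)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- mat[, idx, drop = FALSE]
    Db <- char_matrix_pdist(sub)
    tb <- tree_builder(Db)
    hits <- intersect(bipartitions(tb), splits)
    counts[hits] <- counts[hits] + 1
  }
  support <- 100 * counts / n_reps
  attr(point, "bootstrap") <- support
  point <- annotate_supports(point, support)
  point
}

char_matrix_pdist <- function(mat) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(keep)) stop("no gap-free columns in bootstrap replicate")
    D[i, j] <- D[j, i] <- mean(mat[i, keep] != mat[j, keep])
  }
  D
}

## Attach per-internal-node labels matching the bipartition supports.
annotate_supports <- function(tree, support) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  nt <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  pp <- ape::prop.part(tree)
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) labs[k] <- format(support[[key]])
  }
  tree$node.label <- labs
  tree
}

#' Serialise a tree to newick
#'
#' Branch lengths are written; bootstrap supports below `support_threshold`
#' are omitted, others appear as internal node labels.
#'
#' @param tree A `phylo`, typically from [bootstrap_support()].
#' @param support_threshold Hide supports below this percentage (default 50).
#' @param digits Branch-length digits.
#' @return A newick string.
#' @export
to_newick <- function(tree, support_threshold = 50, digits = 10) {
  t2 <- tree
  if (!is.null(t2$node.label)) {
    vals <- suppressWarnings(as.numeric(t2$node.label))
    t2$node.label <- ifelse(!is.na(vals) & vals < support_threshold, "",
                            t2$node.label)
  }
  ape::write.tree(t2, digits = digits)
}
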