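# Neighbor-joining tree construction for domain-family clustering.
#
# Hand-written NJ rather than a wrapper so that the contract is explicit:
# deterministic tie-breaking by leaf label, and negative branch lengths
# clamped to zero with the deficit moved to the sibling branch (total length
# of the joined pair is preserved). Trees are returned as ape "phylo"
# objects; the root is the usual unrooted trifurcation.

#' Build a neighbor-joining tree from a distance matrix
#'
#' Standard NJ: iteratively join the pair (i, j) minimising
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` where `R_i` is the row sum over the
#' r active nodes; branch lengths from the usual closed form
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2 (r - 2))`. Ties in Q break to the pair
#' with the lexicographically smallest (smaller label, larger label), where
#' an internal node carries the smallest leaf label beneath it. Negative
#' branch lengths are clamped to 0 and the deficit added to the sibling
#' branch.
#'
#' @param d symmetric numeric matrix of distances with identical row/column
#'   names (the leaf ids); at least 3 leaves.
#' @return an unrooted `phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  ids <- rownames(d)
  if (is.null(ids) || !identical(ids, colnames(d)) || anyDuplicated(ids)) {
    stop("d must have identical, unique row and column names")
  }
  if (nrow(d) < 3) stop("neighbor joining requires at least 3 leaves")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")

  labels <- ids                       # tie-break label per active node
  newick <- ids                       # growing subtree strings
  dm <- d
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(dm) > 3) {
    r <- nrow(dm)
    R <- rowSums(dm)
    Q <- (r - 2) * dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(labels[cand[, 1]], labels[cand[, 2]])
    hi <- pmax(labels[cand[, 1]], labels[cand[, 2]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    dij <- dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    new_nwk <- paste0("(", newick[i], ":", fmt(li), ",",
                      newick[j], ":", fmt(lj), ")")
    new_lab <- min(labels[i], labels[j])
    du <- (dm[i, ] + dm[j, ] - dij) / 2

    keep <- setdiff(seq_len(r), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    labels <- c(labels[keep], new_lab)
    newick <- c(newick[keep], new_nwk)
    rownames(dm2) <- colnames(dm2) <- labels
    dm <- dm2
  }

  # final trifurcation, 3-taxon closed form
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- paste0("(", newick[1], ":", fmt(la), ",",
                newick[2], ":", fmt(lb), ",",
                newick[3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

#' Assign family labels to tree leaves from labelled anchors
#'
#' Every unlabelled leaf receives the family label of the anchor leaf with the
#' minimum path-length (sum of branch lengths) distance in the tree; ties
#' break to the smallest anchor id.
#'
#' @param tree a `phylo` tree.
#' @param anchors named character vector: names are anchor leaf ids, values
#'   family labels.
#' @return named character vector mapping every leaf id to a family label.
#' @export
assign_families <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"))
  if (length(anchors) == 0) stop("anchors must be non-empty")
  missing <- setdiff(names(anchors), tree$tip.label)
  if (length(missing) > 0) {
    stop("anchor leaves not in tree: ", paste(missing, collapse = ", "))
  }
  pd <- ape::cophenetic.phylo(tree)
  anchor_ids <- sort(names(anchors))
  out <- vapply(tree$tip.label, function(leaf) {
    if (leaf %in% names(anchors)) return(unname(anchors[[leaf]]))
    dists <- pd[leaf, anchor_ids]
    unname(anchors[[anchor_ids[which.min(dists)]]])
  }, character(1))
  stats::setNames(out, tree$tip.label)
}

#' Cluster domain sequences into a family tree
#'
#' Convenience wrapper over [p_distance_matrix()] and [nj_tree()]; optionally
#' assigns family labels from anchors and writes Newick / TSV outputs.
#'
#' @param seqs named character vector of domain sequences.
#' @param anchors optional named character vector of family anchors.
#' @param params alignment scoring parameters.
#' @param out_prefix optional path prefix: writes `<prefix>.nwk`,
#'   `<prefix>.dist.tsv` and (with anchors) `<prefix>.families.tsv`.
#' @return list with `tree` (phylo), `dist` (matrix), and `families`
#'   (named vector or NULL).
#' @export
build_domain_tree <- function(seqs, anchors = NULL, params = align_params(),
                              out_prefix = NULL) {
  d <- p_distance_matrix(seqs, params = params)
  tree <- nj_tree(d)
  fams <- if (!is.null(anchors)) assign_families(tree, anchors) else NULL
  if (!is.null(out_prefix)) {
    ape::write.tree(tree, paste0(out_prefix, ".nwk"))
    dd <- data.frame(id = rownames(d), d, check.names = FALSE)
    write_tsv(dd, paste0(out_prefix, ".dist.tsv"),
              comment = "pairwise p-distances")
    if (!is.null(fams)) {
      write_tsv(data.frame(leaf_id = names(fams), family = unname(fams)),
                paste0(out_prefix, ".families.tsv"),
                comment = "nearest-anchor family assignment")
    }
  }
  list(tree = tree, dist = d, families = fams)
}
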