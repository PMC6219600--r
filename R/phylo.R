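# Pearson correlation distance d = 100(1 - r) over SNP score vectors and
# UPGMA (average-linkage) clustering with a declared, reproducible tie
# rule, serializable to Newick.

#' Correlation distance matrix over samples
#'
#' Pearson's r between the raw 0/1/2 score vectors of each sample pair,
#' transformed to the distance scale `d = 100 * (1 - r)` (0 for identical
#' profiles, 200 for perfect anti-correlation).
#'
#' @param x a `snp_matrix` (a `marker_matrix` is also accepted).
#' @param samples subset of sample ids; default all.
#' @param pairwise_policy `"pairwise"` (default): r per pair over the
#'   markers non-missing in both; `"listwise"`: only markers non-missing
#'   in every sample enter any pair.
#' @return a `corr_dist`: list with `d` (distance matrix), `r` (the raw
#'   correlations, retained for audit) and `labels`.
#' @export
correlation_distance <- function(x, samples = NULL,
                                 pairwise_policy = c("pairwise", "listwise")) {
  pairwise_policy <- match.arg(pairwise_policy)
  stopifnot(inherits(x, "dart_matrix"))
  samples <- samples %||% colnames(x$scores)
  if (length(samples) < 2L) stop_ctx("need at least 2 samples")
  miss <- setdiff(samples, colnames(x$scores))
  if (length(miss)) stop_ctx("unknown sample(s): %s", paste(miss, collapse = ", "))
  sc <- x$scores[, samples, drop = FALSE]
  obs <- !is.na(sc)
  overlap <- crossprod(obs)           # shared non-missing markers per pair
  short <- which(overlap < 2 & upper.tri(overlap), arr.ind = TRUE)
  if (nrow(short))
    stop_ctx("samples \"%s\" and \"%s\" share only %d marker(s) with calls in both (need >= 2)",
             samples[short[1, 1]], samples[short[1, 2]],
             overlap[short[1, 1], short[1, 2]])
  use <- if (pairwise_policy == "pairwise") "pairwise.complete.obs" else "complete.obs"
  r <- suppressWarnings(cor(sc, use = use, method = "pearson"))
  if (anyNA(r)) {
    bad <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
    stop_ctx("Pearson r undefined for samples \"%s\" and \"%s\" (constant score vector over their shared markers)",
             samples[bad[1, 1]], samples[bad[1, 2]])
  }
  d <- 100 * (1 - r)
  diag(d) <- 0
  structure(list(d = d, r = r, labels = samples), class = "corr_dist")
}

#' @export
print.corr_dist <- function(x, ...) {
  cat(sprintf("<corr_dist> %d samples, d = 100(1 - r), range [%.2f, %.2f]\n",
              length(x$labels), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Write a distance matrix as square CSV
#'
#' @param dm a `corr_dist` or square numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  m <- if (inherits(dm, "corr_dist")) dm$d else as.matrix(dm)
  write.csv(data.frame(sample = rownames(m), m, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "corr_dist")) d <- d$d
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (any(!is.finite(m))) stop_ctx("non-finite distances")
  if (max(abs(m - t(m))) > 1e-8) stop_ctx("distance matrix is not symmetric")
  m
}

#' UPGMA clustering
#'
#' Classical average-linkage agglomeration: the two closest clusters merge
#' at a node of height half their distance, and the merged cluster's
#' distance to any other is the cluster-size-weighted mean of its members'
#' distances (so every leaf pair contributes equally). Ties are broken
#' deterministically: among equally close pairs, the one whose
#' concatenated sorted leaf-label string is lexicographically smallest
#' merges first, making the result invariant to input order.
#'
#' @param d a `corr_dist`, `dist` or symmetric numeric matrix with labels.
#' @param tie_rule only `"lexicographic"` is implemented.
#' @return an `upgma_tree`: list with `phylo` (an [ape::read.tree()] tree,
#'   rooted and ultrametric), `newick` (the serialized string, branch
#'   lengths on the input distance scale), `heights` (merge heights in
#'   order) and `labels`.
#' @export
upgma <- function(d, tie_rule = "lexicographic") {
  tie_rule <- match.arg(tie_rule)
  m <- as_dist_matrix(d)
  labels <- rownames(m)
  n <- nrow(m)
  fmt <- function(v) sprintf("%.*g", 15, v)
  qlab <- function(l) ifelse(grepl("[][(),:;'\" \t]", l),
                             paste0("'", gsub("'", "''", l), "'"), l)
  if (n == 1L) {
    nwk <- paste0(qlab(labels), ":0;")
    phy <- structure(list(edge = matrix(c(2L, 1L), 1L),
                          tip.label = labels, edge.length = 0,
                          Nnode = 1L), class = "phylo")
    return(structure(list(phylo = phy, newick = nwk,
                          heights = numeric(0), labels = labels,
                          merges = list()),
                     class = "upgma_tree"))
  }
  # cluster state: newick fragment, height, size, sorted member labels
  cl <- lapply(labels, function(l) list(str = qlab(l), h = 0, size = 1L,
                                        members = l))
  names(cl) <- labels
  act <- labels
  heights <- numeric(0)
  merges <- list()
  while (length(act) > 1L) {
    sub <- m[act, act, drop = FALSE]
    dv <- sub[upper.tri(sub)]
    dmin <- min(dv)
    idx <- which(sub == dmin & upper.tri(sub), arr.ind = TRUE)
    if (nrow(idx) > 1L) {   # lexicographic tie rule on merged member labels
      keys <- apply(idx, 1, function(k)
        paste(sort(c(cl[[act[k[1]]]]$members, cl[[act[k[2]]]]$members)),
              collapse = "\r"))
      idx <- idx[order(keys)[1], , drop = FALSE]
    }
    i <- act[idx[1, 1]]; j <- act[idx[1, 2]]
    h <- dmin / 2
    ci <- cl[[i]]; cj <- cl[[j]]
    kids <- list(ci, cj)[order(c(min(ci$members), min(cj$members)))]
    new <- list(
      str = sprintf("(%s:%s,%s:%s)", kids[[1]]$str, fmt(h - kids[[1]]$h),
                    kids[[2]]$str, fmt(h - kids[[2]]$h)),
      h = h, size = ci$size + cj$size,
      members = sort(c(ci$members, cj$members)))
    key <- paste(new$members, collapse = "\r")
    # size-weighted average distance of the new cluster to the rest
    others <- setdiff(act, c(i, j))
    m <- rbind(cbind(m, rep(0, nrow(m))), rep(0, ncol(m) + 1L))
    rownames(m)[nrow(m)] <- colnames(m)[ncol(m)] <- key
    for (o in others)
      m[key, o] <- m[o, key] <-
        (ci$size * m[i, o] + cj$size * m[j, o]) / (ci$size + cj$size)
    cl[[key]] <- new
    act <- c(others, key)
    heights <- c(heights, h)
    merges <- c(merges, list(list(left = ci$members, right = cj$members,
                                  height = h)))
  }
  root <- cl[[act]]
  nwk <- paste0(root$str, ";")
  structure(list(phylo = ape::read.tree(text = nwk), newick = nwk,
                 heights = heights, labels = labels, merges = merges),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %s\n", length(x$labels),
              if (length(x$heights)) format(max(x$heights)) else "0"))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' Branch lengths stay on the input distance scale; leaf labels containing
#' Newick-reserved characters are single-quoted.
#'
#' @param tree an `upgma_tree` or [ape] `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "upgma_tree")) {
    writeLines(tree$newick, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}
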