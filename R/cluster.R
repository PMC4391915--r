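#' Assay-by-species response matrix with coregulator annotations
#'
#' Container for the summary bioinformatic analysis: a real-valued matrix of
#' functional-assay readouts (rows = assays, columns = species/receptors)
#' together with per-assay type (transient transactivation `"TT"` or
#' mammalian 2-hybrid `"M2H"`) and coregulator presence/absence annotations
#' (the Pickett-plot panel of the heatmap).
#'
#' @param values Numeric matrix, assays in rows (rownames = assay ids),
#'   species in columns (colnames = species labels). No missing values.
#' @param assay_type Character vector per row, `"TT"` or `"M2H"`.
#' @param coregulators Named list per assay id of coregulator labels present
#'   (e.g. `c("SRC1")`, `c("RXR_WT","GRIP1")`, or `character()`).
#' @return An object of class `assay_matrix`.
#' @export
assay_matrix <- function(values, assay_type = NULL, coregulators = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be a numeric matrix with no missing values",
         call. = FALSE)
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("need >= 2 assays and >= 2 species", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("assay", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("'values' must carry species labels as column names", call. = FALSE)
  }
  if (is.null(assay_type)) assay_type <- rep("TT", nrow(values))
  if (length(assay_type) != nrow(values) ||
      !all(assay_type %in% c("TT", "M2H"))) {
    stop("'assay_type' must be TT or M2H for every assay row", call. = FALSE)
  }
  if (is.null(coregulators)) {
    coregulators <- setNames(rep(list(character()), nrow(values)),
                             rownames(values))
  }
  if (!setequal(names(coregulators), rownames(values))) {
    stop("'coregulators' must annotate every assay row", call. = FALSE)
  }
  structure(list(values = values,
                 assay_ids = rownames(values),
                 species = colnames(values),
                 assay_type = assay_type,
                 coregulators = lapply(coregulators[rownames(values)],
                                       as.character)),
            class = "assay_matrix")
}

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("assay_matrix: %d assays x %d species\n",
              nrow(x$values), ncol(x$values)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  assay types:", paste(sprintf("%s=%d", names(table(x$assay_type)),
                                      table(x$assay_type)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.assay_matrix <- function(x) dim(x$values)

as_assay_values <- function(x) {
  if (inherits(x, "assay_matrix")) x$values else as.matrix(x)
}

#' Standardize assay rows as z-scores across species
#'
#' Each assay row is centred to mean 0 and scaled to sample (n-1) standard
#' deviation 1 across species, putting heterogeneous assay readouts on a
#' common scale before clustering.
#'
#' @param x An [assay_matrix()] or plain numeric matrix (rows = assays).
#' @return Same class as the input with standardized rows.
#' @export
zscore_rows <- function(x) {
  vals <- as_assay_values(x)
  sds <- apply(vals, 1, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- rownames(vals)[which(sds == 0 | !is.finite(sds))]
    stop("cannot standardize constant assay row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- (vals - rowMeans(vals)) / sds
  if (inherits(x, "assay_matrix")) {
    out <- x
    out$values <- z
    out
  } else z
}

#' Hierarchical clustering of species by assay profiles
#'
#' Agglomerative clustering of the matrix columns (species) with Manhattan
#' distance (sum over assays of absolute z-score differences) and complete
#' linkage (cluster-cluster distance = maximum pairwise). Ties in the
#' minimum inter-cluster distance are broken deterministically by the
#' lexicographically smallest pair of cluster indices (clusters indexed by
#' their smallest original leaf), so the merge order is reproducible across
#' platforms.
#'
#' @param x A standardized [assay_matrix()] (see [zscore_rows()]) or numeric
#'   matrix with species in columns.
#' @return An object of class `cluster_tree`: list with hclust-style `merge`
#'   matrix, `height` vector (non-decreasing under complete linkage),
#'   `labels` (species) and `order` for plotting. Convert with
#'   [as.hclust.cluster_tree()] or export with [write_tree_newick()].
#' @export
cluster_species <- function(x) {
  vals <- as_assay_values(x)
  n <- ncol(vals)
  if (n < 2) stop("need at least 2 species to cluster", call. = FALSE)
  labels <- colnames(vals)
  if (is.null(labels)) labels <- paste0("sp", seq_len(n))
  # pairwise Manhattan distances between columns
  d <- as.matrix(dist(t(vals), method = "manhattan"))
  # active[i]: representative id of cluster i; members: leaf indices;
  # node[i]: hclust code (-leaf or +merge step)
  members <- as.list(seq_len(n))
  node <- -seq_len(n)
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  # cd[i, j]: complete-linkage distance between active clusters
  cd <- d
  for (step in seq_len(n - 1)) {
    best_i <- best_j <- 0L
    best_d <- Inf
    for (a in seq_along(active)) {
      if (is.na(active[a])) next
      for (b in seq_along(active)) {
        if (b <= a || is.na(active[b])) next
        dij <- cd[a, b]
        if (dij < best_d) {  # strict: ties keep the lexicographically first
          best_d <- dij; best_i <- a; best_j <- b
        }
      }
    }
    # hclust convention: singletons (negative) listed before merges
    if (node[best_i] < 0 && node[best_j] < 0) {
      merge[step, ] <- sort(c(node[best_i], node[best_j]), decreasing = TRUE)
    } else if (xor(node[best_i] < 0, node[best_j] < 0)) {
      merge[step, ] <- c(min(node[best_i], node[best_j]),
                         max(node[best_i], node[best_j]))
    } else {
      merge[step, ] <- sort(c(node[best_i], node[best_j]))
    }
    height[step] <- best_d
    # merge j into i (i has the smaller original leaf index by construction)
    members[[best_i]] <- c(members[[best_i]], members[[best_j]])
    node[best_i] <- step
    for (k in seq_along(active)) {
      if (is.na(active[k]) || k == best_i || k == best_j) next
      m <- max(cd[best_i, k], cd[best_j, k])
      cd[best_i, k] <- m
      cd[k, best_i] <- m
    }
    active[best_j] <- NA_integer_
    members[best_j] <- list(NULL)
  }
  ord <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, dist.method = "manhattan",
                 method = "complete"),
            class = "cluster_tree")
}

# left-to-right leaf traversal of an hclust-style merge matrix
tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

# leaf label set under each internal node, as a list of character vectors
node_leaf_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    grab <- function(code) {
      if (code < 0) tree$labels[-code] else sets[[code]]
    }
    sets[[i]] <- c(grab(tree$merge[i, 1]), grab(tree$merge[i, 2]))
  }
  sets
}

#' Test whether a species set is a clade of a dendrogram
#'
#' A target set is "recapitulated" as a clade when some internal node's leaf
#' set equals the target exactly. Singletons and the full leaf set are
#' always clades.
#'
#' @param tree A [cluster_species()] result.
#' @param target Character vector of species labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_clade <- function(tree, target) {
  if (!inherits(tree, "cluster_tree")) {
    stop("'tree' must be a cluster_tree", call. = FALSE)
  }
  target <- unique(as.character(target))
  unknown <- setdiff(target, tree$labels)
  if (length(unknown)) {
    stop("unknown species in target: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(target) <= 1 || length(target) == length(tree$labels)) {
    return(TRUE)
  }
  for (s in node_leaf_sets(tree)) {
    if (length(s) == length(target) && setequal(s, target)) return(TRUE)
  }
  FALSE
}

#' Cut a dendrogram into k clusters
#'
#' @param tree A [cluster_species()] result.
#' @param k Number of clusters (1..n).
#' @return Named integer vector of cluster memberships per species.
#' @export
cut_tree <- function(tree, k) {
  stats::cutree(as.hclust(tree), k = k)
}

#' Convert a cluster_tree to a base-R hclust object
#'
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method,
                 call = match.call()),
            class = "hclust")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d species, %s distance, %s linkage\n",
              length(x$labels), x$dist.method, x$method))
  cat("  merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cluster_tree <- function(x, ...) {
  plot(as.hclust(x), ...)
  invisible(x)
}

#' Export a dendrogram as a Newick string or file
#'
#' Merge heights become branch lengths via the usual ultrametric conversion
#' (leaf depth = root height).
#'
#' @param tree A [cluster_species()] result.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when writing to file.
#' @export
write_tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(as.hclust(tree))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @importFrom stats dist as.hclust anova
NULL
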