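#' Center each protein at its mean log2 value (heatmap scaling)
#'
#' Subtracts, per protein (row), the mean log2 value across lanes, so the
#' heatmap shows each lane's log2 difference from the protein mean.
#'
#' @param expr log2 `npx_matrix`.
#' @return `npx_matrix` (stage `"log2"`) with every row mean 0.
#' @export
heatmap_scale <- function(expr) {
  check_stage(expr, "log2", "heatmap_scale")
  values <- unclass(expr)
  restage(values - rowMeans(values), expr, "log2")
}

#' Spearman-correlation distance matrix
#'
#' `d(i, j) = 1 - rho(i, j)` with mid-rank Spearman correlation, computed
#' between rows or between columns. The range is `[0, 2]`, the diagonal 0.
#' Constant items have undefined correlation; they are excluded with a
#' warning and recorded in the `excluded` attribute.
#'
#' @param m numeric matrix (an `npx_matrix` or plain matrix).
#' @param axis `"rows"` or `"columns"`.
#' @return a [stats::dist] object over the retained items.
#' @export
spearman_distance <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  values <- unclass(m)
  if (axis == "rows") values <- t(values)
  # items are now columns
  if (ncol(values) < 2) stop("need >= 2 items to compute distances",
                             call. = FALSE)
  if (nrow(values) < 3) stop("need >= 3 observations per item", call. = FALSE)
  constant <- apply(values, 2, function(x) sd(x) == 0)
  if (any(constant)) {
    warning("excluding constant item(s) with undefined correlation: ",
            paste(colnames(values)[constant], collapse = ", "),
            call. = FALSE)
    values <- values[, !constant, drop = FALSE]
    if (ncol(values) < 2) stop("fewer than 2 non-constant items",
                               call. = FALSE)
  }
  rho <- cor(values, method = "spearman")
  d <- as.dist(1 - rho)
  attr(d, "excluded") <- names(constant)[constant]
  d
}

#' Average-linkage hierarchical clustering with a two-group cut
#'
#' Agglomerative clustering (UPGMA / average linkage by default) on a
#' distance matrix, plus the structural 2-cut: the partition obtained by
#' removing the final merge. Tie-breaking follows `stats::hclust`, which is
#' deterministic for a fixed item order; items are ordered lexicographically
#' first so results do not depend on input order.
#'
#' @param d a [stats::dist] object (n >= 2).
#' @param linkage linkage method (default `"average"`).
#' @return list of class `"npx_hclust"`: `hclust` (the tree), `order`
#'   (item labels in dendrogram order), `k2` (named two-group labels).
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) stop("need a dist object with n >= 2",
                                call. = FALSE)
  labs <- attr(d, "Labels")
  ord <- order(labs)
  dm <- as.matrix(d)[ord, ord]
  tree <- hclust(as.dist(dm), method = linkage)
  k2 <- cutree(tree, k = 2)
  structure(list(hclust = tree, order = tree$labels[tree$order], k2 = k2),
            class = "npx_hclust")
}

#' Two-way clustering of an expression matrix
#'
#' Protein-axis and lane-axis average-linkage clustering on
#' Spearman-correlation distance. By default both axes use the
#' mean-centered matrix ([heatmap_scale()]), as a heatmap display would;
#' set `scale = FALSE` to cluster the raw log2 values.
#'
#' @param expr log2 `npx_matrix`.
#' @param scale center each protein first (default `TRUE`).
#' @param linkage linkage method (default `"average"`).
#' @return list of class `"npx_clustering"`: `rows`, `cols` (each an
#'   `"npx_hclust"`), and `scaled` (the matrix that was clustered).
#' @export
two_way_cluster <- function(expr, scale = TRUE, linkage = "average") {
  m <- if (scale) heatmap_scale(expr) else expr
  rows <- hierarchical_cluster(spearman_distance(m, "rows"), linkage)
  cols <- hierarchical_cluster(spearman_distance(m, "columns"), linkage)
  structure(list(rows = rows, cols = cols, scaled = m),
            class = "npx_clustering")
}

#' @export
print.npx_clustering <- function(x, ...) {
  cat("<npx_clustering>\n")
  cat(sprintf("  %d proteins x %d lanes; 2-cut sizes: rows %s | cols %s\n",
              length(x$rows$k2), length(x$cols$k2),
              paste(table(x$rows$k2), collapse = "/"),
              paste(table(x$cols$k2), collapse = "/")))
  invisible(x)
}

#' Tidy cluster assignments
#'
#' @param x an `"npx_clustering"` object.
#' @param ... unused.
#' @return tibble with `item`, `axis` (protein/lane), `cluster` (2-cut
#'   label), `position` (dendrogram order).
#' @export
tidy.npx_clustering <- function(x, ...) {
  one <- function(cl, axis) {
    tibble(item = names(cl$k2), axis = axis,
           cluster = as.integer(cl$k2),
           position = match(names(cl$k2), cl$order))
  }
  dplyr::bind_rows(one(x$rows, "protein"), one(x$cols, "lane"))
}

#' Export a clustering tree as Newick
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param x an `"npx_hclust"` object.
#' @param path output file.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "npx_hclust"))
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

# leaf sets of every internal node of an hclust tree
merge_leaf_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[i, ]
    leaves <- c()
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) tree$labels[-k] else sets[[k]])
    }
    sets[[i]] <- sort(leaves)
  }
  sets
}

#' Dilution-replicate concordance QC
#'
#' Clusters all replicate lanes (Spearman distance, average linkage) and
#' checks, per sample, that its dilution replicates form a complete subtree
#' — i.e. they all merge with each other before any other sample's lane
#' joins. Mirrors the QC of running one sample at several dilutions and
#' requiring the dilutions to cluster together.
#'
#' @param counts probes x lanes matrix of the dilution experiment (raw
#'   counts or expression; Spearman distance is scale-invariant). Endogenous
#'   probes should be supplied.
#' @param samples lane metadata with `dilution_tag` set on replicate lanes.
#' @return tibble: `patient_id`, `n_replicates`, `pass`.
#' @export
dilution_replicate_check <- function(counts, samples) {
  reps <- samples |> dplyr::filter(!is.na(.data$dilution_tag))
  rep_counts <- reps |> dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(rep_counts) < 2) {
    stop("need >= 2 samples with >= 2 dilution replicates each",
         call. = FALSE)
  }
  lanes <- reps$lane_id[reps$patient_id %in% rep_counts$patient_id]
  values <- unclass(counts)[, lanes, drop = FALSE]
  lv <- log2(values + 0.5)
  cl <- hierarchical_cluster(spearman_distance(lv, "columns"))
  sets <- merge_leaf_sets(cl$hclust)
  purrr::map(rep_counts$patient_id, function(pid) {
    own <- sort(reps$lane_id[reps$patient_id == pid])
    pass <- any(vapply(sets, function(s) identical(s, own), logical(1)))
    tibble(patient_id = pid, n_replicates = length(own), pass = pass)
  }) |> dplyr::bind_rows()
}
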