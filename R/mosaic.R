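#' Configuration for Leiden/CPM clustering of the correlation matrix
#'
#' @param gamma resolution parameter of the constant Potts model, in (0, 1].
#'   Larger values give many small, highly correlated clusters; smaller
#'   values give few large, loosely correlated clusters.
#' @param min_cluster_size clusters smaller than this are reported as noise.
#' @param n_restarts number of seeded Leiden restarts; the partition with the
#'   best CPM objective wins.
#' @param seed base seed for the restarts.
#' @return list of class `"cd_mosaic_config"`.
#' @export
mosaic_config <- function(gamma = 0.5, min_cluster_size = 2L,
                          n_restarts = 10L, seed = 42L) {
  stopifnot(gamma > 0, gamma <= 1, min_cluster_size >= 1, n_restarts >= 1)
  structure(list(gamma = gamma, min_cluster_size = as.integer(min_cluster_size),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "cd_mosaic_config")
}

#' Assemble a frames-by-features matrix from extracted series
#'
#' Subsamples each series by `stride` (correlations are robust to sparse
#' data), removes the per-trajectory mean of each feature, and concatenates
#' frames across trajectories.
#'
#' @param series_list a `"cd_series_list"`.
#' @param stride subsampling stride (default 5, i.e. every fifth frame).
#' @param center `"per_trajectory"` (default) or `"none"`.
#' @return numeric matrix, one column per contact feature (lexicographic
#'   contact order), frames pooled over trajectories.
#' @export
series_feature_matrix <- function(series_list, stride = 5L,
                                  center = c("per_trajectory", "none")) {
  center <- match.arg(center)
  series_list <- subsample(series_list, stride)
  feats <- unique(vapply(series_list, `[[`, "", "contact"))
  pr <- parse_contact_name(feats)
  feats <- feats[order(pr$res_a, pr$res_b)]
  trajs <- unique(vapply(series_list, `[[`, "", "trajectory_id"))
  key <- function(s) paste(s$trajectory_id, s$contact, sep = "\r")
  by_key <- stats::setNames(series_list, vapply(series_list, key, ""))
  blocks <- lapply(trajs, function(tid) {
    cols <- lapply(feats, function(f) {
      s <- by_key[[paste(tid, f, sep = "\r")]]
      if (is.null(s)) stop("feature ", f, " missing in trajectory ", tid)
      v <- s$values
      if (center == "per_trajectory") v <- v - mean(v)
      v
    })
    do.call(cbind, cols)
  })
  m <- do.call(rbind, blocks)
  colnames(m) <- feats
  m
}

# Normalized mutual information between two numeric vectors, histogram
# estimator with ceiling(sqrt(N)) equal-width bins per variable,
# normalization by the arithmetic mean of the marginal entropies.
nmi_pair <- function(x, y) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  bx <- cut(x, breaks = nb, labels = FALSE, include.lowest = TRUE)
  by <- cut(y, breaks = nb, labels = FALSE, include.lowest = TRUE)
  pj <- table(bx, by) / n
  px <- rowSums(pj); py <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  if (hx + hy == 0) return(0)
  mi <- hx + hy - ent(as.vector(pj))
  min(max(mi / ((hx + hy) / 2), 0), 1)
}

#' Correlation model between contact-distance features
#'
#' `pearson_abs` computes the linear Pearson correlation and uses its
#' absolute value as the similarity (anticorrelated contacts are dynamically
#' coupled just the same); the signed matrix is retained for reporting.
#' `nmi` computes histogram-based normalized mutual information in [0, 1].
#'
#' @param x frames-by-features numeric matrix (see
#'   [series_feature_matrix()]) with feature names as column names.
#' @param method `"pearson_abs"` or `"nmi"`.
#' @return list of class `"cd_correlation"` with fields `features`, `matrix`
#'   (similarity in [0,1], diagonal 1), `signed` (signed Pearson or NULL),
#'   `method`.
#' @export
correlation_matrix <- function(x, method = c("pearson_abs", "nmi")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), ncol(x) >= 2)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("zero-variance feature(s): ", paste(feats[flat], collapse = ", "),
            "; their off-diagonal similarities are set to 0")
  }
  n <- ncol(x)
  signed <- NULL
  if (method == "pearson_abs") {
    signed <- suppressWarnings(stats::cor(x))
    signed[!is.finite(signed)] <- 0
    diag(signed) <- 1
    m <- abs(signed)
  } else {
    m <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- if (flat[i] || flat[j]) 0 else nmi_pair(x[, i], x[, j])
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m[flat, ] <- 0; m[, flat] <- 0; diag(m) <- 1
  dimnames(m) <- list(feats, feats)
  if (!is.null(signed)) dimnames(signed) <- dimnames(m)
  structure(list(features = feats, matrix = m, signed = signed,
                 method = method),
            class = "cd_correlation")
}

#' Constant Potts model objective of a partition
#'
#' `sum_c [W_c - gamma * n_c (n_c - 1) / 2]` where `W_c` is the sum of
#' intra-cluster off-diagonal similarities, each unordered pair counted once,
#' and `n_c` the cluster size. The diagonal (self-similarity) is excluded.
#'
#' @param m symmetric similarity matrix.
#' @param membership integer cluster label per feature.
#' @param gamma resolution parameter.
#' @return numeric objective value.
#' @export
cpm_objective <- function(m, membership, gamma) {
  obj <- 0
  for (cl in unique(membership)) {
    idx <- which(membership == cl)
    nc <- length(idx)
    if (nc > 1) {
      sub <- m[idx, idx]
      obj <- obj + sum(sub[upper.tri(sub)]) - gamma * nc * (nc - 1) / 2
    }
  }
  obj
}

# Canonical relabeling: clusters numbered by first occurrence.
canonical_membership <- function(membership) {
  match(membership, unique(membership))
}

#' Leiden clustering of a correlation model under the constant Potts model
#'
#' Runs `n_restarts` seeded Leiden optimizations (via igraph) on the fully
#' connected weighted graph whose edge weights are the similarity-matrix
#' entries, and returns the partition with the highest CPM objective. Ties
#' are broken in favor of fewer clusters, then lexicographically on the
#' canonical membership vector. Clusters smaller than `min_cluster_size`
#' are reported as noise.
#'
#' @param model a `"cd_correlation"`.
#' @param config a [mosaic_config()].
#' @return list of class `"cd_partition"` with fields `assignment` (named
#'   integer, NA for noise), `clusters` (list of feature-name vectors,
#'   ordered by decreasing size then smallest feature position), `noise`
#'   (feature names), `objective` (CPM score of the selected partition,
#'   before noise reassignment), `gamma`, `config`.
#' @export
leiden_cpm <- function(model, config = mosaic_config()) {
  stopifnot(inherits(model, "cd_correlation"),
            inherits(config, "cd_mosaic_config"))
  m <- model$matrix
  n <- nrow(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$seed + r - 1L)
    cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                                 weights = igraph::E(g)$weight,
                                 resolution = config$gamma,
                                 n_iterations = 10L)
    memb <- canonical_membership(as.integer(igraph::membership(cl)))
    obj <- cpm_objective(m, memb, config$gamma)
    cand <- list(membership = memb, objective = obj,
                 n_clusters = length(unique(memb)))
    if (is.null(best) || better_partition(cand, best)) best <- cand
  }
  partition_from_membership(model, best$membership, best$objective, config)
}

# TRUE when candidate partition a beats b: higher objective; ties -> fewer
# clusters; further ties -> lexicographically smaller membership vector.
better_partition <- function(a, b, tol = 1e-10) {
  if (a$objective > b$objective + tol) return(TRUE)
  if (a$objective < b$objective - tol) return(FALSE)
  if (a$n_clusters != b$n_clusters) return(a$n_clusters < b$n_clusters)
  d <- which(a$membership != b$membership)
  length(d) > 0 && a$membership[d[1]] < b$membership[d[1]]
}

partition_from_membership <- function(model, membership, objective, config) {
  feats <- model$features
  groups <- split(seq_along(feats), membership)
  sizes <- vapply(groups, length, integer(1))
  first <- vapply(groups, min, integer(1))
  ord <- order(-sizes, first)
  groups <- groups[ord]; sizes <- sizes[ord]
  keep <- sizes >= config$min_cluster_size
  clusters <- lapply(groups[keep], function(ix) feats[ix])
  names(clusters) <- if (sum(keep)) paste0("C", seq_len(sum(keep))) else character(0)
  noise <- feats[sort(unlist(groups[!keep], use.names = FALSE))]
  assignment <- stats::setNames(rep(NA_integer_, length(feats)), feats)
  for (i in seq_along(clusters)) assignment[clusters[[i]]] <- i
  structure(list(assignment = assignment, clusters = clusters, noise = noise,
                 objective = objective, gamma = config$gamma, config = config),
            class = "cd_partition")
}

#' @export
print.cd_partition <- function(x, ...) {
  cat(sprintf("cd_partition: %d clusters (+%d noise features), gamma = %g, CPM objective = %.6g\n",
              length(x$clusters), length(x$noise), x$gamma, x$objective))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  %s (%d): %s\n", names(x$clusters)[i], length(x$clusters[[i]]),
                paste(utils::head(x$clusters[[i]], 8), collapse = " ")))
  }
  invisible(x)
}

#' Permute a correlation matrix into approximately block-diagonal form
#'
#' Rows/columns are reordered so that each cluster's features are contiguous
#' (clusters in partition order, noise last); values are unchanged.
#'
#' @param model a `"cd_correlation"`.
#' @param partition a `"cd_partition"` over the same features.
#' @return a reordered `"cd_correlation"`.
#' @export
reorder_block_diagonal <- function(model, partition) {
  feats <- model$features
  pfeats <- c(unlist(partition$clusters, use.names = FALSE), partition$noise)
  if (!setequal(feats, pfeats) || length(pfeats) != length(feats)) {
    stop("partition features do not match correlation model features")
  }
  ord <- match(pfeats, feats)
  out <- model
  out$features <- pfeats
  out$matrix <- model$matrix[ord, ord]
  if (!is.null(model$signed)) out$signed <- model$signed[ord, ord]
  out
}

# Mean intra-cluster off-diagonal similarity over all clustered pairs.
mean_intra_correlation <- function(model, partition) {
  tot <- 0; np <- 0
  for (cl in partition$clusters) {
    idx <- match(cl, model$features)
    sub <- model$matrix[idx, idx]
    tot <- tot + sum(sub[upper.tri(sub)])
    np <- np + length(idx) * (length(idx) - 1) / 2
  }
  if (np == 0) NA_real_ else tot / np
}

#' Scan the CPM resolution parameter
#'
#' Clusters the same correlation model at each value of `gamma` with a shared
#' seed policy, reporting cluster counts and mean intra-cluster correlation.
#'
#' @param model a `"cd_correlation"`.
#' @param gammas numeric vector of resolutions, each in (0, 1].
#' @param config a [mosaic_config()] (its `gamma` is ignored).
#' @return list with `summary` (data.frame: gamma, n_clusters, n_noise,
#'   objective, mean_intra_correlation) and `partitions` (list of
#'   `"cd_partition"` in gamma order).
#' @export
gamma_scan <- function(model, gammas, config = mosaic_config()) {
  stopifnot(length(gammas) >= 1, all(gammas > 0), all(gammas <= 1))
  parts <- lapply(gammas, function(g) {
    cfg <- config; cfg$gamma <- g
    leiden_cpm(model, cfg)
  })
  summary <- data.frame(
    gamma = gammas,
    n_clusters = vapply(parts, function(p) length(p$clusters), integer(1)),
    n_noise = vapply(parts, function(p) length(p$noise), integer(1)),
    objective = vapply(parts, function(p) p$objective, numeric(1)),
    mean_intra_correlation = vapply(parts, function(p)
      mean_intra_correlation(model, p), numeric(1)))
  list(summary = summary, partitions = parts)
}

#' Write a partition as JSON or two-column TSV
#' @param partition a `"cd_partition"`.
#' @param file path; `.json` gives `{cluster: [contact, ...], ...}` (noise
#'   under `"noise"`), anything else a `contact\tcluster` TSV.
#' @return `file`, invisibly.
#' @export
write_partition <- function(partition, file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    obj <- partition$clusters
    obj$noise <- as.list(partition$noise)
    jsonlite::write_json(obj, file, auto_unbox = FALSE)
  } else {
    df <- data.frame(
      contact = c(unlist(partition$clusters, use.names = FALSE), partition$noise),
      cluster = c(rep(names(partition$clusters),
                      vapply(partition$clusters, length, integer(1))),
                  rep("noise", length(partition$noise))))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Read a partition JSON written by [write_partition()]
#' @param file JSON path.
#' @return list with `clusters` (named list) and `noise` (character).
#' @export
read_partition <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  noise <- as.character(obj[["noise"]])
  obj[["noise"]] <- NULL
  list(clusters = lapply(obj, as.character), noise = noise)
}

#' Write a correlation matrix as CSV
#' @param model a `"cd_correlation"`.
#' @param file CSV path.
#' @param which `"matrix"` (similarity) or `"signed"`.
#' @return `file`, invisibly.
#' @export
write_correlation_csv <- function(model, file, which = c("matrix", "signed")) {
  which <- match.arg(which)
  m <- model[[which]]
  if (is.null(m)) stop("no ", which, " matrix stored for method ", model$method)
  utils::write.csv(as.data.frame(m), file, row.names = TRUE, quote = FALSE)
  invisible(file)
}
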