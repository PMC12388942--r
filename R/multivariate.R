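#' Assemble the events x drugs lnROR matrix
#'
#' Rows are the selected event PTs (observations), columns the selected
#' drugs (variables), entries the Haldane-corrected lnROR of each pair —
#' the orientation in which drugs get loadings and events get scores.
#'
#' @param signals output of [pairwise_signals()].
#' @param events,drugs the selected row/column label sets (default: all in
#'   `signals`). A pair absent from `signals` is an error.
#' @return numeric matrix with events as rownames, drugs as colnames.
#' @export
assemble_matrix <- function(signals, events = NULL, drugs = NULL) {
  s <- as.data.table(signals)
  if (is.null(events)) events <- sort(unique(s$event))
  if (is.null(drugs)) drugs <- sort(unique(s$drug))
  if (anyDuplicated(events)) stop("duplicate event labels")
  if (anyDuplicated(drugs)) stop("duplicate drug labels")
  s <- s[event %chin% events & drug %chin% drugs]
  grid <- CJ(event = events, drug = drugs)
  miss <- s[grid, on = c("event", "drug")][is.na(ln_ror)]
  if (nrow(miss)) {
    stop(sprintf("missing signal for pair(s): %s",
                 paste(head(miss[, paste(drug, event, sep = " / ")], 5), collapse = "; ")))
  }
  m <- matrix(NA_real_, length(events), length(drugs),
              dimnames = list(events, drugs))
  m[cbind(match(s$event, events), match(s$drug, drugs))] <- s$ln_ror
  if (any(!is.finite(m))) stop("lnROR matrix has non-finite entries; Haldane-correct the signals")
  m
}

#' Correlation-matrix principal component analysis
#'
#' PCA on the column correlation matrix (i.e. columns centred and scaled to
#' unit variance). Eigenvalues sum to the number of variables; the percent
#' variance of each component is `100 * lambda / n_variables`. Scores are
#' standardized to unit variance per component; loadings are the Pearson
#' correlations between each component and each original column (equal to
#' `eigenvector * sqrt(lambda)` for correlation PCA). Each retained
#' component's sign is fixed so that its largest-|loading| variable loads
#' positively, making results reproducible.
#'
#' @param x numeric matrix, observations x variables, >= 3 rows.
#' @param n_retain number of components retained for scores/loadings
#'   (default 3).
#' @return a `pca_result` list: `eigenvalues`, `pct_variance` (over all
#'   components), `scores` (obs x retained, unit variance), `loadings`
#'   (variables x retained, correlations), `n_retain`.
#' @export
pca_correlation <- function(x, n_retain = 3) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 observations (rows)")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  p <- ncol(x)
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  lambda <- pc$sdev^2
  pct <- 100 * lambda / p
  n_retain <- min(n_retain, sum(lambda > 1e-12))
  idx <- seq_len(n_retain)
  scores <- sweep(pc$x[, idx, drop = FALSE], 2, pc$sdev[idx], `/`)
  loadings <- sweep(pc$rotation[, idx, drop = FALSE], 2, pc$sdev[idx], `*`)
  for (j in idx) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  cn <- paste0("PC", idx)
  colnames(scores) <- cn
  colnames(loadings) <- cn
  structure(list(eigenvalues = lambda, pct_variance = pct,
                 scores = scores, loadings = loadings, n_retain = n_retain),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(x$n_retain, length(x$pct_variance))
  cat(sprintf("correlation-matrix PCA: %d variables, %d retained components\n",
              length(x$eigenvalues) + 0, x$n_retain))
  cat(sprintf("  PC%d: %.1f%% of variance\n", seq_len(k), x$pct_variance[seq_len(k)]),
      sep = "")
  invisible(x)
}

#' Compare component scores between injury sites
#'
#' Two-sample t-test of per-event component scores between the upper and
#' lower GI site groups; `not_classified` events are excluded. Pooled
#' (Student) variance by default, Welch via `var_equal = FALSE`.
#'
#' @param scores named numeric vector of per-event scores (names = PTs), or
#'   unnamed when `sites` is given positionally.
#' @param sites character vector of sites for each score (upper/lower/
#'   not_classified).
#' @param var_equal use the pooled-variance Student form (default TRUE).
#' @return list: `t`, `df`, `p_value`, group means.
#' @export
pc_site_ttest <- function(scores, sites, var_equal = TRUE) {
  stopifnot(length(scores) == length(sites))
  keep <- sites %in% c("upper", "lower")
  scores <- scores[keep]; sites <- sites[keep]
  if (sum(sites == "upper") < 2 || sum(sites == "lower") < 2) {
    stop("need at least 2 events in each of the upper and lower site groups")
  }
  ht <- t.test(scores[sites == "upper"], scores[sites == "lower"],
               var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_upper = mean(scores[sites == "upper"]),
       mean_lower = mean(scores[sites == "lower"]))
}

#' Ward hierarchical clustering of drugs on their PCA loadings
#'
#' Ward's minimum-variance linkage (squared-Euclidean update; `ward.D2` on
#' Euclidean distances) over the rows of the loading matrix. Merge heights
#' are non-decreasing.
#'
#' @param loadings drugs x components numeric matrix (rownames = drugs).
#' @return the `hclust` object.
#' @export
ward_cluster <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (nrow(loadings) < 2) stop("need at least 2 drugs to cluster")
  hclust(dist(loadings), method = "ward.D2")
}

#' Elbow selection of the cluster count
#'
#' Reading the dendrogram top-down, candidate `k` is scored by the ratio of
#' the merge height crossed when going from `k` to `k - 1` clusters to the
#' height crossed when going from `k + 1` to `k` — the size of the jump at
#' `k`. The `k` (2..k_max) with the largest ratio is selected; ties break
#' toward smaller `k`. If all heights are equal there is no elbow and 1 is
#' returned with a warning.
#'
#' @param hc an `hclust` from [ward_cluster()], or a numeric vector of merge
#'   heights.
#' @param k_max largest cluster count considered (default 10).
#' @export
elbow_select_k <- function(hc, k_max = 10) {
  heights <- if (inherits(hc, "hclust")) hc$height else hc
  if (length(heights) < 2) stop("need at least 2 merges to select k")
  H <- sort(heights, decreasing = TRUE)  # H[1] = final merge (2 clusters)
  if (diff(range(heights)) == 0) {
    warning("all merge heights equal; no elbow, returning k = 1")
    return(1L)
  }
  ks <- 2:min(k_max, length(H))
  ratio <- H[ks - 1] / H[ks]
  ratio[!is.finite(ratio)] <- Inf
  as.integer(ks[which.max(ratio)])
}

#' Cut the dendrogram into k clusters
#'
#' Clusters are renumbered by decreasing size; equal-sized clusters are
#' ordered by their lexicographically first member.
#'
#' @param hc an `hclust`.
#' @param k number of clusters.
#' @return named integer vector: drug -> cluster id in 1..k.
#' @export
assign_clusters <- function(hc, k) {
  n <- length(hc$labels)
  if (k < 1 || k > n) stop(sprintf("k must be in 1..%d", n))
  raw <- cutree(hc, k = k)
  first <- vapply(split(names(raw), raw), function(m) sort(m)[1], character(1))
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), first)
  remap <- integer(k)
  remap[as.integer(names(sizes))[ord]] <- seq_len(k)
  out <- remap[raw]
  names(out) <- names(raw)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' items; 1 means identical partitions, 0 the chance level.
#'
#' @param x,y label vectors of equal length.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
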