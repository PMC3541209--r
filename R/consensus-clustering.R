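#' Configuration for bootstrap consensus clustering
#'
#' @param k_range Candidate numbers of clusters (default 2..8).
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param sample_frac Fraction of samples (columns) drawn without
#'   replacement in each iteration (default 0.8); genes are never
#'   resampled, so gene co-membership is observable in every iteration.
#' @param algorithms Clustering algorithm families to merge; any subset of
#'   `agglomerative_average` (average-linkage hierarchical),
#'   `divisive` (diana), `kmeans`, `kmedoids` (pam).
#' @param robustness_cutoff Membership-robustness threshold above which a
#'   gene counts as a robust cluster member (default 0.6).
#' @param min_robust_members Minimum robust members for a cluster to be
#'   signature-eligible (default 5).
#' @param top_n_variable Default size of the most-variable-gene subset
#'   fed to clustering (default 200).
#' @param seed Integer seed for the bootstrap resampling.
#' @return A validated `consensus_config` list.
#' @export
consensus_config <- function(k_range = 2:8,
                             n_boot = 100,
                             sample_frac = 0.8,
                             algorithms = c("agglomerative_average", "divisive",
                                            "kmeans", "kmedoids"),
                             robustness_cutoff = 0.6,
                             min_robust_members = 5,
                             top_n_variable = 200,
                             seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (sample_frac <= 0 || sample_frac > 1) abort("sample_frac must be in (0, 1].")
  if (n_boot < 1) abort("n_boot must be >= 1.")
  if (robustness_cutoff < 0 || robustness_cutoff > 1) {
    abort("robustness_cutoff must be in [0, 1].")
  }
  if (any(k_range < 2)) abort("k_range values must be >= 2.")
  structure(
    list(
      k_range = sort(unique(as.integer(k_range))), n_boot = as.integer(n_boot),
      sample_frac = sample_frac, algorithms = algorithms,
      robustness_cutoff = robustness_cutoff,
      min_robust_members = as.integer(min_robust_members),
      top_n_variable = as.integer(top_n_variable), seed = as.integer(seed)
    ),
    class = "consensus_config"
  )
}

#' Select the most variable up-regulated DE genes
#'
#' Among transcripts called differentially expressed, ranks by variance of
#' the log2 fold changes across all samples, keeps the top `n`, then drops
#' down-regulated calls — uninformative genes are excluded before
#' clustering, and signatures are built from over-expressed genes only.
#'
#' @param fc Wide log2 fold-change tibble.
#' @param de [call_differential()] result for the same transcripts.
#' @param n Number of genes to keep before the direction filter
#'   (default 200).
#' @return A tibble `transcript_id`, `variance`, `call`, most variable
#'   first, containing only up-regulated genes.
#' @export
select_top_variable <- function(fc, de, n = 200) {
  if (n < 1) abort("`n` must be >= 1.")
  de_genes <- de$transcript_id[de$call != "none"]
  if (length(de_genes) == 0) abort("no differentially expressed genes.")
  m <- expr_matrix(fc)
  de_genes <- intersect(rownames(m), de_genes)
  v <- row_vars(m[de_genes, , drop = FALSE])
  picked <- tibble(transcript_id = de_genes, variance = v) |>
    dplyr::arrange(dplyr::desc(.data$variance)) |>
    dplyr::slice_head(n = n) |>
    dplyr::left_join(de[, c("transcript_id", "call")], by = "transcript_id") |>
    dplyr::filter(.data$call == "up")
  picked
}

#' Bootstrap multi-algorithm consensus clustering of gene profiles
#'
#' In each of `n_boot` iterations a random subset of samples is drawn and
#' each algorithm clusters the gene fold-change profiles — hierarchical
#' methods on the correlation distance `1 - Pearson`, partitioning methods
#' (k-means, k-medoids) on row-standardized profiles — at every `k` in
#' `k_range`.  Per algorithm and `k`, the consensus matrix is the
#' co-membership frequency over iterations; the merged matrix `M` is their
#' mean across algorithms.  The final partition at each `k` is an
#' average-linkage cut of `1 - M`; `k` is chosen to maximize the product
#' of mean cluster robustness (cohesion) and one minus the mean
#' off-diagonal consensus (separation), ties broken toward smaller `k` —
#' cohesion alone saturates for coarse partitions of stably-merging
#' modules, so the product selects the finest partition that is still
#' robust.
#'
#' @param fc Wide log2 fold-change tibble (typically restricted to the
#'   [select_top_variable()] genes).
#' @param config A [consensus_config()].
#' @param genes Optional transcript ids to restrict to (character vector
#'   or the tibble returned by [select_top_variable()]).
#' @return An object of class `myo_consensus`: gene ids, merged consensus
#'   matrix for the chosen `k`, partition labels, per-gene membership
#'   robustness, robust member lists per cluster, and the per-`k` mean
#'   robustness trace.  See [tidy.myo_consensus()] / [glance.myo_consensus()].
#' @export
run_consensus <- function(fc, config = consensus_config(), genes = NULL) {
  assert_expr_tbl(fc)
  if (is.data.frame(genes)) genes <- genes$transcript_id
  m <- expr_matrix(fc)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("genes absent from `fc`: ", paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  G <- nrow(m); S <- ncol(m)
  if (G < max(config$k_range)) abort("need at least max(k_range) genes.")
  if (any(row_vars(m) == 0)) {
    abort("constant gene rows: correlation distance undefined.")
  }
  n_sub <- ceiling(config$sample_frac * S)
  if (n_sub < 3) abort("subsampled sample count must be >= 3.")

  ks <- config$k_range
  algs <- config$algorithms
  acc <- lapply(algs, function(a) lapply(ks, function(k) matrix(0, G, G)))
  names(acc) <- algs

  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      cols <- sample.int(S, n_sub)
      sub <- m[, cols, drop = FALSE]
      sdv <- sqrt(row_vars(sub))
      # a gene that happens to be constant within this subsample gets zero
      # correlation to everything rather than poisoning the distance with NAs
      co <- suppressWarnings(cor(t(sub)))
      co[!is.finite(co)] <- 0
      diag(co) <- 1
      D <- as.dist(1 - co)
      std <- (sub - rowMeans(sub)) / ifelse(sdv > 0, sdv, 1)

      fits <- list()
      if ("agglomerative_average" %in% algs) {
        fits$agglomerative_average <- hclust(D, method = "average")
      }
      if ("divisive" %in% algs) {
        fits$divisive <- as.hclust(cluster::diana(D, diss = TRUE))
      }
      for (ki in seq_along(ks)) {
        k <- ks[ki]
        for (a in algs) {
          labels <- switch(a,
            agglomerative_average = cutree(fits$agglomerative_average, k),
            divisive = cutree(fits$divisive, k),
            kmeans = kmeans_labels(std, k),
            kmedoids = cluster::pam(std, k = k, cluster.only = TRUE,
                                    pamonce = 5)
          )
          Z <- matrix(0, G, k)
          Z[cbind(seq_len(G), labels)] <- 1
          acc[[a]][[ki]] <- acc[[a]][[ki]] + tcrossprod(Z)
        }
      }
    }
  })

  per_k <- purrr::map(seq_along(ks), function(ki) {
    M <- Reduce(`+`, purrr::map(acc, ki)) / (length(algs) * config$n_boot)
    dimnames(M) <- list(rownames(m), rownames(m))
    labels <- cutree(hclust(as.dist(1 - M), method = "average"), ks[ki])
    rob <- membership_robustness(M, labels)
    cl_rob <- vapply(split(rob, labels), mean, numeric(1))
    # separation: 1 - mean off-diagonal consensus; cohesion alone is biased
    # toward coarse partitions (stably merged modules co-cluster perfectly),
    # so k is picked by the cohesion x separation product
    sep <- 1 - mean(M[upper.tri(M)])
    list(k = ks[ki], M = M, labels = labels, robustness = rob,
         mean_cluster_robustness = mean(cl_rob), separation = sep)
  })

  trace <- tibble(
    k = ks,
    mean_cluster_robustness =
      vapply(per_k, `[[`, numeric(1), "mean_cluster_robustness"),
    separation = vapply(per_k, `[[`, numeric(1), "separation")
  )
  trace$score <- trace$mean_cluster_robustness * trace$separation
  best <- per_k[[which.max(trace$score)]]

  robust <- best$robustness >= config$robustness_cutoff
  members <- split(names(best$labels)[robust], best$labels[robust])

  structure(
    list(
      gene_ids = rownames(m),
      consensus = best$M,
      k = best$k,
      labels = best$labels,
      robustness = best$robustness,
      robust_members = members,
      per_k = trace,
      config = config
    ),
    class = "myo_consensus"
  )
}

# k-means with a guard for degenerate inputs: when there are at most k
# distinct standardized profiles, duplicates are grouped by identity
# (k-means cannot seed k distinct centers there).
kmeans_labels <- function(std, k) {
  u <- unique(std)
  if (nrow(u) <= k) {
    return(as.integer(factor(apply(std, 1, paste, collapse = "\r"))))
  }
  kmeans(std, centers = k, nstart = 3, iter.max = 30)$cluster
}

#' Membership robustness of each gene in a partition
#'
#' The robustness of gene `g` is the average consensus (co-clustering
#' frequency) between `g` and all other members of its cluster; genes in
#' singleton clusters score 0 by convention.
#'
#' @param M Symmetric consensus matrix in `[0, 1]` with unit diagonal.
#' @param labels Integer partition labels, one per row of `M`.
#' @return Named numeric vector of robustness scores in `[0, 1]`.
#' @export
membership_robustness <- function(M, labels) {
  if (nrow(M) != length(labels)) abort("labels do not match consensus matrix.")
  score <- vapply(seq_along(labels), function(g) {
    peers <- which(labels == labels[g])
    peers <- peers[peers != g]
    if (length(peers) == 0) 0 else mean(M[g, peers])
  }, numeric(1))
  names(score) <- rownames(M) %||% names(labels)
  score
}

#' @export
print.myo_consensus <- function(x, ...) {
  n_elig <- sum(lengths(x$robust_members) >= x$config$min_robust_members)
  cat(sprintf(
    "Consensus clustering of %d genes: k = %d (%d signature-eligible cluster%s)\n",
    length(x$gene_ids), x$k, n_elig, if (n_elig == 1) "" else "s"
  ))
  cat(sprintf("robust members per cluster: %s\n",
              paste(lengths(x$robust_members), collapse = ", ")))
  invisible(x)
}

#' Tidy a consensus clustering result
#'
#' @param x A `myo_consensus` object.
#' @param ... Unused.
#' @return One row per gene: `transcript_id`, `cluster`, `robustness`,
#'   `robust`.
#' @export
tidy.myo_consensus <- function(x, ...) {
  tibble(
    transcript_id = names(x$labels),
    cluster = unname(x$labels),
    robustness = unname(x$robustness[names(x$labels)]),
    robust = unname(x$robustness[names(x$labels)] >= x$config$robustness_cutoff)
  )
}

#' @rdname tidy.myo_consensus
#' @return `glance()`: a one-row summary with the chosen `k`, gene and
#'   cluster counts, the number of signature-eligible clusters and the
#'   mean cluster robustness at the chosen `k`.
#' @export
glance.myo_consensus <- function(x, ...) {
  tibble(
    k = x$k,
    n_genes = length(x$gene_ids),
    n_clusters = length(unique(x$labels)),
    n_eligible = sum(lengths(x$robust_members) >= x$config$min_robust_members),
    mean_cluster_robustness =
      x$per_k$mean_cluster_robustness[x$per_k$k == x$k]
  )
}
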