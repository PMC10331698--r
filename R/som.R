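#' Batch self-organizing map over response profiles
#'
#' Trains a rectangular-grid SOM with batch updates, a Gaussian
#' neighborhood whose radius decays linearly from `max(grid)/2` to 1, and
#' deterministic initialization on the first two principal-component axes
#' of the data. Nodes are numbered 1..N from the lower-left corner to the
#' top-right, row by row (id = row_from_bottom * cols + col_from_left + 1).
#'
#' @param pm a [profile_matrix()] or plain numeric matrix of profiles.
#' @param grid integer `(rows, cols)` of the node grid.
#' @param epochs training epochs (default 100).
#' @param radius0 initial neighborhood radius (defaults to `max(grid)/2`).
#' @param seed kept for interface symmetry; training is deterministic.
#' @return object of class `som_model` with the codebook (one row per
#'   node, in cluster-id order), the grid, and the per-epoch quantization
#'   error trajectory `qe`.
#' @export
train_som <- function(pm, grid = c(7L, 7L), epochs = 100L,
                      radius0 = max(grid) / 2, seed = 1L) {
  x <- unclass(pm)
  if (nrow(x) == 0L) stop("empty profile set")
  if (nrow(x) < prod(grid)) {
    warning("fewer profiles (", nrow(x), ") than SOM nodes (", prod(grid), ")")
  }
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  # node coordinates in cluster-id order: bottom row first, left to right
  coord <- cbind(row = rep(seq_len(rows) - 1L, each = cols),
                 col = rep(seq_len(cols) - 1L, times = rows))
  dgrid <- as.matrix(stats::dist(coord))

  codebook <- som_init_pca(x, coord)
  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    sigma <- if (epochs == 1L) 1 else
      radius0 - (radius0 - 1) * (e - 1) / (epochs - 1)
    d2 <- cross_dist2(x, codebook)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-dgrid[, bmu, drop = FALSE]^2 / (2 * sigma^2))
    w <- rowSums(h)
    upd <- (h %*% x) / w
    live <- w > 1e-12
    codebook[live, ] <- upd[live, ]
    qe[e] <- mean(sqrt(pmax(0, apply(cross_dist2(x, codebook), 1L, min))))
  }
  structure(list(codebook = codebook, grid = c(rows = rows, cols = cols),
                 qe = qe, epochs = epochs, radius0 = radius0, seed = seed,
                 endpoints = colnames(x)),
            class = "som_model")
}

som_init_pca <- function(x, coord) {
  n_nodes <- nrow(coord)
  center <- colMeans(x)
  codebook <- matrix(rep(center, each = n_nodes), nrow = n_nodes,
                     dimnames = list(NULL, colnames(x)))
  sv <- tryCatch(La.svd(sweep(x, 2L, center), nu = 0, nv = 2L),
                 error = function(e) NULL)
  if (!is.null(sv) && length(sv$d) >= 1L) {
    # the first principal axis spans the longer grid dimension
    col_first <- diff(range(coord[, "col"])) >= diff(range(coord[, "row"]))
    axes <- if (col_first) c("col", "row") else c("row", "col")
    for (k in seq_len(min(2L, length(sv$d), nrow(sv$vt)))) {
      pc <- sv$vt[k, ]
      # sign convention: largest-magnitude loading positive, for determinism
      if (pc[which.max(abs(pc))] < 0) pc <- -pc
      score_sd <- sv$d[k] / sqrt(max(1L, nrow(x) - 1L))
      axis <- coord[, axes[k]]
      span <- diff(range(axis))
      pos <- if (span == 0) rep(0, n_nodes) else (axis - mean(axis)) / (span / 2)
      codebook <- codebook + outer(pos * score_sd, pc)
    }
  }
  codebook
}

# squared Euclidean distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  pmax(d2, 0)
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d grid, %d epochs, final QE %.4g\n",
              x$grid["rows"], x$grid["cols"], x$epochs,
              x$qe[length(x$qe)]))
  invisible(x)
}

#' Assign profiles to SOM clusters
#'
#' Nearest-codebook (Euclidean) assignment; ties resolve to the lowest
#' cluster id. Cluster ids follow the lower-left to top-right numbering.
#'
#' @param model a [train_som()] model.
#' @param pm profiles over the same endpoint set.
#' @return integer vector of cluster ids, one per profile row.
#' @export
assign_clusters <- function(model, pm) {
  x <- unclass(pm)
  if (!identical(colnames(x), model$endpoints)) {
    stop("profile endpoints do not match the trained model")
  }
  max.col(-cross_dist2(x, model$codebook), ties.method = "first")
}

#' Two-pass SOM clustering with cytotoxicity filtering
#'
#' Pass 1 clusters every profile on the full grid (default 7x7). Pass 2
#' removes profiles with more than `max_cytotox` positive cytotoxicity
#' endpoints and re-clusters the remainder on the smaller grid (default
#' 6x6), where mechanistic structure is no longer dominated by general
#' suppression secondary to cytotoxicity.
#'
#' @param pm a [profile_matrix()].
#' @param counts per-profile cytotoxicity counts from [cytotox_counts()].
#' @param config a [pipeline_config()].
#' @return list with `full` and `filtered` components, each holding
#'   `model`, `assignments` (data.frame sample_id, concentration,
#'   chemical_id, cluster, n_cytotox) and `cluster_summary` (per-cluster
#'   size and mean cytotoxicity count).
#' @export
two_pass_clustering <- function(pm, counts, config = pipeline_config()) {
  max_ct <- config$max_cytotox_endpoints_for_profiling
  key_pm <- paste(pm_samples(pm), pm_concs(pm), sep = "\r")
  key_ct <- paste(counts$sample_id, counts$concentration, sep = "\r")
  n_ct <- counts$n_cytotox[match(key_pm, key_ct)]

  run_pass <- function(p, nct, grid) {
    model <- train_som(p, grid = grid, epochs = config$som_epochs,
                       seed = config$seed)
    cl <- assign_clusters(model, p)
    assignments <- data.frame(sample_id = pm_samples(p),
                              concentration = pm_concs(p),
                              chemical_id = pm_chemicals(p),
                              cluster = cl, n_cytotox = nct,
                              stringsAsFactors = FALSE)
    summ <- data.frame(
      cluster = sort(unique(cl)),
      n_profiles = as.integer(table(cl)),
      mean_n_cytotox = as.numeric(tapply(nct, cl, mean)),
      chemicals = vapply(split(assignments$chemical_id, cl), function(ch)
        paste(sort(unique(ch)), collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    list(model = model, assignments = assignments, cluster_summary = summ)
  }

  keep <- n_ct <= max_ct
  list(full = run_pass(pm, n_ct, config$som_grid_full),
       filtered = run_pass(pm[keep, , drop = FALSE], n_ct[keep],
                           config$som_grid_filtered))
}
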