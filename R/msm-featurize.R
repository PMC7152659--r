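#' Binarize a ligand-residue distance table into a contact map
#'
#' A frame-by-pair distance matrix (Angstrom) becomes a binary feature
#' matrix with entry 1 iff the distance is strictly below the cutoff
#' (default 8 A, the conventional contact threshold between ligand halide /
#' attacked-carbon atoms and protein C-alpha atoms).
#'
#' @param distance_table Numeric matrix or data frame of nonnegative
#'   distances, frames in rows.
#' @param cutoff Contact cutoff in Angstrom (> 0); contact means
#'   `distance < cutoff` (strict).
#' @return Integer 0/1 matrix of the same shape.
#' @export
#' @examples
#' binary_contact_featurize(matrix(c(7, 9, 8, 1), 2, 2), cutoff = 8)
binary_contact_featurize <- function(distance_table, cutoff = 8) {
  d <- as.matrix(distance_table)
  if (cutoff <= 0) abort("cutoff must be > 0", class = "dhalokin_config_error")
  if (any(d < 0)) {
    abort("distances must be >= 0", class = "dhalokin_validation_error")
  }
  m <- (d < cutoff) + 0L
  dimnames(m) <- dimnames(d)
  m
}

#' Time-lagged independent component analysis
#'
#' Finds the linear projections of a (mean-free) feature time series with
#' the slowest decorrelation: solves the generalized eigenproblem
#' `C(tau) w = lambda C(0) w` with the symmetrized lag-covariance
#' `C(tau) = (C + C')/2`. Eigenvalues sort descending; components whose
#' eigenvalue is near 1 change slowly and are the kinetically informative
#' coordinates to cluster on. Component sign is arbitrary.
#'
#' A near-singular instantaneous covariance is regularized by a ridge
#' (`ridge`, logged via a message); if the rank after regularization is
#' still below `n_components` an error is raised.
#'
#' @param features Numeric matrix (frames x dimensions) or a list of such
#'   matrices (one per trajectory; lagged pairs never cross trajectories).
#' @param lag Lag in frames, >= 1, less than each series length.
#' @param n_components Number of components, <= feature dimension.
#' @param ridge Ridge added to `C(0)` when near-singular.
#' @return An object of class `"tica"`: `components` (columns are
#'   eigenvectors in feature space), `eigenvalues`, `projections` (frames x
#'   n_components, trajectories concatenated), `lag`, `mean`.
#' @export
tica <- function(features, lag, n_components = NULL, ridge = 1e-8) {
  blocks <- if (is.list(features)) purrr::map(features, as.matrix) else list(as.matrix(features))
  d <- ncol(blocks[[1]])
  if (is.null(n_components)) n_components <- min(5L, d)
  if (n_components > d) {
    abort("n_components must be <= feature dimension",
      class = "dhalokin_contract_error"
    )
  }
  if (any(vapply(blocks, nrow, 1L) <= lag)) {
    abort("each series must be longer than the lag",
      class = "dhalokin_contract_error"
    )
  }
  mu <- colMeans(do.call(rbind, blocks))
  c0 <- matrix(0, d, d)
  ct <- matrix(0, d, d)
  n_pairs <- 0
  for (b in blocks) {
    x <- sweep(b, 2, mu)
    n <- nrow(x)
    x0 <- x[1:(n - lag), , drop = FALSE]
    xt <- x[(1 + lag):n, , drop = FALSE]
    c0 <- c0 + crossprod(x0) + crossprod(xt)
    ct <- ct + crossprod(x0, xt)
    n_pairs <- n_pairs + (n - lag)
  }
  c0 <- c0 / (2 * n_pairs)
  ct <- ct / n_pairs
  ct <- (ct + t(ct)) / 2

  # whiten via Cholesky; ridge if C0 is not positive definite
  ch <- tryCatch(chol(c0), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(ridge)) {
    message("tica: instantaneous covariance near-singular, ridge ", ridge, " applied")
    c0 <- c0 + ridge * diag(d)
    ch <- tryCatch(chol(c0), error = function(e) NULL)
    if (is.null(ch)) {
      abort("covariance rank deficient even after regularization",
        class = "dhalokin_numeric_error"
      )
    }
  }
  li <- backsolve(ch, diag(d), transpose = TRUE) # inv(L) with c0 = L' L? chol gives U: c0 = U'U
  m <- li %*% ct %*% t(li)
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  if (sum(abs(eg$values) > 1e-12) < n_components) {
    abort("covariance rank below n_components after regularization",
      class = "dhalokin_numeric_error"
    )
  }
  comps <- t(li) %*% eg$vectors[, seq_len(n_components), drop = FALSE]
  vals <- eg$values[seq_len(n_components)]
  if (any(abs(vals) > 1 + 1e-8)) {
    warn("tica eigenvalue magnitude exceeds 1; check lag/sampling")
  }
  proj <- do.call(rbind, purrr::map(blocks, function(b) sweep(b, 2, mu) %*% comps))
  structure(
    list(
      components = comps, eigenvalues = vals, projections = proj,
      lag = lag, mean = mu
    ),
    class = "tica"
  )
}

#' Cluster TICA projections into microstates
#'
#' k-means clustering (seeded, deterministic) of projected frames into
#' microstates. Any empty cluster is re-seeded on the farthest frames and
#' logged. The conventional production setting is 200 clusters; synthetic
#' tests run with far fewer.
#'
#' @param projections Numeric matrix (frames x dims).
#' @param n_clusters Number of microstates, >= 2 and <= number of frames.
#' @param seed Integer seed.
#' @param iter_max,nstart Passed to [stats::kmeans()].
#' @return A list with `assignments` (integer vector, 1-based) and
#'   `centers`.
#' @export
cluster_microstates <- function(projections, n_clusters, seed = 1L,
                                iter_max = 100, nstart = 5) {
  x <- as.matrix(projections)
  if (n_clusters > nrow(x)) {
    abort("n_clusters must be <= number of frames",
      class = "dhalokin_contract_error"
    )
  }
  if (n_clusters < 1) abort("n_clusters must be >= 1", class = "dhalokin_contract_error")
  if (n_clusters == nrow(x)) {
    return(list(assignments = seq_len(nrow(x)), centers = x))
  }
  km <- with_seed(seed, function() {
    stats::kmeans(x, centers = n_clusters, iter.max = iter_max, nstart = nstart)
  })
  sizes <- tabulate(km$cluster, n_clusters)
  if (any(sizes == 0)) {
    message("cluster_microstates: re-seeded ", sum(sizes == 0), " empty cluster(s)")
  }
  list(assignments = km$cluster, centers = km$centers)
}
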