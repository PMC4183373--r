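# PCA of chain-opening trajectories. The covariance is computed over the
# non-clamp openings only; the particle coordinate is carried alongside the
# projections but never mixed into the covariance (it is binned separately
# by the Markov-network stage).

#' Principal component analysis of opening trajectories
#'
#' Pools the frames of all realizations, centers them, and diagonalizes the
#' covariance matrix of the masked (non-clamp) openings. Components are
#' ordered by decreasing eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive (deterministic downstream binning).
#'
#' @param trajectories A `breath_trajectory` or list of them.
#' @param mask Logical vector selecting analysis sites (default: the chain's
#'   non-clamp mask, taken from `chain`).
#' @param chain Optional [encode_chain()] supplying the mask.
#' @return An object of class `breath_pca`: `center`, `eigenvalues`
#'   (descending, clipped at 0), `eigenvectors` (orthonormal columns),
#'   `explained_fraction`, `mask`, `n_frames`.
#' @export
fit_pca <- function(trajectories, mask = NULL, chain = NULL) {
  if (inherits(trajectories, "breath_trajectory"))
    trajectories <- list(trajectories)
  nc <- ncol(trajectories[[1L]]$Y)
  if (is.null(mask)) {
    mask <- if (!is.null(chain)) chain$mask else rep(TRUE, nc)
  }
  # accumulate sufficient statistics per realization rather than pooling all
  # frames into one matrix: large ensembles would not fit in memory otherwise
  n <- 0L
  s <- numeric(sum(mask))
  S <- matrix(0, sum(mask), sum(mask))
  for (t in trajectories) {
    if (ncol(t$Y) != nc) stop("trajectories have inconsistent widths")
    Ym <- t$Y[, mask, drop = FALSE]
    n <- n + nrow(Ym)
    s <- s + colSums(Ym)
    S <- S + crossprod(Ym)
  }
  if (n < 2L) stop("need at least 2 frames for a covariance")
  ctr <- s / n
  cv <- (S - n * tcrossprod(ctr)) / (n - 1)
  cv <- (cv + t(cv)) / 2
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(center = ctr, eigenvalues = vals, eigenvectors = vecs,
                 explained_fraction = vals / sum(vals), mask = mask,
                 n_frames = n),
            class = "breath_pca")
}

#' @export
print.breath_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("breath_pca: %d sites, %d frames; first %d components explain %.1f%% of fluctuations\n",
              length(x$center), x$n_frames, k, 100 * explained_by(x, k)))
  invisible(x)
}

#' Project a trajectory onto leading principal components
#'
#' Centers each frame and multiplies onto the first `n_pc` eigenvectors; the
#' particle coordinate is appended unchanged as the extra reaction
#' coordinate.
#'
#' @param traj A `breath_trajectory`.
#' @param pca A [fit_pca()] result.
#' @param n_pc Number of components to keep (default 5).
#' @return An object of class `breath_projection`: `scores` (frames x n_pc),
#'   `x` (particle coordinate per frame), `realization_id`.
#' @export
project_trajectory <- function(traj, pca, n_pc = 5L) {
  stopifnot(inherits(pca, "breath_pca"))
  n_pc <- as.integer(n_pc)
  if (n_pc < 1L || n_pc > ncol(pca$eigenvectors))
    stop("n_pc must be in 1..", ncol(pca$eigenvectors))
  if (ncol(traj$Y) != length(pca$mask))
    stop("trajectory width does not match the PCA basis")
  Ym <- traj$Y[, pca$mask, drop = FALSE]
  scores <- sweep(Ym, 2, pca$center) %*%
    pca$eigenvectors[, seq_len(n_pc), drop = FALSE]
  structure(list(scores = scores, x = traj$x,
                 realization_id = traj$realization_id),
            class = "breath_projection")
}

#' Reconstruct masked openings from projected coordinates
#'
#' Inverse of [project_trajectory()]; lossless at full rank.
#'
#' @param proj A `breath_projection`.
#' @param pca The [fit_pca()] result used for projection.
#' @return Matrix of reconstructed masked openings (frames x masked sites).
#' @export
reconstruct_trajectory <- function(proj, pca) {
  n_pc <- ncol(proj$scores)
  rec <- proj$scores %*% t(pca$eigenvectors[, seq_len(n_pc), drop = FALSE])
  sweep(rec, 2, pca$center, "+")
}

#' Cumulative fraction of fluctuations captured by leading components
#'
#' @param pca A [fit_pca()] result.
#' @param n_pc Number of leading components (0 allowed).
#' @return Fraction in `[0, 1]`.
#' @export
explained_by <- function(pca, n_pc) {
  stopifnot(inherits(pca, "breath_pca"))
  n_pc <- as.integer(n_pc)
  if (n_pc < 0L || n_pc > length(pca$explained_fraction))
    stop("n_pc must be in 0..", length(pca$explained_fraction))
  if (n_pc == 0L) return(0)
  sum(pca$explained_fraction[seq_len(n_pc)])
}

#' Eigenvector localization over labeled sequence regions
#'
#' For each of the first `n_components` eigenvectors, computes the share of
#' squared amplitude falling in each user-labeled region and the
#' participation ratio `PR = 1 / sum_n v_n^4` (for an orthonormal
#' eigenvector), i.e. the effective number of sites the component spans.
#' A delocalized component has `PR ~ N`; a component localized on a soft
#' promoter window has small `PR` and a large squared-amplitude share there.
#'
#' @param pca A [fit_pca()] result.
#' @param regions Named list of integer vectors of masked-site indices
#'   (1-based positions within the masked chain). Regions must be disjoint
#'   and jointly cover all masked sites.
#' @param n_components Number of leading components to report (default 4).
#' @return A data.frame with one row per component: `component`,
#'   `participation_ratio`, and one squared-amplitude share column per
#'   region.
#' @export
eigenvector_localization <- function(pca, regions, n_components = 4L) {
  stopifnot(inherits(pca, "breath_pca"))
  n <- length(pca$center)
  idx <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(idx)) stop("regions overlap")
  if (!setequal(idx, seq_len(n)))
    stop("regions must partition the ", n, " masked sites")
  n_components <- min(as.integer(n_components), ncol(pca$eigenvectors))
  out <- data.frame(component = seq_len(n_components),
                    participation_ratio = NA_real_)
  for (rn in names(regions)) out[[rn]] <- NA_real_
  for (j in seq_len(n_components)) {
    v <- pca$eigenvectors[, j]
    v <- v / sqrt(sum(v^2))
    out$participation_ratio[j] <- 1 / sum(v^4)
    for (rn in names(regions))
      out[[rn]][j] <- sum(v[regions[[rn]]]^2)
  }
  out
}
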