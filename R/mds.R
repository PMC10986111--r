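# Classical (Torgerson) multidimensional scaling of population distances.

#' Classical multidimensional scaling
#'
#' Torgerson's metric MDS: square the dissimilarities, double-centre
#' (B = -1/2 * J D2 J), eigendecompose, and take the top-m eigenvectors
#' scaled by the square roots of their eigenvalues. When the input matrix is
#' exactly Euclidean-embeddable in m dimensions the pairwise Euclidean
#' distances of the coordinates reproduce it to machine precision. The sign
#' of each axis is fixed by forcing its largest-magnitude coordinate
#' positive, so plots are deterministic.
#'
#' FST matrices can contain slightly negative entries (sampling noise);
#' passing a `ystr_fst` clamps them to zero before embedding, as MDS needs
#' non-negative dissimilarities. An all-zero matrix embeds as all points at
#' the origin (not an error).
#'
#' @param d symmetric non-negative dissimilarity matrix with zero diagonal,
#'   or a `ystr_fst` object (negatives clamped to 0).
#' @param m number of dimensions, at most k - 1 for k objects.
#' @return Object of class `ystr_mds`: list with `coordinates` (k x m,
#'   centred at the origin), `eigenvalues` (all k, descending) and
#'   `goodness` (share of positive-eigenvalue mass captured by the m axes;
#'   `NA` for a zero matrix).
#' @export
classical_mds <- function(d, m = 2L) {
  if (inherits(d, "ystr_fst")) d <- pmax(d$values, 0)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    .ystr_stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8)
    .ystr_stop("d must be symmetric")
  if (any(d < 0))
    .ystr_stop("d must be non-negative (clamp FST estimates upstream)")
  k <- nrow(d)
  m <- as.integer(m)
  if (m < 1L || m > k - 1L)
    .ystr_stop(sprintf("m must be between 1 and k-1 = %d", k - 1L),
               "ystr_config_error")
  D2 <- d^2
  J <- diag(k) - 1 / k
  Bmat <- -0.5 * J %*% D2 %*% J
  e <- eigen((Bmat + t(Bmat)) / 2, symmetric = TRUE)
  coords <- matrix(0, k, m)
  for (a in seq_len(m)) {
    lam <- e$values[a]
    if (lam > 1e-12) {
      v <- e$vectors[, a] * sqrt(lam)
      if (v[which.max(abs(v))] < 0) v <- -v
      coords[, a] <- v
    }
  }
  dimnames(coords) <- list(rownames(d), paste0("dim", seq_len(m)))
  pos <- e$values[e$values > 1e-12]
  goodness <- if (length(pos) == 0) NA_real_
              else sum(pmax(e$values[seq_len(m)], 0)) / sum(pos)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 goodness = goodness),
            class = "ystr_mds")
}

#' @export
print.ystr_mds <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d objects in %d dimensions (goodness %s)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              ifelse(is.na(x$goodness), "NA", sprintf("%.3f", x$goodness))))
  print(round(x$coordinates, 4))
  invisible(x)
}
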