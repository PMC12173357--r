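#' Fuse selected components through their first principal component
#'
#' The `m` selected components, on a common uniform grid, form the columns
#' of a matrix `X`. Columns are centered (and, by default, scaled to unit
#' variance so seconds-valued interval series and amplitude-valued series
#' weigh equally -- disable with `normalize = FALSE` for covariance-only
#' PCA). The covariance matrix of the columns is eigendecomposed, and the
#' fused respiratory waveform is the projection of `X` onto the unit
#' eigenvector of the largest eigenvalue. The eigenvector sign is fixed so
#' its largest-magnitude loading is positive, making the output
#' deterministic.
#'
#' @param rmcs List of `uniform_series` (or `filtered_rmc` carrying
#'   `values`) of identical length on a common grid; or a numeric matrix
#'   with the series as columns.
#' @param normalize Scale each centered column to unit variance.
#' @param component_tags Optional character tags for the columns.
#' @return A `fused_waveform`: list with `values` (the fused series),
#'   `loadings` (unit first-eigenvector weights), `explained_variance_ratio`,
#'   `component_tags`.
#' @export
fuse_components <- function(rmcs, normalize = TRUE, component_tags = NULL) {
  if (is.matrix(rmcs)) {
    X <- rmcs
  } else {
    lens <- vapply(rmcs, function(s) length(s$values), 0L)
    if (length(unique(lens)) != 1)
      rf_data_error("components must share one grid (lengths: %s)",
                    paste(lens, collapse = ", "))
    X <- vapply(rmcs, function(s) s$values, numeric(lens[1]))
    if (is.null(component_tags))
      component_tags <- vapply(rmcs, function(s)
        if (!is.null(s$component)) s$component else NA_character_, "")
  }
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  L <- nrow(X); m <- ncol(X)
  if (L < 32) rf_short_window("fusion needs series of length >= 32, got %d", L)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  sds <- apply(Xc, 2, stats::sd)
  if (all(sds == 0)) rf_degenerate("all components constant; nothing to fuse")
  if (normalize) {
    nz <- sds > 0
    Xc[, nz] <- sweep(Xc[, nz, drop = FALSE], 2, sds[nz], "/")
  }
  P <- stats::cov(Xc)
  eg <- eigen(P, symmetric = TRUE)     # eigenvalues already descending
  v1 <- eg$vectors[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  ev <- pmax(eg$values, 0)
  structure(list(values = as.numeric(Xc %*% v1),
                 loadings = v1,
                 explained_variance_ratio = ev[1] / sum(ev),
                 component_tags = component_tags),
            class = "fused_waveform")
}
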