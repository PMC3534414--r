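#' Correspondence analysis of a metabolite x time-point table
#'
#' Classical correspondence analysis of a nonnegative table: the chi-square
#' standardized residual matrix is decomposed, inertia fractions are the
#' squared singular values over the total inertia, and principal coordinates
#' are returned for rows and columns. The decomposition is delegated to
#' \code{vegan::cca} (unconstrained CA).
#'
#' Normalized profiles can contain negative values; those rows are shifted by
#' their minimum to nonnegativity before the analysis (recorded in
#' \code{shifted_rows}), since a correspondence table must be nonnegative.
#'
#' @param x numeric matrix (metabolites x time points) or a
#'   [profile_matrix()] (replicate means are used).
#' @return Object of class \code{ca_result}: \code{row_coordinates},
#'   \code{column_coordinates} (principal coordinates, one column per axis),
#'   \code{inertia_fractions}, \code{shifted_rows}.
#' @export
correspondence_analysis <- function(x) {
  if (inherits(x, "profile_matrix"))
    x <- apply(x$values, c(1, 2), mean, na.rm = TRUE)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("col%d", seq_len(ncol(x)))
  row_min <- apply(x, 1, min)
  shifted <- rownames(x)[row_min < 0]
  if (length(shifted) > 0)
    x[row_min < 0, ] <- x[row_min < 0, , drop = FALSE] - row_min[row_min < 0]
  if (any(x < 0)) stop_usage("correspondence table must be nonnegative")
  zr <- rowSums(x) == 0
  if (any(zr))
    stop_usage("all-zero row in correspondence table: ",
               paste(rownames(x)[zr], collapse = ", "))
  zc <- colSums(x) == 0
  if (any(zc))
    stop_usage("all-zero column in correspondence table: ",
               paste(colnames(x)[zc], collapse = ", "))
  fit <- vegan::cca(x)
  eig <- fit$CA$eig
  naxes <- length(eig)
  # vegan stores weighted-orthonormal axes; principal coordinates scale the
  # unit-variance scores u, v by the singular values sqrt(eig)
  row_pc <- fit$CA$u %*% diag(sqrt(eig), naxes)
  col_pc <- fit$CA$v %*% diag(sqrt(eig), naxes)
  dimnames(row_pc) <- list(rownames(x), names(eig))
  dimnames(col_pc) <- list(colnames(x), names(eig))
  structure(list(row_coordinates = row_pc, column_coordinates = col_pc,
                 inertia_fractions = eig / sum(eig),
                 total_inertia = sum(eig), shifted_rows = shifted),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  fr <- x$inertia_fractions
  cat(sprintf("correspondence analysis: %d axes; first two explain %.1f%% of inertia\n",
              length(fr), 100 * sum(fr[seq_len(min(2, length(fr)))])))
  invisible(x)
}
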