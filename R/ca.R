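#' Correspondence analysis of a gene-by-signal count matrix
#'
#' Classical correspondence analysis of the non-negative matrix of per-gene
#' stop-signal counts.  With `P` the matrix of proportions (counts divided
#' by the grand total), row masses `r` and column masses `c`, the
#' standardized residuals `S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)` are
#' decomposed by SVD; row principal coordinates are `u_ik sigma_k /
#' sqrt(r_i)` and column coordinates the analog in `v`.  The total inertia
#' `sum_k sigma_k^2` equals the Pearson chi-square statistic of the table
#' divided by its grand total.  Because CA analyzes row profiles, running
#' it on raw counts is equivalent to analyzing each gene's Genic-TSSR while
#' keeping proper (total-count) masses.
#'
#' Axis signs are fixed deterministically: on every axis the column with
#' the largest absolute coordinate is made positive.  All-zero rows carry
#' no profile and are dropped with a message.
#'
#' @param counts Numeric matrix (genes x signals) of non-negative values;
#'   typically a [tss_count()] matrix.
#' @param naxes Maximum number of axes to keep; default all
#'   (`min(dim) - 1`).
#' @return An object of class `tssr_ca`: list with `row_coords`,
#'   `col_coords`, `singular_values`, `inertia` (total), `inertia_share`,
#'   `row_masses`, `col_masses`, `N` (grand total) and `dropped` (ids of
#'   all-zero rows).
#' @examples
#' m <- diag(3) * 10
#' tssr_ca(m)$inertia  # 2: maximal association in a 3x3 table
#' @export
tssr_ca <- function(counts, naxes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  dropped <- character(0)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    dropped <- if (is.null(rownames(counts))) as.character(which(zero))
               else rownames(counts)[zero]
    message(sprintf("dropped %d all-zero row(s)", sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("correspondence analysis needs at least 2 rows and 2 columns")
  N <- sum(counts)
  if (N <= 0) stop("grand total must be positive")
  P <- counts / N
  r <- rowSums(P)
  cm <- colSums(P)
  if (any(cm == 0)) {
    # empty signal classes carry no inertia; keep them with zero coordinates
    keep <- cm > 0
    S <- (P[, keep, drop = FALSE] - outer(r, cm[keep])) /
      sqrt(outer(r, cm[keep]))
  } else {
    keep <- rep(TRUE, ncol(P))
    S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  }
  k <- min(nrow(S), sum(keep)) - 1L
  if (is.null(naxes)) naxes <- k else naxes <- min(naxes, k)
  sv <- svd(S)
  sig <- sv$d[seq_len(naxes)]
  U <- sv$u[, seq_len(naxes), drop = FALSE]
  V <- sv$v[, seq_len(naxes), drop = FALSE]
  colF <- matrix(0, ncol(P), naxes,
                 dimnames = list(colnames(P), paste0("Axis", seq_len(naxes))))
  colF[keep, ] <- V * rep(sig, each = sum(keep)) / sqrt(cm[keep])
  # deterministic sign: largest-|loading| column coordinate positive per axis
  for (a in seq_len(naxes)) {
    j <- which.max(abs(colF[, a]))
    if (length(j) && colF[j, a] < 0) {
      colF[, a] <- -colF[, a]
      U[, a] <- -U[, a]
    }
  }
  rowF <- U * rep(sig, each = nrow(U)) / sqrt(r)
  dimnames(rowF) <- list(rownames(counts), paste0("Axis", seq_len(naxes)))
  inertia <- sum(sv$d^2)
  structure(list(row_coords = rowF, col_coords = colF,
                 singular_values = sig,
                 inertia = inertia,
                 inertia_share = if (inertia > 0) sig^2 / inertia
                                 else rep(NA_real_, naxes),
                 row_masses = r, col_masses = cm, N = N, dropped = dropped),
            class = "tssr_ca")
}

#' @export
print.tssr_ca <- function(x, ...) {
  cat(sprintf("Correspondence analysis: %d rows x %d columns, %d axes\n",
              nrow(x$row_coords), nrow(x$col_coords), length(x$singular_values)))
  cat(sprintf("  total inertia %.5g\n", x$inertia))
  sh <- utils::head(x$inertia_share, 4L)
  cat("  axis inertia share:", paste(sprintf("%.1f%%", 100 * sh), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.tssr_ca <- function(object, ...) {
  data.frame(axis = seq_along(object$singular_values),
             singular_value = object$singular_values,
             inertia = object$singular_values^2,
             share = object$inertia_share)
}

#' Reproducible uniform gene subsample
#'
#' Draws `n` items without replacement, uniformly, from a gene collection.
#' Used to mirror the published protocol of analyzing a fixed-size random
#' subset of genes per genome.  When `seed` is given the sample is
#' reproducible and the caller's random number state is left untouched.
#'
#' @param genes A vector (e.g. gene ids), a `tssr_genes` data frame, or a
#'   matrix with one gene per row.
#' @param n Sample size; must not exceed the population size.
#' @param seed Optional integer seed.
#' @return An object of the same kind as `genes`, holding the sampled rows
#'   or elements (in sampled order).
#' @export
sample_genes <- function(genes, n, seed = NULL) {
  size <- if (is.data.frame(genes) || is.matrix(genes)) nrow(genes)
          else length(genes)
  if (n > size) stop(sprintf("cannot sample %d of %d genes", n, size))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  idx <- sample.int(size, n)
  if (is.data.frame(genes) || is.matrix(genes)) genes[idx, , drop = FALSE]
  else genes[idx]
}

#' Group centroids and confidence ellipses on the first CA plane
#'
#' Summarizes labeled genes on CA axes 1-2: the centroid is the
#' mass-weighted mean of the member row coordinates, and the confidence
#' region is the data ellipse of the member coordinates -- the 2x2
#' covariance scaled by the chi-square quantile with 2 degrees of freedom
#' (5.991 at the 0.95 level), so the ellipse is expected to contain about
#' `level` of the group's genes under bivariate normality.
#'
#' @param result A `tssr_ca` object with at least 2 axes.
#' @param groups Group label per analyzed gene: a vector aligned with the
#'   rows of `result$row_coords` (or named by row).
#' @param level Coverage level of the ellipse, default 0.95.
#' @return A data frame of class `tssr_group_summary`: `group`, `n`,
#'   centroid (`axis1`, `axis2`), ellipse semi-axes and orientation angle
#'   (radians).  Full 2x2 covariances are kept in `attr(, "ellipses")`.
#'   Groups with fewer than 3 members get `NA` ellipses (centroid still
#'   reported).
#' @export
ca_group_summary <- function(result, groups, level = 0.95) {
  stopifnot(inherits(result, "tssr_ca"))
  if (ncol(result$row_coords) < 2L) stop("need at least 2 CA axes")
  xy <- result$row_coords[, 1:2, drop = FALSE]
  if (!is.null(names(groups))) groups <- groups[rownames(xy)]
  if (length(groups) != nrow(xy))
    stop("'groups' must label every analyzed gene")
  if (anyNA(groups)) stop("'groups' must label every analyzed gene")
  groups <- as.factor(groups)
  r2 <- stats::qchisq(level, df = 2)
  ell <- list()
  rows <- lapply(levels(groups), function(g) {
    sel <- groups == g
    w <- result$row_masses[sel] / sum(result$row_masses[sel])
    cen <- colSums(xy[sel, , drop = FALSE] * w)
    if (sum(sel) >= 3L) {
      V <- stats::cov(xy[sel, , drop = FALSE])
      eg <- eigen(V, symmetric = TRUE)
      eval <- pmax(eg$values, 0)
      semi <- sqrt(eval * r2)
      ang <- atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L])
      ell[[g]] <<- list(center = cen, cov = V, level = level, radius2 = r2)
    } else {
      semi <- c(NA_real_, NA_real_)
      ang <- NA_real_
      ell[[g]] <<- NULL
    }
    data.frame(group = g, n = sum(sel), axis1 = cen[1L], axis2 = cen[2L],
               semi_major = semi[1L], semi_minor = semi[2L], angle = ang)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ellipses") <- ell
  attr(out, "level") <- level
  class(out) <- c("tssr_group_summary", "data.frame")
  out
}

#' Points on a group's confidence ellipse
#'
#' @param summary A `tssr_group_summary`.
#' @param group Group label.
#' @param n Number of boundary points.
#' @return A two-column matrix of ellipse boundary coordinates, or `NULL`
#'   when the group's ellipse is undefined.
#' @export
ellipse_points <- function(summary, group, n = 180L) {
  e <- attr(summary, "ellipses")[[as.character(group)]]
  if (is.null(e)) return(NULL)
  eg <- eigen(e$cov, symmetric = TRUE)
  semi <- sqrt(pmax(eg$values, 0) * e$radius2)
  th <- seq(0, 2 * pi, length.out = n)
  pts <- cbind(semi[1L] * cos(th), semi[2L] * sin(th)) %*% t(eg$vectors)
  sweep(pts, 2L, e$center, "+")
}

#' Scatter plot of CA row coordinates with group ellipses
#'
#' @param x A `tssr_ca` object.
#' @param groups Optional group labels per gene; when given, points are
#'   colored by group and 95% ellipses and centroids are drawn.
#' @param axes Which two axes to plot (default 1:2; ellipses are only drawn
#'   on axes 1:2).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tssr_ca <- function(x, groups = NULL, axes = c(1L, 2L), ...) {
  xy <- x$row_coords[, axes, drop = FALSE]
  lab <- sprintf("Axis %d (%.1f%%)", axes, 100 * x$inertia_share[axes])
  if (is.null(groups)) {
    graphics::plot(xy, xlab = lab[1L], ylab = lab[2L], pch = 20,
                   col = grDevices::grey(0.4), ...)
  } else {
    g <- as.factor(groups)
    cols <- grDevices::hcl.colors(nlevels(g), "Dark 3")
    graphics::plot(xy, xlab = lab[1L], ylab = lab[2L], pch = 20,
                   col = cols[as.integer(g)], ...)
    if (identical(sort(axes), c(1L, 2L))) {
      gs <- ca_group_summary(x, groups)
      for (i in seq_len(nrow(gs))) {
        pts <- ellipse_points(gs, gs$group[i])
        if (!is.null(pts)) graphics::lines(pts, col = cols[i], lwd = 2)
        graphics::points(gs$axis1[i], gs$axis2[i], pch = 3, cex = 1.5,
                         col = cols[i], lwd = 2)
      }
    }
    graphics::legend("topright", legend = levels(g), col = cols, pch = 20,
                     bty = "n")
  }
  invisible(x)
}
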