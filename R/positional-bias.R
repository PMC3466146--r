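#' Replication layout of a circular chromosome
#'
#' Bundles the chromosome length, the replication origin (Ori) and terminus
#' (Ter) coordinates, and the window size (genes per side) used to pick the
#' genes "near" Ori and Ter.  Coordinates are 1-based on the circular
#' chromosome.
#'
#' @param length Chromosome length in nucleotides.
#' @param ori,ter Ori and Ter coordinates (1-based, distinct).
#' @param window_n Genes selected on each side of Ori and of Ter
#'   (default 100, i.e. 200 Ori genes and 200 Ter genes in total).
#' @return A list of class `chromosome_config`.
#' @export
chromosome_config <- function(length, ori, ter, window_n = 100L) {
  length <- as.numeric(length)
  stopifnot(length >= 2, ori >= 1, ori <= length, ter >= 1, ter <= length,
            window_n >= 1)
  if (ori == ter) stop("ori and ter must differ")
  structure(list(length = length, ori = as.numeric(ori),
                 ter = as.numeric(ter), window_n = as.integer(window_n)),
            class = "chromosome_config")
}

# forward (clockwise, increasing-coordinate) arc length from a to b
arc_forward <- function(a, b, L) (b - a) %% L

# circular midpoint of a 1-based inclusive [start, end] that may wrap
circular_midpoint <- function(start, end, L) {
  span <- ((end - start) %% L) + 1
  ((start - 1 + (span - 1) / 2) %% L) + 1
}

#' Assign genes to replichore, strand orientation and Ori/Ter windows
#'
#' Each gene is reduced to its circular midpoint and categorized three
#' ways.  Replichore: the chromosome arc running from Ori in increasing
#' coordinate (mod length) to Ter is the Right replichore, the
#' complementary arc the Left.  Orientation: Forward for `+`-strand genes,
#' Reverse for `-`.  Proximity: on each side of Ori (lower and higher
#' coordinate, circularly) the `window_n` genes with midpoints nearest Ori
#' are labeled `Ori`; likewise for `Ter`; all other genes are `none`.
#' Nearest-gene ties are broken by gene id so the assignment is
#' deterministic.
#'
#' @param locations A `tssr_locations` data frame (see
#'   [read_gene_locations()]); its `chromosome_length` attribute is ignored
#'   in favor of `cfg$length`.
#' @param cfg A [chromosome_config()].
#' @return A data frame of class `tssr_categories`: `gene_id`, `midpoint`,
#'   `replichore` (`Left`/`Right`), `orientation` (`Forward`/`Reverse`) and
#'   `proximity` (`Ori`/`Ter`/`none`).
#' @export
assign_categories <- function(locations, cfg) {
  stopifnot(inherits(cfg, "chromosome_config"),
            all(c("gene_id", "start", "end", "strand") %in% names(locations)))
  L <- cfg$length
  mid <- circular_midpoint(locations$start, locations$end, L)
  repli <- ifelse(arc_forward(cfg$ori, mid, L) < arc_forward(cfg$ori, cfg$ter, L),
                  "Right", "Left")
  orient <- ifelse(locations$strand == "+", "Forward", "Reverse")

  pick_window <- function(anchor) {
    fwd <- arc_forward(anchor, mid, L)     # distance going to higher coords
    bwd <- arc_forward(mid, anchor, L)     # distance going to lower coords
    high <- fwd <= bwd                     # gene sits on the higher-coordinate side
    d <- pmin(fwd, bwd)
    sel_side <- function(side) {
      i <- which(side)
      if (length(i) < cfg$window_n)
        stop(sprintf("only %d gene(s) on one side of coordinate %g; need %d",
                     length(i), anchor, cfg$window_n))
      i[order(d[i], locations$gene_id[i])][seq_len(cfg$window_n)]
    }
    c(sel_side(high), sel_side(!high))
  }
  ori_idx <- pick_window(cfg$ori)
  ter_idx <- pick_window(cfg$ter)
  if (length(intersect(ori_idx, ter_idx)))
    stop("Ori and Ter windows overlap; reduce window_n or check coordinates")
  prox <- rep("none", nrow(locations))
  prox[ori_idx] <- "Ori"
  prox[ter_idx] <- "Ter"
  out <- data.frame(gene_id = locations$gene_id, midpoint = mid,
                    replichore = repli, orientation = orient, proximity = prox,
                    stringsAsFactors = FALSE)
  class(out) <- c("tssr_categories", "data.frame")
  out
}

#' Mean TSSR profile of a gene group
#'
#' The per-signal arithmetic mean of a set of Genic-TSSR vectors (the
#' "average percentage of counts" of each signal over the group).
#'
#' @param genes Numeric matrix (genes x 9) of Genic-TSSR rows, or a single
#'   9-vector.
#' @return Named numeric 9-vector.
#' @export
mean_profile <- function(genes) {
  genes <- as_counts_matrix(genes)
  if (nrow(genes) == 0L) stop("empty gene group")
  out <- colMeans(genes)
  names(out) <- tssr_signals()
  out
}

#' Kolmogorov-Smirnov distance between two 9-bin signal distributions
#'
#' The two-sided KS statistic over the nine ordered signal categories:
#' both profiles are renormalized to sum 1, accumulated in canonical signal
#' order, and `D` is the maximum vertical deviation between the two
#' cumulative curves.
#'
#' @param a,b Numeric 9-vectors (non-negative; renormalized internally).
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  stopifnot(length(a) == length(b))
  max(abs(cumsum(a / sum(a)) - cumsum(b / sum(b))))
}

#' Permutation KS test between two gene groups' TSSR profiles
#'
#' Compares the TSSR profiles of two equal-sized gene groups with the
#' discrete KS statistic and calibrates it by resampling.  The observed `D`
#' is computed between the two group profiles (by default the per-signal
#' mean of the groups' Genic-TSSR rows).  The two groups are then pooled
#' and, in each of `M` resamplings, partitioned uniformly at random into
#' two disjoint halves of the original sizes (sampling with replacement is
#' available as an option); the permutation p-value is `p = sum_m I(D_m >=
#' D) / M`.  Also reported are the two observed group mean profiles and,
#' for each, the sample standard deviation over its nine entries -- a
#' scalar summary of how uneven the signal usage is within the group.
#'
#' @param a,b Numeric matrices (genes x 9) of per-gene profiles, one row
#'   per gene; the groups must be the same size.  Rows may be Genic-TSSR
#'   proportions or raw counts (see `profile`).
#' @param M Number of resamplings, default 1000.
#' @param seed Optional integer seed; when given the result is fully
#'   reproducible and the caller's random number state is restored.
#' @param profile `"mean"` (default): a group's profile is the mean of its
#'   rows, each row first renormalized to sum 1, so every gene has equal
#'   weight.  `"pooled"`: the rows are summed and then normalized, so genes
#'   with larger totals weigh more (only meaningful for count input).
#' @param replace Resample with replacement instead of partitioning the
#'   pool (default `FALSE`, a disjoint split).
#' @return An object of class `tssr_ks`: list with `D`, `p.value`, `M`,
#'   `seed`, `group_means` (2 x 9), `sd_of_means` (length 2) and the
#'   options used.
#' @export
tssr_ks_test <- function(a, b, M = 1000L, seed = NULL,
                         profile = c("mean", "pooled"), replace = FALSE) {
  profile <- match.arg(profile)
  a <- as_counts_matrix(a)
  b <- as_counts_matrix(b)
  if (nrow(a) != nrow(b))
    stop("the two gene groups must be the same size (got ",
         nrow(a), " and ", nrow(b), ")")
  nA <- nrow(a)
  if (nA + nrow(b) < 2L) stop("pooled group too small")
  M <- as.integer(M)
  if (M < 1L) stop("M must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  grp_profile <- if (profile == "mean") {
    function(m) colMeans(m / rowSums(m))
  } else {
    function(m) colSums(m) / sum(m)
  }
  mA <- grp_profile(a)
  mB <- grp_profile(b)
  D <- ks_statistic(mA, mB)
  pool <- rbind(a, b)
  n <- nrow(pool)
  Dm <- numeric(M)
  if (!replace) {
    # disjoint split: pre-normalize once and derive the complement's
    # profile from the pooled column totals
    w <- if (profile == "mean") pool / rowSums(pool) else pool
    tot <- colSums(w)
    for (m in seq_len(M)) {
      sA <- colSums(w[sample.int(n, nA), , drop = FALSE])
      pA <- sA / sum(sA)
      pB <- (tot - sA) / sum(tot - sA)
      Dm[m] <- max(abs(cumsum(pA) - cumsum(pB)))
    }
  } else {
    for (m in seq_len(M)) {
      ia <- sample.int(n, nA, replace = TRUE)
      ib <- sample.int(n, nA, replace = TRUE)
      Dm[m] <- ks_statistic(grp_profile(pool[ia, , drop = FALSE]),
                            grp_profile(pool[ib, , drop = FALSE]))
    }
  }
  # small tolerance so relabelings reproducing the observed split count as >=
  p <- mean(Dm >= D - 1e-12)
  gm <- rbind(A = mA, B = mB)
  colnames(gm) <- tssr_signals()
  structure(list(D = D, p.value = p, M = M, seed = seed,
                 group_means = gm,
                 sd_of_means = c(A = stats::sd(mA), B = stats::sd(mB)),
                 profile = profile, replace = replace, n_per_group = nA),
            class = "tssr_ks")
}

#' @export
print.tssr_ks <- function(x, ...) {
  cat("Permutation Kolmogorov-Smirnov test on 9-bin TSSR profiles\n")
  cat(sprintf("  %d genes per group, profile = %s\n", x$n_per_group, x$profile))
  cat(sprintf("  D = %.4f, p = %.4g (M = %d resamplings%s)\n",
              x$D, x$p.value, x$M,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  SD of group mean profiles: %.6f / %.6f\n",
              x$sd_of_means[1L], x$sd_of_means[2L]))
  invisible(x)
}

#' Positional bias screen of a chromosome
#'
#' Convenience wrapper reproducing the full positional analysis: genes are
#' categorized by [assign_categories()], and for each of the three paired
#' contrasts -- Left vs Right replichore, Forward vs Reverse orientation,
#' Ori vs Ter proximity -- equal-sized groups are compared with
#' [tssr_ks_test()].  For the replichore and orientation contrasts the
#' comparison is restricted to the windowed (Ori + Ter) genes, as in the
#' published protocol, and groups are trimmed to equal size by dropping the
#' genes farthest from their anchor (ties by gene id).
#'
#' @param counts Gene-by-9 count matrix ([tss_count()]), rows named by
#'   gene id.
#' @param locations Gene location table covering (at least) those genes.
#' @param cfg A [chromosome_config()].
#' @param M,seed Passed to [tssr_ks_test()].
#' @return A list of class `tssr_bias` with one `tssr_ks` per contrast
#'   (`replichore`, `orientation`, `proximity`) plus the category
#'   assignment.
#' @export
tssr_bias_test <- function(counts, locations, cfg, M = 1000L, seed = NULL) {
  counts <- as_counts_matrix(counts)
  if (is.null(rownames(counts))) stop("'counts' must have gene ids as row names")
  cats <- assign_categories(locations, cfg)
  sel <- cats$proximity != "none"
  win <- cats[sel, ]
  ratios <- suppressWarnings(genic_tssr(counts[match(win$gene_id,
                                                     rownames(counts)), ,
                                               drop = FALSE]))
  if (anyNA(ratios))
    stop("windowed genes include zero-signal or unknown genes")
  equalize <- function(fac) {
    # trim the larger side to the smaller, deterministically by gene id
    nmin <- min(table(fac))
    keep <- unlist(lapply(split(seq_len(nrow(win)), fac), function(i)
      i[order(win$gene_id[i])][seq_len(nmin)]), use.names = FALSE)
    sort(keep)
  }
  run <- function(fac, seed_off) {
    keep <- equalize(fac)
    s <- fac[keep]
    lv <- sort(unique(s))
    tssr_ks_test(ratios[keep[s == lv[1L]], , drop = FALSE],
                 ratios[keep[s == lv[2L]], , drop = FALSE],
                 M = M, seed = if (is.null(seed)) NULL else seed + seed_off)
  }
  out <- list(replichore = run(win$replichore, 0L),
              orientation = run(win$orientation, 1L),
              proximity = run(win$proximity, 2L),
              categories = cats)
  class(out) <- "tssr_bias"
  out
}

#' @export
print.tssr_bias <- function(x, ...) {
  for (nm in c("replichore", "orientation", "proximity")) {
    cat(sprintf("-- %s --\n", nm))
    print(x[[nm]])
  }
  invisible(x)
}
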