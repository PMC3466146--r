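#' All 64 codons, the 3 stop trimers, and the 61 sense codons
#' @noRd
all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_TRIMERS)

#' Codon usage model for gene simulation
#'
#' Defines the generative model behind [simulate_genes()]: a gene is `n`
#' body codons drawn from `sense` (i.i.d., or first-order Markov when a
#' junction bias is set) followed by one terminal stop codon drawn from
#' `stop`.  When `sense` is not supplied it is built from an
#' independent-nucleotide composition at the given GC fraction (each codon
#' proportional to the product of its base frequencies, stop trimers
#' excluded and the rest renormalized) -- a standard null model whose only
#' parameter is GC content.
#'
#' Off-frame stop signals arise in this model exclusively at codon
#' junctions: a frame-2 signal when the last two bases of one codon plus
#' the first base of the next form TAA/TAG/TGA, a frame-3 signal from the
#' last base plus the next codon's first two.  `junction_bias` injects
#' frame-specific effects for power studies: a named factor such as
#' `c("TGA.2" = 2)` multiplies the transition weight of every codon pair
#' forming that signal (here: frame-2 TGA pairs made twice as frequent),
#' and body codons become a Markov chain with row-normalized transitions
#' `T(c2 | c1) proportional to sense(c2) * bias(c1, c2)`.
#'
#' @param sense Named probability vector over the 61 sense codons (sums to
#'   1), or `NULL` to derive it from `gc`.
#' @param stop Named probability vector over `c("TAA","TAG","TGA")`.  The
#'   default (0.631, 0.076, 0.293) is the in-frame stop usage implied by
#'   the published pooled E. coli K-12 stop counts.
#' @param length Body codon count: a single integer for fixed-length genes
#'   or a length-2 integer range for uniform sampling.
#' @param gc GC fraction used when `sense` is `NULL` (default 0.508,
#'   E. coli-like).
#' @param junction_bias Optional named numeric factor(s) on signal classes
#'   (names from [tssr_signals()], frames 2-3 only), e.g. `c("TGA.2" = 2)`.
#' @return An object of class `codon_usage`.
#' @export
codon_usage <- function(sense = NULL, stop = c(TAA = 0.631, TAG = 0.076,
                                               TGA = 0.293),
                        length = 300L, gc = 0.508, junction_bias = NULL) {
  if (is.null(sense)) {
    p <- c(T = (1 - gc) / 2, C = gc / 2, A = (1 - gc) / 2, G = gc / 2)
    cods <- sense_codons()
    w <- apply(matrix(unlist(strsplit(cods, "")), nrow = 3L), 2L,
               function(b) prod(p[b]))
    sense <- stats::setNames(w / sum(w), cods)
  }
  if (!setequal(names(sense), sense_codons()))
    stop("'sense' must be named by the 61 sense codons")
  sense <- sense[sense_codons()]
  if (any(sense < 0) || abs(sum(sense) - 1) > 1e-12)
    stop("'sense' must be a probability vector summing to 1")
  if (!setequal(names(stop), STOP_TRIMERS))
    stop("'stop' must be named TAA, TAG, TGA")
  stop <- stop[STOP_TRIMERS]
  if (any(stop < 0) || abs(sum(stop) - 1) > 1e-12)
    stop("'stop' must be a probability vector summing to 1")
  length <- as.integer(length)
  if (!length(length) %in% 1:2 || any(length < 1L))
    stop("'length' must be a positive codon count or range")
  if (!is.null(junction_bias)) {
    ok <- names(junction_bias) %in% tssr_signals()[4:9]
    if (is.null(names(junction_bias)) || !all(ok) || any(junction_bias < 0))
      stop("'junction_bias' must be non-negative and named by frame-2/3 signals")
  }
  structure(list(sense = sense, stop = stop, length = length,
                 junction_bias = junction_bias,
                 transition = junction_transition(sense, junction_bias)),
            class = "codon_usage")
}

# row-stochastic 61x61 transition matrix over sense codons; NULL when the
# body codons are i.i.d. (no junction bias)
junction_transition <- function(sense, bias) {
  if (is.null(bias)) return(NULL)
  cods <- names(sense)
  W <- matrix(rep(sense, each = length(cods)), nrow = length(cods),
              dimnames = list(cods, cods))
  for (nm in names(bias)) {
    s <- sub("\\..$", "", nm)
    fr <- as.integer(sub("^.*\\.", "", nm))
    hit <- if (fr == 2L) {
      outer(substr(cods, 2L, 3L), substr(cods, 1L, 1L), paste0) == s
    } else {
      outer(substr(cods, 3L, 3L), substr(cods, 1L, 2L), paste0) == s
    }
    W[hit] <- W[hit] * bias[[nm]]
  }
  W / rowSums(W)
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage model: %s body codons, %s\n",
              paste(x$length, collapse = "-"),
              if (is.null(x$junction_bias)) "i.i.d. sense codons"
              else paste("junction bias",
                         paste(names(x$junction_bias), x$junction_bias,
                               sep = "=", collapse = ", "))))
  cat("  stop usage:", paste(sprintf("%s %.3f", names(x$stop), x$stop),
                             collapse = ", "), "\n")
  invisible(x)
}

draw_lengths <- function(model, n_genes) {
  if (length(model$length) == 1L) rep(model$length, n_genes)
  else sample(model$length[1L]:model$length[2L], n_genes, replace = TRUE)
}

#' Simulate coding sequences from a codon usage model
#'
#' Each gene is an independent draw from the model: body codons from the
#' sense usage (i.i.d., or the junction-biased Markov chain), one terminal
#' stop from the stop usage.  Sense codons contain no stop trimer, so every
#' simulated gene has exactly one frame-1 signal -- its stop codon.
#'
#' @param model A [codon_usage()] model.
#' @param n_genes Number of genes.
#' @param seed Optional integer seed (caller's random state is restored).
#' @param prefix Gene id prefix, default `"gene"`.
#' @return A `tssr_genes` data frame (columns `gene_id`, `sequence`).
#' @export
simulate_genes <- function(model, n_genes, seed = NULL, prefix = "gene") {
  stopifnot(inherits(model, "codon_usage"), n_genes >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- draw_lengths(model, n_genes)
  cods <- names(model$sense)
  if (is.null(model$transition)) {
    body <- sample(cods, sum(n), replace = TRUE, prob = model$sense)
    gene_of <- rep.int(seq_len(n_genes), n)
    bodies <- vapply(split(body, gene_of), paste0, "", collapse = "")
  } else {
    # Markov body: advance all genes one codon position at a time,
    # sampling the successor within groups that share the current codon
    maxn <- max(n)
    cur <- sample.int(length(cods), n_genes, replace = TRUE,
                      prob = model$sense)
    seqs <- matrix(NA_integer_, nrow = n_genes, ncol = maxn)
    seqs[, 1L] <- cur
    for (pos in 2L:maxn) {
      alive <- which(n >= pos)
      for (c1 in unique(seqs[alive, pos - 1L])) {
        g <- alive[seqs[alive, pos - 1L] == c1]
        seqs[g, pos] <- sample.int(length(cods), length(g), replace = TRUE,
                                   prob = model$transition[c1, ])
      }
    }
    bodies <- vapply(seq_len(n_genes), function(i)
      paste0(cods[seqs[i, seq_len(n[i])]], collapse = ""), "")
  }
  stops <- sample(STOP_TRIMERS, n_genes, replace = TRUE, prob = model$stop)
  out <- data.frame(gene_id = sprintf("%s%05d", prefix, seq_len(n_genes)),
                    sequence = unname(paste0(bodies, stops)),
                    stringsAsFactors = FALSE)
  class(out) <- c("tssr_genes", "data.frame")
  out
}

#' Exact expected stop-signal counts under a codon usage model
#'
#' The analytic oracle for [simulate_genes()]: the expected value of each
#' of the nine [tss_count()] counters for a gene with `n` body codons.
#' Frame-1 expectations equal the stop usage (the terminal stop is the only
#' in-frame signal).  Off-frame signals occur only at codon junctions, so
#' the frame-2/3 expectation is the sum over the `n - 1` body junctions --
#' plus the body-to-stop junction, which can never complete a stop trimer
#' (every stop starts with T, and no stop trimer has T in second or third
#' position) but is included for completeness -- of the pair-probability
#' mass on signal-forming codon pairs, enumerated exactly over all pairs.
#' Under a junction bias the body codons form a Markov chain and the
#' position marginals are propagated through the transition matrix before
#' summing.
#'
#' @param model A [codon_usage()] model.
#' @param n Body codon count; defaults to the model's fixed length.
#' @return Named numeric 9-vector of expected counts.
#' @export
expected_tss_counts <- function(model, n = NULL) {
  stopifnot(inherits(model, "codon_usage"))
  if (is.null(n)) {
    if (length(model$length) != 1L)
      stop("give 'n' explicitly for a variable-length model")
    n <- model$length
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  cods <- names(model$sense)
  out <- stats::setNames(numeric(9L), tssr_signals())
  out[1:3] <- model$stop
  # signal indicators over ordered sense-codon pairs
  match2 <- lapply(STOP_TRIMERS, function(s)
    outer(substr(cods, 2L, 3L), substr(cods, 1L, 1L), paste0) == s)
  match3 <- lapply(STOP_TRIMERS, function(s)
    outer(substr(cods, 3L, 3L), substr(cods, 1L, 2L), paste0) == s)
  if (n >= 2L) {
    if (is.null(model$transition)) {
      pair <- outer(model$sense, model$sense) * (n - 1L)
    } else {
      m <- model$sense          # marginal at position 1
      pair <- matrix(0, length(cods), length(cods))
      for (i in seq_len(n - 1L)) {
        pair <- pair + m * model$transition
        m <- as.vector(m %*% model$transition)
      }
    }
    for (s in 1:3) {
      out[3L + s] <- out[3L + s] + sum(pair[match2[[s]]])
      out[6L + s] <- out[6L + s] + sum(pair[match3[[s]]])
    }
  }
  # body -> stop junction (always zero-mass on signals; kept for completeness)
  mlast <- model$sense
  if (!is.null(model$transition) && n >= 2L)
    for (i in seq_len(n - 1L)) mlast <- as.vector(mlast %*% model$transition)
  for (s in 1:3) {
    m2 <- outer(substr(cods, 2L, 3L), substr(STOP_TRIMERS, 1L, 1L),
                paste0) == STOP_TRIMERS[s]
    m3 <- outer(substr(cods, 3L, 3L), substr(STOP_TRIMERS, 1L, 2L),
                paste0) == STOP_TRIMERS[s]
    pairBS <- outer(mlast, model$stop)
    out[3L + s] <- out[3L + s] + sum(pairBS[m2])
    out[6L + s] <- out[6L + s] + sum(pairBS[m3])
  }
  out
}

#' Normalized expected Genic-TSSR of a codon usage model
#'
#' @inheritParams expected_tss_counts
#' @return Named 9-vector of expected counts normalized to sum 1.
#' @export
expected_tssr <- function(model, n = NULL) {
  e <- expected_tss_counts(model, n)
  e / sum(e)
}

#' Simulate a genome: genes plus a circular chromosome layout
#'
#' Simulates `n_genes` coding sequences and places them head-to-tail with
#' fixed intergenic gaps on a circular chromosome sized to fit exactly.
#' Each gene's strand is an independent fair coin flip (the stored sequence
#' is always the coding strand; the strand only affects the location
#' record).
#'
#' @param model A [codon_usage()] model.
#' @param n_genes Number of genes.
#' @param seed Optional integer seed.
#' @param gap Intergenic gap in nucleotides, default 50.
#' @param prefix Gene id prefix.
#' @return A list with `genes` (a `tssr_genes` data frame) and `locations`
#'   (a `tssr_locations` data frame whose `chromosome_length` attribute is
#'   the total length).
#' @export
simulate_genome <- function(model, n_genes, seed = NULL, gap = 50L,
                            prefix = "gene") {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  genes <- simulate_genes(model, n_genes, prefix = prefix)
  len <- nchar(genes$sequence)
  L <- sum(len) + n_genes * gap
  start <- cumsum(c(1L, utils::head(len + gap, -1L)))
  strand <- ifelse(stats::runif(n_genes) < 0.5, "+", "-")
  loc <- data.frame(gene_id = genes$gene_id, start = start,
                    end = start + len - 1L, strand = strand,
                    stringsAsFactors = FALSE)
  attr(loc, "chromosome_length") <- L
  class(loc) <- c("tssr_locations", "data.frame")
  list(genes = genes, locations = loc)
}

#' Read a codon usage table
#'
#' TSV with header and columns `codon`, `probability`; must contain the 61
#' sense codons and the 3 stop trimers, each block summing to 1.
#'
#' @param path Path to the TSV file.
#' @param ... Passed to [codon_usage()] (e.g. `length`, `junction_bias`).
#' @return A `codon_usage` model.
#' @export
read_codon_usage <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "probability") %in% names(tab)))
    stop("usage table needs columns 'codon' and 'probability'")
  p <- stats::setNames(tab$probability, toupper(tab$codon))
  codon_usage(sense = p[sense_codons()] / sum(p[sense_codons()]),
              stop = p[STOP_TRIMERS] / sum(p[STOP_TRIMERS]), ...)
}
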