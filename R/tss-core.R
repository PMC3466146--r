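#' Canonical translation stop signal names
#'
#' The nine translation stop signal (TSS) classes, in the fixed column order
#' used throughout the package: the three stop trimers TAA, TAG, TGA on
#' reading frame 1 (in-frame stop codons), then frames 2 and 3 (off-frame,
#' "premature" or "hidden" stop codons).
#'
#' @return Character vector of length 9: `"TAA.1"`, `"TAG.1"`, `"TGA.1"`,
#'   `"TAA.2"`, ..., `"TGA.3"`.
#' @export
tssr_signals <- function() {
  as.vector(t(outer(1:3, c("TAA", "TAG", "TGA"),
                    function(f, s) paste(s, f, sep = "."))))
}

STOP_TRIMERS <- c("TAA", "TAG", "TGA")

#' Coerce input to a character vector of canonical CDS sequences
#'
#' Accepts a character vector, a `tssr_genes` data frame (from
#' [read_cds_fasta()] or [simulate_genes()]), or a Biostrings `XStringSet`.
#' Sequences are uppercased and RNA `U` is mapped to `T`.
#' @noRd
as_cds_sequences <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "sequence") %in% names(x)))
      stop("data frame input must have 'gene_id' and 'sequence' columns")
    seqs <- as.character(x$sequence)
    names(seqs) <- as.character(x$gene_id)
  } else if (methods::is(x, "XStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop("cannot interpret 'x' as CDS sequences")
  }
  chartr("u", "T", chartr("U", "T", toupper(seqs)))
}

#' Count translation stop signals on the three reading frames
#'
#' Scans each coding sequence for the trimers TAA, TAG and TGA on all three
#' reading frames of the coding strand.  Frame `f` consists of the trimer
#' windows starting at 0-based offsets congruent to `f - 1` modulo 3, so
#' frame 1 is the codon frame (its single expected signal is the terminal
#' stop codon) and frames 2 and 3 hold the off-frame premature stop signals.
#' A window counts only if it matches a stop trimer exactly; windows
#' containing any non-ACGT character (e.g. IUPAC ambiguity codes) never
#' match.  Sequences whose length is not a multiple of 3 are accepted --
#' counting only requires complete trimer windows -- but are reported with a
#' warning, since a well-formed CDS should be a whole number of codons.
#'
#' @param x Coding sequences: a character vector (optionally named by gene
#'   id), a `tssr_genes` data frame, or a Biostrings `XStringSet`.  Each
#'   element is one gene on its coding strand, 5'->3', stop codon included.
#' @return An integer matrix with one row per gene and nine columns in the
#'   order given by [tssr_signals()].
#' @examples
#' tss_count("ATGGTAAGGGTGAGTATAATGGTAGCCGGTGGTTAA")
#' @export
tss_count <- function(x) {
  seqs <- as_cds_sequences(x)
  n <- length(seqs)
  out <- matrix(0L, nrow = n, ncol = 9L,
                dimnames = list(names(seqs), tssr_signals()))
  if (n == 0L) return(out)
  n_ragged <- sum(nchar(seqs) %% 3L != 0L)
  if (n_ragged > 0L)
    warning(sprintf("%d sequence(s) have length not a multiple of 3", n_ragged))
  for (s in 1:3) {
    # stop trimers cannot overlap themselves, so a left-to-right
    # non-overlapping fixed search finds every occurrence
    hits <- gregexpr(STOP_TRIMERS[s], seqs, fixed = TRUE)
    for (i in seq_len(n)) {
      p <- hits[[i]]
      if (p[1L] == -1L) next
      out[i, (0:2) * 3L + s] <- tabulate((p - 1L) %% 3L + 1L, nbins = 3L)
    }
  }
  out
}

as_counts_matrix <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  if (ncol(counts) != 9L)
    stop("expected 9 signal columns, got ", ncol(counts))
  if (any(counts < 0)) stop("negative signal counts are not allowed")
  counts
}

#' Genic translation stop signal ratio
#'
#' Normalizes each gene's nine stop signal counts to proportions summing to
#' one (the Genic-TSSR).  A gene with no signal at all has an undefined
#' ratio; its row is returned as `NA` with a warning so the caller can
#' decide whether to exclude it.
#'
#' @param counts A gene-by-9 count matrix from [tss_count()], or a single
#'   9-vector.
#' @return A numeric matrix of the same shape (a 9-vector input returns a
#'   named 9-vector); each defined row sums to 1.
#' @examples
#' genic_tssr(c(1, 0, 0, 2, 1, 1, 1, 1, 1))
#' @export
genic_tssr <- function(counts) {
  vec_in <- is.null(dim(counts))
  counts <- as_counts_matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning(sprintf("%d gene(s) have zero stop signals; ratios set to NA",
                    sum(tot == 0)))
  out <- counts / ifelse(tot > 0, tot, NA_real_)
  colnames(out) <- tssr_signals()
  if (vec_in) out[1L, ] else out
}

#' Per-frame translation stop signal ratio
#'
#' The TSSR-1, TSSR-2 or TSSR-3 of a gene: that frame's TAA:TAG:TGA counts
#' normalized to proportions.  Undefined (all-`NA` with a warning) for genes
#' with no signal on the selected frame.
#'
#' @inheritParams genic_tssr
#' @param frame Reading frame, 1, 2 or 3.
#' @return Matrix (or named 3-vector for vector input) with columns TAA,
#'   TAG, TGA.
#' @export
frame_tssr <- function(counts, frame) {
  stopifnot(length(frame) == 1L, frame %in% 1:3)
  vec_in <- is.null(dim(counts))
  counts <- as_counts_matrix(counts)
  sub <- counts[, (frame - 1L) * 3L + 1:3, drop = FALSE]
  tot <- rowSums(sub)
  if (any(tot == 0))
    warning(sprintf("%d gene(s) have zero frame-%d signals; ratios set to NA",
                    sum(tot == 0), frame))
  out <- sub / ifelse(tot > 0, tot, NA_real_)
  colnames(out) <- STOP_TRIMERS
  if (vec_in) out[1L, ] else out
}

#' Genomic translation stop signal ratio
#'
#' Summarizes a set of genes into one genome-level 9-vector (the
#' Genomic-TSSR).  Two conventions are supported.  `"pooled"` (the default)
#' sums the nine counters over all genes and divides by the grand total;
#' this is the arithmetic behind the published per-genome tables.  `"mean"`
#' averages the per-gene Genic-TSSR vectors, giving every gene equal weight
#' regardless of its length; genes with zero signals are excluded from the
#' average (they contribute nothing to the pooled form either).
#'
#' @param counts Gene-by-9 count matrix from [tss_count()].
#' @param mode `"pooled"` or `"mean"`.
#' @return Named numeric 9-vector summing to 1.
#' @export
genomic_tssr <- function(counts, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  counts <- as_counts_matrix(counts)
  tot <- rowSums(counts)
  if (nrow(counts) == 0L || all(tot == 0))
    stop("no genes with stop signals: Genomic-TSSR is undefined")
  out <- if (mode == "pooled") {
    colSums(counts) / sum(counts)
  } else {
    keep <- tot > 0
    colMeans(suppressWarnings(genic_tssr(counts[keep, , drop = FALSE])))
  }
  names(out) <- tssr_signals()
  out
}

#' Genomic per-frame translation stop signal ratio
#'
#' The genome-level TSSR-1/2/3: as [genomic_tssr()] restricted to one
#' frame's three counters.
#'
#' @inheritParams genomic_tssr
#' @param frame Reading frame, 1, 2 or 3.
#' @return Named numeric 3-vector (TAA, TAG, TGA) summing to 1.
#' @export
genomic_frame_tssr <- function(counts, frame, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(frame) == 1L, frame %in% 1:3)
  counts <- as_counts_matrix(counts)
  sub <- counts[, (frame - 1L) * 3L + 1:3, drop = FALSE]
  tot <- rowSums(sub)
  if (nrow(sub) == 0L || all(tot == 0))
    stop(sprintf("no genes with frame-%d signals: ratio is undefined", frame))
  out <- if (mode == "pooled") {
    colSums(sub) / sum(sub)
  } else {
    colMeans(sub[tot > 0, , drop = FALSE] / tot[tot > 0])
  }
  names(out) <- STOP_TRIMERS
  out
}
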