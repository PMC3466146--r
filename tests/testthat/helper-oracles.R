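# Independent oracles used across the suite.  These deliberately take the
# slowest, most literal route so they share no code path with the package.

# Scan every start position p, classify any stop-trimer match by p mod 3.
naive_tss_count <- function(seq) {
  seq <- chartr("Uu", "TT", toupper(seq))
  out <- stats::setNames(integer(9L), tssr_signals())
  L <- nchar(seq)
  if (L >= 3L) {
    for (p in 1:(L - 2L)) {
      s <- match(substr(seq, p, p + 2L), c("TAA", "TAG", "TGA"))
      if (!is.na(s)) {
        f <- (p - 1L) %% 3L
        out[f * 3L + s] <- out[f * 3L + s] + 1L
      }
    }
  }
  out
}

# Complete-linkage merge heights, recomputing every max pairwise distance
# from scratch at each step.
brute_complete_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (h < best) {
          best <- h
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T", "N")) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# leaf-set bipartitions induced by a rooted binary tree, as sorted strings
tree_partitions <- function(phy) {
  parts <- lapply(ape::prop.part(phy), function(i)
    paste(sort(phy$tip.label[i]), collapse = "|"))
  sort(unlist(parts))
}

# Usage models emulating the two extremes of the published per-gene cloud
# contrast: an AT-rich, TAA-dominated signal profile (Rickettsia-like) and
# a GC-rich, TGA-dominated one (Neisseria-like).
atrich_usage <- function(length = 300L) {
  codon_usage(gc = 0.32, length = length,
              stop = c(TAA = 0.8, TAG = 0.1, TGA = 0.1),
              junction_bias = c(TAA.2 = 2, TAA.3 = 2))
}
gcrich_usage <- function(length = 300L) {
  codon_usage(gc = 0.55, length = length,
              stop = c(TAA = 0.4, TAG = 0.1, TGA = 0.5),
              junction_bias = c(TGA.2 = 3, TGA.3 = 3))
}

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fna",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}
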