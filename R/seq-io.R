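#' Read protein-coding sequences from a multi-FASTA file
#'
#' Reads one nucleotide CDS per FASTA record (coding strand, 5'->3').
#' Sequences are uppercased and RNA `U` is mapped to `T`.  The gene id is
#' the first whitespace-separated token of the header; duplicated ids are
#' disambiguated with a numeric suffix (and a message).  Genes annotated as
#' spanning multiple reading frames -- headers containing the
#' case-insensitive substring `"authentic frameshift"` -- are dropped by
#' default, since a frameshifted CDS has no single well-defined set of
#' reading frames.
#'
#' @param path Path to a (optionally gzip-compressed) multi-FASTA file.
#' @param exclude_frameshift Drop records whose header marks an authentic
#'   frameshift?  Default `TRUE`.
#' @return A data frame of class `tssr_genes` with columns `gene_id`,
#'   `sequence` and `header`; the number of excluded records is in
#'   `attr(, "n_excluded")`.
#' @export
read_cds_fasta <- function(path, exclude_frameshift = TRUE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- chartr("Uu", "TT", toupper(as.character(ss)))
  n_excluded <- 0L
  if (isTRUE(exclude_frameshift) && length(headers)) {
    drop <- grepl("authentic frameshift", headers, ignore.case = TRUE)
    n_excluded <- sum(drop)
    if (n_excluded > 0L) {
      message(sprintf("excluded %d 'authentic frameshift' gene(s)", n_excluded))
      headers <- headers[!drop]
      seqs <- seqs[!drop]
    }
  }
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    message(sprintf("%d duplicate gene id(s) suffixed to make ids unique",
                    sum(duplicated(ids))))
    ids <- make.unique(ids)
  }
  out <- data.frame(gene_id = ids, sequence = unname(seqs), header = headers,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("tssr_genes", "data.frame")
  out
}

#' Write coding sequences to a FASTA file
#'
#' @param genes A `tssr_genes` data frame (columns `gene_id`, `sequence`).
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path, width = 60L) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "sequence") %in% names(genes)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- if ("header" %in% names(genes)) genes$header else genes$gene_id
  for (i in seq_len(nrow(genes))) {
    s <- genes$sequence[i]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", hdr[i]), substring(s, starts, starts + width - 1L)),
               con)
  }
  invisible(path)
}

#' @export
print.tssr_genes <- function(x, ...) {
  cat(sprintf("%d coding sequence(s); lengths %s nt\n", nrow(x),
              if (nrow(x)) paste(range(nchar(x$sequence)), collapse = "-") else "0"))
  if (nrow(x)) {
    show <- utils::head(x$gene_id, 6L)
    cat("  ", paste(show, collapse = ", "),
        if (nrow(x) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read a genome TSSR profile table
#'
#' A profile table is a TSV file with a header line and one row per genome:
#' a `genome_id` column, an optional `subphylum` (or any single grouping)
#' column, then the nine TSSR proportions in canonical signal order (see
#' [tssr_signals()]).  Published tables are rounded, so each row need only
#' sum to 1 within 0.01.
#'
#' @param path Path to the TSV file (optionally gzip-compressed).
#' @return A data frame of class `tssr_profiles`: `genome_id`, `subphylum`
#'   (`NA` when absent from the file), and the nine signal columns.
#' @seealso [tssr_table2()] for the packaged 61-genome table,
#'   [profile_matrix()] to extract the numeric matrix.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("cannot read profile table: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 10L) {
    tab <- data.frame(tab[1L], subphylum = rep(NA_character_, nrow(tab)),
                      tab[2:10], check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else if (ncol(tab) != 11L) {
    stop("profile table must have genome_id [+ subphylum] + 9 ratio columns; ",
         "got ", ncol(tab), " columns")
  }
  names(tab) <- c("genome_id", "subphylum", tssr_signals())
  for (j in 3:11)   # header-only files type empty columns as logical
    if (is.logical(tab[[j]])) tab[[j]] <- as.numeric(tab[[j]])
  tab$genome_id <- as.character(tab$genome_id)
  tab$subphylum <- as.character(tab$subphylum)
  ratios <- as.matrix(tab[, 3:11])
  if (nrow(tab) && !is.numeric(ratios))
    stop("non-numeric ratio cell in profile table")
  if (anyDuplicated(tab$genome_id))
    stop("duplicate genome_id in profile table: ",
         paste(unique(tab$genome_id[duplicated(tab$genome_id)]), collapse = ", "))
  if (nrow(tab) && (any(ratios < 0) || any(abs(rowSums(ratios) - 1) > 0.01)))
    stop("profile rows must be non-negative and sum to 1 (within 0.01)")
  class(tab) <- c("tssr_profiles", "data.frame")
  tab
}

#' @rdname read_profile_table
#' @param table A `tssr_profiles` data frame.
#' @export
write_profile_table <- function(table, path) {
  stopifnot(inherits(table, "tssr_profiles") || is.data.frame(table))
  out <- table
  if (all(is.na(out$subphylum))) out$subphylum <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the numeric profile matrix from a profile table
#'
#' @param x A `tssr_profiles` data frame.
#' @return Numeric matrix (genomes x 9) with genome ids as row names.
#' @export
profile_matrix <- function(x) {
  stopifnot(is.data.frame(x), all(tssr_signals() %in% names(x)))
  m <- as.matrix(x[, tssr_signals()])
  rownames(m) <- x$genome_id
  m
}

#' The published 61-genome Genomic-TSSR table
#'
#' Loads the packaged table of published Genomic-TSSR vectors (3-decimal
#' precision) for 61 alpha-, beta- and gamma-proteobacterial genomes,
#' annotated with their subphylum.
#'
#' @return A `tssr_profiles` data frame with 61 rows.
#' @export
tssr_table2 <- function() {
  read_profile_table(system.file("extdata", "table2_genomic_tssr.tsv",
                                 package = "tssr", mustWork = TRUE))
}

#' @export
print.tssr_profiles <- function(x, ...) {
  cat(sprintf("TSSR profile table: %d genome(s) x 9 signals\n", nrow(x)))
  NextMethod()
}

#' Read or write a per-gene stop-signal count table
#'
#' A TSV with a header and one row per gene: `gene_id` then the nine
#' integer counters in canonical order.  This is the on-disk form of a
#' [tss_count()] matrix, used to hand gene-level counts between the
#' command-line steps.
#'
#' @param path Path to the TSV file.
#' @return For the reader, an integer matrix (genes x 9) with gene ids as
#'   row names.
#' @export
read_tss_counts <- function(path) {
  if (!file.exists(path)) stop("cannot read counts table: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 10L)
    stop("counts table must have gene_id + 9 count columns")
  m <- as.matrix(tab[, -1L])
  if (!is.numeric(m) || any(m < 0)) stop("counts must be non-negative numbers")
  rownames(m) <- tab[[1L]]
  colnames(m) <- tssr_signals()
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_tss_counts
#' @param counts Gene-by-9 count matrix.
#' @export
write_tss_counts <- function(counts, path) {
  counts <- as_counts_matrix(counts)
  out <- data.frame(gene_id = if (is.null(rownames(counts)))
    sprintf("gene%05d", seq_len(nrow(counts))) else rownames(counts),
    counts, check.names = FALSE)
  names(out) <- c("gene_id", tssr_signals())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene locations on a circular chromosome
#'
#' The location table is a TSV whose first line declares the chromosome
#' length as `#chromosome_length=<L>`, followed by a header and one row per
#' gene: `gene_id`, `start`, `end`, `strand`.  Coordinates are 1-based and
#' inclusive on a circular chromosome (a gene with `end < start` wraps
#' through the origin of the coordinate system); strand is `+` or `-`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `tssr_locations` with the chromosome
#'   length in `attr(, "chromosome_length")`.
#' @export
read_gene_locations <- function(path) {
  if (!file.exists(path)) stop("cannot read locations table: ", path)
  con <- file(path, open = "rt")
  first <- readLines(con, n = 1L)
  close(con)
  m <- regmatches(first, regexec("^#chromosome_length=([0-9]+)$", first))[[1L]]
  if (length(m) != 2L)
    stop("locations file must start with '#chromosome_length=<L>'")
  len <- as.integer(m[2L])
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "start", "end", "strand") %in% names(tab)))
    stop("locations table needs columns gene_id, start, end, strand")
  if (any(tab$start < 1L | tab$start > len | tab$end < 1L | tab$end > len))
    stop("start/end must lie in 1..chromosome_length (1-based, inclusive)")
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  attr(tab, "chromosome_length") <- len
  class(tab) <- c("tssr_locations", "data.frame")
  tab
}

#' @rdname read_gene_locations
#' @param locations A `tssr_locations` data frame (or any data frame with
#'   `gene_id`, `start`, `end`, `strand` and a `chromosome_length`
#'   attribute).
#' @export
write_gene_locations <- function(locations, path) {
  len <- attr(locations, "chromosome_length")
  if (is.null(len)) stop("locations must carry a 'chromosome_length' attribute")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#chromosome_length=%d", as.integer(len)), con)
  utils::write.table(locations[, c("gene_id", "start", "end", "strand")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
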