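# Amino-acid alignment container and sequence I/O.
#
# Residues are stored as integer codes 1..20 in the canonical order
# A R N D C Q E G H I L K M F P S T W Y V (the order all empirical rate
# matrices in this package use); NA marks missing data.  Gaps and all
# ambiguity codes (X, B, Z, J, U, O, '-', '.', '?', '*') map to NA.

#' Amino-acid alignment
#'
#' Builds an `aa_alignment`, the package's container for an aligned set of
#' protein sequences: an integer matrix (taxa x sites) of residue codes
#' 1..20 in the canonical order `A R N D C Q E G H I L K M F P S T W Y V`,
#' with `NA` for gaps/ambiguous states.
#'
#' @param x a character matrix of one-letter residues, a named character
#'   vector of equal-length sequence strings, or an integer matrix of codes.
#' @param labels taxon names; defaults to `rownames(x)` or `names(x)`.
#' @return an object of class `aa_alignment`.
#' @examples
#' aln <- aa_alignment(c(t1 = "ARND", t2 = "ARNE"))
#' dim(aln$states)
#' @export
aa_alignment <- function(x, labels = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(labels)) labels <- names(x)
    if (is.null(labels)) stop("sequence labels are required")
    nc <- unique(nchar(x))
    if (length(nc) != 1L) stop("sequences have unequal lengths")
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (is.character(x)) {
    if (is.null(labels)) labels <- rownames(x)
    states <- matrix(match(toupper(x), AA_RESIDUES),
                     nrow = nrow(x), ncol = ncol(x))
  } else if (is.numeric(x)) {
    if (is.null(labels)) labels <- rownames(x)
    states <- matrix(as.integer(x), nrow(x), ncol(x))
    if (any(states < 1L | states > 20L, na.rm = TRUE))
      stop("integer states must lie in 1..20 or be NA")
  } else stop("unsupported input type for aa_alignment()")
  if (is.null(labels)) stop("sequence labels are required")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  if (length(labels) != nrow(states)) stop("labels do not match row count")
  if (nrow(states) < 2L) stop("alignment needs at least 2 taxa")
  if (ncol(states) < 1L) stop("alignment needs at least 1 site")
  rownames(states) <- labels
  structure(list(labels = labels, states = states), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d taxa x %d sites (%.1f%% missing)\n",
              nrow(x$states), ncol(x$states),
              100 * mean(is.na(x$states))))
  invisible(x)
}

#' @export
dim.aa_alignment <- function(x) dim(x$states)

#' Convert an alignment back to residue characters
#'
#' @param x an `aa_alignment`.
#' @param missing_char character used for missing cells (default `"-"`).
#' @param ... unused.
#' @return character matrix of one-letter residues.
#' @export
as.character.aa_alignment <- function(x, missing_char = "-", ...) {
  m <- matrix(AA_RESIDUES[x$states], nrow(x$states), ncol(x$states))
  m[is.na(x$states)] <- missing_char
  rownames(m) <- x$labels
  m
}

aln_seq_strings <- function(aln, missing_char = "-") {
  m <- as.character(aln, missing_char = missing_char)
  stats::setNames(apply(m, 1L, paste, collapse = ""), aln$labels)
}

#' Read an amino-acid FASTA alignment
#'
#' @param path file path.
#' @return an `aa_alignment`.
#' @export
read_fasta_aa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^[;#]", lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  aa_alignment(gsub("\\s", "", seqs), labels = labels)
}

#' Write an alignment as FASTA
#'
#' @param aln an `aa_alignment`.
#' @param path output file path.
#' @param width residues per line.
#' @param header optional comment line(s) written before the records,
#'   each prefixed with `;` (a legal FASTA comment).
#' @return `path`, invisibly.
#' @export
write_fasta_aa <- function(aln, path, width = 60L, header = NULL) {
  seqs <- aln_seq_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0(";", header), con)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a relaxed PHYLIP amino-acid alignment
#'
#' Relaxed sequential format: a header line `ntaxa nsites`, then for each
#' taxon a whitespace-delimited name followed by its sequence, which may be
#' split across tokens and lines.  Names may exceed 10 characters (hence
#' "relaxed") but may not contain whitespace.
#'
#' @param path file path.
#' @return an `aa_alignment`.
#' @export
read_phylip_aa <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE)
  ntax <- suppressWarnings(as.integer(toks[1]))
  nsite <- suppressWarnings(as.integer(toks[2]))
  if (is.na(ntax) || is.na(nsite)) stop("malformed PHYLIP header")
  toks <- toks[-(1:2)]
  labels <- character(ntax)
  seqs <- character(ntax)
  i <- 1L
  for (row in seq_len(ntax)) {
    if (i > length(toks)) stop("truncated PHYLIP file")
    labels[row] <- toks[i]; i <- i + 1L
    while (nchar(seqs[row]) < nsite) {
      if (i > length(toks)) stop("truncated PHYLIP file")
      seqs[row] <- paste0(seqs[row], toks[i]); i <- i + 1L
    }
    if (nchar(seqs[row]) != nsite)
      stop("sequence for ", labels[row], " does not match stated site count")
  }
  aa_alignment(stats::setNames(seqs, labels))
}

#' Write an alignment in relaxed sequential PHYLIP format
#'
#' @param aln an `aa_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phylip_aa <- function(aln, path) {
  seqs <- aln_seq_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln$states), ncol(aln$states)), con)
  writeLines(paste(names(seqs), seqs), con)
  invisible(path)
}

#' Read an alignment, sniffing FASTA versus relaxed PHYLIP
#'
#' @param path file path; a leading `>` (after comments) means FASTA.
#' @return an `aa_alignment`.
#' @export
read_alignment_aa <- function(path) {
  lines <- readLines(path, n = 20L, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^[;#]", lines)]
  if (length(lines) && grepl("^>", lines[1])) read_fasta_aa(path)
  else read_phylip_aa(path)
}

#' Empirical residue frequencies of an alignment
#'
#' Observed residue proportions with a small pseudocount per residue so
#' that no frequency is exactly zero (needed for \code{+F} models).
#'
#' @param aln an `aa_alignment`.
#' @param pseudocount added to each residue count scale (default 1e-6).
#' @return numeric vector of 20 frequencies summing to 1.
#' @export
empirical_frequencies <- function(aln, pseudocount = 1e-6) {
  counts <- tabulate(aln$states[!is.na(aln$states)], nbins = 20L)
  f <- counts / max(sum(counts), 1L) + pseudocount
  stats::setNames(f / sum(f), AA_RESIDUES)
}
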