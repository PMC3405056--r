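#' Construct a DNA alignment
#'
#' A light container for an aligned set of DNA sequences: a named character
#' vector of equal-length IUPAC strings with class `dna_alignment`.
#' Ambiguity codes and gaps are permitted and treated as missing data by the
#' likelihood machinery.
#'
#' @param x named character vector of aligned sequences (IUPAC DNA).
#' @return a `dna_alignment` object.
#' @export
dna_alignment <- function(x) {
  if (length(x) == 0) stop("alignment is empty")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x <- toupper(x)
  len <- unique(nchar(x))
  if (length(len) != 1)
    stop("ragged alignment: sequence lengths ", paste(len, collapse = ", "))
  if (len == 0) stop("sequences are empty")
  ok <- vapply(x, is_iupac_dna, logical(1))
  if (!all(ok))
    stop("non-IUPAC sequences: ", paste(names(x)[!ok], collapse = ", "))
  structure(x, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x), "sequences x", nchar(x[[1]]), "sites\n")
  invisible(x)
}

n_sites <- function(aln) nchar(unclass(aln)[[1]])

#' Read an aligned FASTA file
#'
#' @param path FASTA file path.
#' @return a [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  chr <- vapply(as.character(seqs), function(s) paste(toupper(s), collapse = ""),
                character(1))
  dna_alignment(chr)
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln)) {
    writeLines(c(paste0(">", nm), unclass(aln)[[nm]]), con)
  }
  invisible(path)
}

# Collapse an alignment restricted to `taxa` into unique site patterns.
# Returns list(conds = list of 4 x npattern matrices per taxon, weights).
site_patterns <- function(aln, taxa) {
  mat <- do.call(rbind, strsplit(toupper(unclass(aln)[taxa]), ""))
  key <- apply(mat, 2, paste, collapse = "\r")
  idx <- which(!duplicated(key))
  w <- as.vector(table(factor(key, levels = key[idx])))
  conds <- lapply(seq_along(taxa), function(i) {
    .iupac_states[, mat[i, idx], drop = FALSE]
  })
  names(conds) <- taxa
  list(conds = conds, weights = w, index = match(key, key[idx]))
}
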