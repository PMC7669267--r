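# Codon-level machinery for NNK saturation libraries.
#
# An NNK codon has any base at positions 1-2 and G or T at position 3;
# the 32 NNK codons cover all 20 amino acids plus the TAG (amber) stop.

DNA_BASES <- c("A", "C", "G", "T")

#' Amino-acid alphabet of an NNK library
#'
#' The 20 standard amino acids plus `"*"` for stop, the 21 protein-level
#' symbols reachable by an NNK codon.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aaAlphabet()
aaAlphabet <- function() {
  c(sort(unique(unname(Biostrings::GENETIC_CODE[nnkCodons()]))[
    unique(unname(Biostrings::GENETIC_CODE[nnkCodons()])) != "*"]), "*")
}

#' The 32 NNK codons
#'
#' @return Character vector of the 32 codons with third base G or T.
#' @export
#' @examples
#' length(nnkCodons())  # 32
nnkCodons <- function() {
  g <- expand.grid(b3 = c("G", "T"), b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#' Test whether a codon satisfies the NNK degeneracy pattern
#'
#' A library read is only retained if every randomised codon matches NNK:
#' bases 1-2 unrestricted, base 3 in \{G, T\}.
#'
#' @param codon Character vector of 3-letter codons over A/C/G/T.
#' @return Logical vector, `TRUE` where the third base is G or T.
#' @export
#' @examples
#' validateNnkCodon(c("CTG", "CTA", "TAG"))
validateNnkCodon <- function(codon) {
  if (!is.character(codon) || any(nchar(codon) != 3L))
    stop("'codon' must be a character vector of 3-letter codons")
  if (any(!strsplit(paste(codon, collapse = ""), "")[[1]] %in% DNA_BASES))
    stop("codons may only contain A, C, G, T")
  substr(codon, 3L, 3L) %in% c("G", "T")
}

# Vectorised translation; returns NA for codons containing non-ACGT symbols.
translateCodons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa
}

# Split an equal-length vector of gene sequences into a codon matrix
# (reads x codons).
codonMatrix <- function(seqs, nCodons) {
  starts <- 3L * (seq_len(nCodons) - 1L) + 1L
  m <- vapply(starts, function(s) substr(seqs, s, s + 2L),
              character(length(seqs)))
  matrix(m, nrow = length(seqs), ncol = nCodons)
}

#' Classify a variant by mutation count relative to a reference triplet
#'
#' Variants carrying a stop at any randomised position are classed `"stop"`;
#' otherwise the class is the Hamming distance (0-3) to the reference.
#'
#' @param aaTriplet Character vector of 3-letter amino-acid triplets
#'   (21-letter alphabet including `*`).
#' @param reference Single reference triplet, e.g. `"DKE"`.
#' @return Character vector with values in `"stop"`, `"0"`, `"1"`, `"2"`, `"3"`.
#' @export
#' @examples
#' classifyVariant(c("DKE", "ILK", "DK*"), "DKE")
classifyVariant <- function(aaTriplet, reference) {
  stopifnot(is.character(reference), length(reference) == 1L,
            nchar(reference) == 3L)
  ok <- strsplit(paste(c(aaTriplet, reference), collapse = ""), "")[[1]]
  if (any(!ok %in% aaAlphabet()))
    stop("triplets may only contain the 20 amino acids and '*'")
  m <- do.call(rbind, strsplit(aaTriplet, ""))
  r <- strsplit(reference, "")[[1]]
  hasStop <- rowSums(m == "*") > 0L
  dist <- rowSums(m != matrix(r, nrow(m), 3L, byrow = TRUE))
  out <- as.character(dist)
  out[hasStop] <- "stop"
  out
}

#' Enumerate the complete NNK library at the protein level
#'
#' All `21^3 = 9261` amino-acid triplets (20 residues + stop at each of the
#' three randomised positions), annotated with mutation class relative to a
#' reference and the number of NNK codon spellings.
#'
#' @param reference Reference triplet (default `"DKE"`).
#' @return `data.frame` with columns `aa_triplet`, `aa1`, `aa2`, `aa3`,
#'   `class` (see [classifyVariant()]), `n_codon_spellings`.
#' @export
#' @examples
#' lib <- enumerateLibrary()
#' table(lib$class)          # 1 wild type, 57 singles, 1083 doubles, 6859 triples
#' sum(lib$n_codon_spellings)  # 32^3 codon-level triplets
enumerateLibrary <- function(reference = "DKE") {
  aa <- aaAlphabet()
  g <- expand.grid(aa3 = aa, aa2 = aa, aa1 = aa, stringsAsFactors = FALSE)
  df <- data.frame(aa_triplet = paste0(g$aa1, g$aa2, g$aa3),
                   aa1 = g$aa1, aa2 = g$aa2, aa3 = g$aa3,
                   stringsAsFactors = FALSE)
  df <- df[order(df$aa_triplet), , drop = FALSE]
  rownames(df) <- df$aa_triplet
  df$class <- classifyVariant(df$aa_triplet, reference)
  syn <- table(translateCodons(nnkCodons()))
  nSyn <- as.numeric(syn[df$aa1]) * as.numeric(syn[df$aa2]) *
    as.numeric(syn[df$aa3])
  df$n_codon_spellings <- as.integer(nSyn)
  df
}

# NNK synonym table: list mapping each of the 21 symbols to its NNK codons.
nnkSynonyms <- function() {
  split(nnkCodons(), translateCodons(nnkCodons()))
}
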