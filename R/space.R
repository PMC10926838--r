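# Protein-level views of a sequence space: alignment matrix, one-hot
# encoding over variable columns, and pairwise Hamming statistics.

# designs x positions character matrix (proteins are gap-free and equal length)
protein_matrix <- function(space) {
  p <- space$designs$protein
  if (length(unique(nchar(p))) != 1L)
    stop("proteins have unequal lengths; provide an aligned library")
  matrix(unlist(strsplit(p, "", fixed = TRUE), use.names = FALSE),
         nrow = length(p), byrow = TRUE)
}

#' One-hot encode a sequence space for the linear Hamming kernel
#'
#' Builds the binary design-by-feature matrix used by the Gaussian-process
#' surrogate. Every alignment column where more than one residue occurs
#' ("variable column") contributes one indicator feature per residue observed
#' there; invariant columns are dropped since they carry no information. The
#' encoding realizes Hamming similarity as a dot product: for designs i and j,
#' \code{rowSums} are all equal to the number of variable columns \code{V},
#' and \code{x_i . x_j = V - Hamming(i, j)}.
#'
#' @param space A \code{sequence_space}.
#' @return Binary matrix with attributes \code{variable_columns} (0-based
#'   alignment column indices) and \code{residues} (per-feature residue), and
#'   column names \code{"<column>_<residue>"}.
#' @examples
#' sp <- toy_space(c(2, 2))
#' X <- encode_space(sp)
#' V <- length(attr(X, "variable_columns"))
#' stopifnot(all(rowSums(X) == V))
#' @export
encode_space <- function(space) {
  if (!is.null(space$.encoding)) return(space$.encoding)
  M <- protein_matrix(space)
  nres <- apply(M, 2, function(col) length(unique(col)))
  vc <- which(nres > 1L)
  feats <- list()
  for (j in vc) {
    res <- sort(unique(M[, j]))
    block <- vapply(res, function(r) as.numeric(M[, j] == r),
                    numeric(nrow(M)))
    colnames(block) <- paste0(j - 1L, "_", res)
    feats[[length(feats) + 1]] <- block
  }
  X <- if (length(feats)) do.call(cbind, feats) else
    matrix(0, nrow(M), 0)
  attr(X, "variable_columns") <- vc - 1L
  attr(X, "residues") <- sub("^[0-9]+_", "", colnames(X))
  X
}

#' Decode one-hot rows back to residues at the variable columns
#' @param X Encoding from [encode_space()].
#' @return Character matrix of residues, one column per variable column.
#' @export
decode_rows <- function(X) {
  cols <- sub("_.*$", "", colnames(X))
  res <- sub("^[0-9]+_", "", colnames(X))
  vc <- unique(cols)
  out <- vapply(vc, function(v) {
    idx <- which(cols == v)
    res[idx][max.col(X[, idx, drop = FALSE])]
  }, character(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, vc))
  out
}

#' Pairwise Hamming distance matrix of a sequence space
#'
#' Computed through the one-hot identity \code{Hamming = V - X X'} so the
#' heavy lifting is a single BLAS matrix product even for thousands of
#' designs.
#'
#' @param space A \code{sequence_space}.
#' @return Integer design-by-design matrix of substitution counts.
#' @export
hamming_matrix <- function(space) {
  X <- encode_space(space)
  V <- length(attr(X, "variable_columns"))
  D <- V - tcrossprod(X)
  storage.mode(D) <- "integer"
  D
}

#' Pairwise substitution statistics of a sequence space
#'
#' Summarizes the diversity of the library: Hamming distances over all
#' unordered design pairs.
#'
#' @param space A \code{sequence_space}.
#' @return List with \code{mean}, \code{min}, \code{max}, \code{n_pairs} and
#'   \code{histogram} (a \code{table} of distance counts). For a single-design
#'   space all entries are \code{NA}/empty, with a warning.
#' @examples
#' st <- pairwise_distance_stats(toy_space(c(2, 3)))
#' st$mean
#' @export
pairwise_distance_stats <- function(space) {
  n <- nrow(space$designs)
  if (n < 2L) {
    warning("fewer than 2 designs: pairwise statistics are undefined")
    return(list(mean = NA_real_, min = NA_integer_, max = NA_integer_,
                n_pairs = 0L, histogram = table(integer(0))))
  }
  D <- hamming_matrix(space)
  d <- D[upper.tri(D)]
  list(mean = mean(d), min = min(d), max = max(d),
       n_pairs = length(d), histogram = table(d))
}

#' Export a sequence space as FASTA
#'
#' @param space A \code{sequence_space}.
#' @param path Output file.
#' @param what \code{"protein"} or \code{"dna"}.
#' @return \code{path}, invisibly.
#' @export
write_space_fasta <- function(space, path, what = c("protein", "dna")) {
  what <- match.arg(what)
  seqs <- space$designs[[what]]
  names(seqs) <- sprintf("design%04d|%s", space$designs$design,
                         space$designs$short_code)
  set <- if (what == "protein") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Small fully-compatible toy space (for examples and tests)
#'
#' Builds a library with the given number of fragments per segment, all
#' overhangs compatible, and random but reproducible coding sequences, then
#' enumerates it. Handy for demonstrating the assembly-graph machinery on a
#' space whose path count is just the product of the segment sizes.
#'
#' @param sizes Integer vector: fragments per segment.
#' @param aa_len Amino acids per fragment.
#' @param seed RNG seed for the fragment sequences.
#' @return A \code{sequence_space}.
#' @export
toy_space <- function(sizes = c(2, 3, 2), aa_len = 6, seed = 42) {
  enumerate_designs(assembly_graph(toy_fragments(sizes, aa_len, seed)))
}

#' @rdname toy_space
#' @return \code{toy_fragments}: the underlying [fragment_set()].
#' @export
toy_fragments <- function(sizes = c(2, 3, 2), aa_len = 6, seed = 42) {
  with_seed(seed, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ovs <- rep(c("AATG", "GCAA", "TTAC", "CAGT", "GGTA", "TGCC", "ACCG",
                 "TAAT"), length.out = length(sizes) + 1L)
    rows <- list()
    for (s in seq_along(sizes)) {
      for (i in seq_len(sizes[s])) {
        aa <- paste0(sample(aas, aa_len, replace = TRUE), collapse = "")
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("P%dF%d", i, s - 1L), segment = s - 1L,
          left_overhang = ovs[s], right_overhang = ovs[s + 1L],
          dna = reverse_translate(aa), stringsAsFactors = FALSE)
      }
    }
    fragment_set(do.call(rbind, rows))
  })
}

# deterministic reverse translation (first codon per residue, standard code)
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codon_of <- vapply(unique(gc), function(a) names(gc)[gc == a][1],
                     character(1))
  vapply(strsplit(aa, "", fixed = TRUE), function(r)
    paste0(codon_of[r], collapse = ""), character(1))
}
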