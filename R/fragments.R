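#' Read a Golden Gate fragment library
#'
#' Loads DNA fragments that define a combinatorial assembly library. Each
#' fragment belongs to a segment (0-based position along the gene) and carries
#' the two 4-bp overhangs produced by Type IIS digestion; overhang
#' compatibility between adjacent segments defines which fragments can be
#' joined. Fragments are validated and translated on load.
#'
#' Two on-disk formats are supported:
#' \itemize{
#'   \item \code{csv}: columns \code{id, segment, left_overhang,
#'     right_overhang, dna} (an optional \code{aa} column is checked against
#'     the translation if present).
#'   \item \code{fasta}: DNA records with structured headers
#'     \code{id|segment|left_overhang|right_overhang}.
#' }
#'
#' @param path Path to the fragment file.
#' @param format \code{"csv"} or \code{"fasta"}; guessed from the file
#'   extension by default.
#' @return A \code{fragment_set}: a data frame with columns \code{id},
#'   \code{segment}, \code{left_overhang}, \code{right_overhang}, \code{dna},
#'   \code{aa}.
#' @examples
#' frags <- synthetic_fragment_library()
#' tf <- tempfile(fileext = ".csv")
#' write.csv(as.data.frame(frags)[, 1:5], tf, row.names = FALSE)
#' frags2 <- read_fragments(tf)
#' stopifnot(identical(frags$aa, frags2$aa))
#' @seealso [assembly_graph()], [synthetic_fragment_library()]
#' @export
read_fragments <- function(path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "segment", "left_overhang", "right_overhang", "dna")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop("fragment CSV is missing column(s): ",
           paste(missing_cols, collapse = ", "))
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad))
      stop("FASTA headers must be 'id|segment|left|right'; offending record: ",
           names(seqs)[which(bad)[1]])
    parts <- do.call(rbind, parts)
    df <- data.frame(id = parts[, 1],
                     segment = as.integer(parts[, 2]),
                     left_overhang = parts[, 3],
                     right_overhang = parts[, 4],
                     dna = as.character(seqs),
                     stringsAsFactors = FALSE)
  }
  fragment_set(df)
}

#' Construct and validate a fragment set
#'
#' Validates fragment records (4-base overhangs, translatable coding DNA,
#' unique ids, equal amino-acid length within each segment) and attaches the
#' translation.
#'
#' @param df Data frame with columns \code{id}, \code{segment},
#'   \code{left_overhang}, \code{right_overhang}, \code{dna}; optionally
#'   \code{aa}.
#' @return A validated \code{fragment_set} data frame (adds \code{aa}).
#' @export
fragment_set <- function(df) {
  df$id <- as.character(df$id)
  df$segment <- as.integer(df$segment)
  for (col in c("left_overhang", "right_overhang", "dna"))
    df[[col]] <- toupper(as.character(df[[col]]))
  if (anyDuplicated(df$id))
    stop("duplicated fragment id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(is.na(df$segment) | df$segment < 0L))
    stop("segment indices must be non-negative integers")
  ov <- c(df$left_overhang, df$right_overhang)
  bad_ov <- nchar(ov) != 4L | grepl("[^ACGT]", ov)
  if (any(bad_ov))
    stop("overhangs must be 4 bases over {A,C,G,T}; offending value: ",
         ov[which(bad_ov)[1]])
  if (any(nchar(df$dna) %% 3L != 0L))
    stop("coding DNA length must be a multiple of 3")
  aa <- translate_dna(df$dna)
  if (any(grepl("\\*", aa)))
    stop("internal stop codon in fragment ",
         df$id[grep("\\*", aa)[1]])
  if (!is.null(df$aa)) {
    if (!identical(toupper(as.character(df$aa)), aa))
      stop("declared aa column disagrees with translation of dna")
  }
  df$aa <- aa
  # gap-free Hamming comparison downstream requires equal lengths per segment
  for (s in sort(unique(df$segment))) {
    len <- unique(nchar(df$aa[df$segment == s]))
    if (length(len) != 1L)
      stop("fragments in segment ", s, " have unequal amino-acid lengths (",
           paste(len, collapse = ", "),
           "); supply a pre-aligned library")
  }
  df <- df[order(df$segment, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Translate coding DNA with the standard genetic code
#' @param dna Character vector of coding DNA strings (length multiple of 3).
#' @return Character vector of amino-acid strings.
#' @keywords internal
translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(toupper(dna)),
                                     if.fuzzy.codon = "error"))
}

#' @export
print.fragment_set <- function(x, ...) {
  segs <- table(x$segment)
  cat("Fragment library: ", nrow(x), " fragments in ", length(segs),
      " segments (", paste(as.integer(segs), collapse = "/"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[, c("id", "segment",
                                                    "left_overhang",
                                                    "right_overhang")], 8))
  if (nrow(x) > 8) cat("... and", nrow(x) - 8, "more\n")
  invisible(x)
}
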