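#' Synthetic GH1-style combinatorial fragment library
#'
#' A deterministic, fully synthetic stand-in for a four-segment glycoside
#' hydrolase (GH1) Golden Gate library. It is generated in code (no sequence
#' data are shipped) and is engineered to the headline statistics of the
#' published GH1 recombination library it emulates: 34 fragments distributed
#' over 4 segments (8/4/9/13), partial overhang compatibility at the second
#' junction giving exactly 1,352 Start-to-Stop paths, roughly 116 amino-acid
#' substitutions between designs on average with a minimum of 16, and at most
#' 4 distinct residues per alignment column. One segment-1 fragment pair is a
#' near-duplicate differing at exactly 16 positions (setting the minimum
#' pairwise distance), one segment-1 fragment and one segment-2 fragment are
#' dead ends whose overhangs match nothing (as happens in real libraries),
#' and all remaining within-segment fragment pairs differ by well over 16
#' residues.
#'
#' The emulation captures the combinatorial structure of such a library —
#' blockwise sequence exchange, a layered assembly DAG, Hamming geometry —
#' but not real GH1 biochemistry: residue identities are random, so nothing
#' about folding or catalysis is encoded.
#'
#' @param seed Integer seed fixing the residue draws. The default defines the
#'   packaged study conditions; change it only to generate an unrelated
#'   library with the same architecture.
#' @return A [fragment_set()] of 34 fragments with attribute
#'   \code{synthetic = TRUE}.
#' @examples
#' g <- assembly_graph(synthetic_fragment_library())
#' count_paths(g)  # 1352
#' @export
synthetic_fragment_library <- function(seed = 1) {
  n_seg <- c(8L, 4L, 9L, 13L)
  aa_len <- c(118L, 112L, 120L, 110L)
  n_var <- c(51L, 40L, 51L, 48L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    seg_aa <- vector("list", 4L)
    for (s in 1:4) {
      base <- sample(aas, aa_len[s], replace = TRUE)
      var_pos <- sort(sample(aa_len[s], n_var[s]))
      # each variable site offers 4 distinct residues ("up to six per site")
      choices <- lapply(var_pos, function(p) sample(aas, 4L))
      draw <- function() {
        f <- base
        f[var_pos] <- vapply(choices, function(ch) sample(ch, 1L),
                             character(1))
        f
      }
      frs <- lapply(seq_len(n_seg[s]), function(i) draw())
      if (s == 2L) {
        # near-duplicate pair: fragment 2 differs from fragment 1 at exactly
        # 16 sites; this pair sets the library's minimum pairwise distance
        f2 <- frs[[1]]
        flip <- sample(var_pos, 16L)
        for (p in flip) {
          j <- match(p, var_pos)
          f2[p] <- sample(setdiff(choices[[j]], frs[[1]][p]), 1L)
        }
        frs[[2]] <- f2
      }
      # every other within-segment pair must exceed 16 substitutions
      repeat {
        dmat <- outer(seq_along(frs), seq_along(frs), Vectorize(function(i, j)
          sum(frs[[i]] != frs[[j]])))
        diag(dmat) <- NA
        if (s == 2L) dmat[1, 2] <- dmat[2, 1] <- NA
        bad <- which(dmat <= 16L, arr.ind = TRUE)
        if (!nrow(bad)) break
        frs[[max(bad[1, ])]] <- draw()
      }
      seg_aa[[s]] <- vapply(frs, paste0, character(1), collapse = "")
    }
    # overhang architecture: junctions 1 and 3 fully compatible; junction 2
    # partially compatible (13 of 36 possible pairs), yielding 1,352 paths
    right2 <- c("TTAC", "TTAC", "CAGT", "GGTA")            # GGTA: dead end
    left3 <- c(rep("TTAC", 5), rep("CAGT", 3), "ACCG")      # ACCG: dead end
    rows <- list()
    for (s in 1:4) {
      for (i in seq_len(n_seg[s])) {
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("P%dF%d", i, s - 1L), segment = s - 1L,
          left_overhang = switch(s, "AATG", "GCAA", left3[i], "TGCC"),
          right_overhang = switch(s, "GCAA", right2[i], "TGCC", "TAAT"),
          dna = reverse_translate(seg_aa[[s]][i]),
          stringsAsFactors = FALSE)
      }
    }
    out <- fragment_set(do.call(rbind, rows))
    attr(out, "synthetic") <- TRUE
    out
  })
}

#' Enumerated synthetic GH1-style sequence space
#'
#' Convenience wrapper: [synthetic_fragment_library()] -> [assembly_graph()]
#' -> [enumerate_designs()]. The result is the 1,352-design space used as the
#' package's default simulation arena.
#'
#' @inheritParams synthetic_fragment_library
#' @return A \code{sequence_space}.
#' @export
synthetic_space <- function(seed = 1) {
  enumerate_designs(assembly_graph(synthetic_fragment_library(seed)))
}
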