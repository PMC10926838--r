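#' Build the DNA assembly graph of a fragment library
#'
#' The assembly graph encodes which fragments can be ligated in a one-pot
#' Golden Gate reaction: a directed edge runs from fragment \code{u} in
#' segment \code{s} to fragment \code{v} in segment \code{s + 1} exactly when
#' \code{u}'s right overhang equals \code{v}'s left overhang (exact 4-mer
#' equality on the top strand as written 5'->3'; fragments are assumed
#' pre-oriented for a single junction convention, so no reverse-complement
#' matching is attempted). A virtual \code{Start} node connects to every
#' segment-0 fragment whose left overhang matches \code{start_overhang}, and
#' every last-segment fragment whose right overhang matches
#' \code{stop_overhang} connects to \code{Stop}. Every Start-to-Stop path is
#' one assemblable gene.
#'
#' @param fragments A [fragment_set()].
#' @param start_overhang 4-base overhang presented by the vector/Start side;
#'   by default the most common left overhang of segment-0 fragments.
#' @param stop_overhang 4-base overhang on the Stop side; by default the most
#'   common right overhang of the last segment.
#' @return An \code{assembly_graph}: list with \code{fragments}, \code{edges}
#'   (data frame \code{from}, \code{to} of fragment ids, with \code{"Start"}
#'   and \code{"Stop"} as virtual ids), \code{start_overhang},
#'   \code{stop_overhang}.
#' @examples
#' frags <- synthetic_fragment_library()
#' g <- assembly_graph(frags)
#' count_paths(g)   # 1352
#' @export
assembly_graph <- function(fragments, start_overhang = NULL,
                           stop_overhang = NULL) {
  stopifnot(inherits(fragments, "fragment_set"))
  segs <- sort(unique(fragments$segment))
  if (!identical(segs, seq_along(segs) - 1L))
    stop("segments must be consecutive starting at 0; got ",
         paste(segs, collapse = ","))
  mode_of <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  first <- fragments[fragments$segment == 0L, ]
  last <- fragments[fragments$segment == max(segs), ]
  if (is.null(start_overhang)) start_overhang <- mode_of(first$left_overhang)
  if (is.null(stop_overhang)) stop_overhang <- mode_of(last$right_overhang)
  start_overhang <- toupper(start_overhang)
  stop_overhang <- toupper(stop_overhang)

  edges <- list()
  edges[[1]] <- data.frame(from = "Start",
                           to = first$id[first$left_overhang == start_overhang],
                           stringsAsFactors = FALSE)
  for (s in segs[-length(segs)]) {
    up <- fragments[fragments$segment == s, ]
    dn <- fragments[fragments$segment == s + 1L, ]
    hit <- outer(up$right_overhang, dn$left_overhang, "==")
    idx <- which(hit, arr.ind = TRUE)
    edges[[length(edges) + 1]] <- data.frame(from = up$id[idx[, 1]],
                                             to = dn$id[idx[, 2]],
                                             stringsAsFactors = FALSE)
  }
  edges[[length(edges) + 1]] <-
    data.frame(from = last$id[last$right_overhang == stop_overhang],
               to = "Stop", stringsAsFactors = FALSE)
  edges <- do.call(rbind, edges)
  structure(list(fragments = fragments, edges = edges,
                 start_overhang = start_overhang,
                 stop_overhang = stop_overhang),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("Assembly graph: ", nrow(x$fragments), " fragments, ",
      nrow(x$edges), " edges (incl. Start/Stop), ",
      count_paths(x), " Start->Stop paths\n", sep = "")
  invisible(x)
}

#' Count assemblable genes by dynamic programming
#'
#' Counts distinct Start-to-Stop paths of an assembly graph. Because segment
#' indices strictly increase along edges the graph is a layered DAG, so the
#' count is accumulated segment by segment in topological order: the number
#' of partial assemblies ending at a fragment is the sum over its compatible
#' predecessors.
#'
#' @param graph An [assembly_graph()].
#' @return Integer path count (0 when no complete assembly exists).
#' @export
count_paths <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  sum(path_counts_to(graph))
}

# complete-path counts attributed to each terminal fragment (0 elsewhere)
path_counts_to <- function(graph) {
  fr <- graph$fragments
  e <- graph$edges
  npaths <- stats::setNames(numeric(nrow(fr)), fr$id)
  seg0 <- fr$id[fr$segment == 0L]
  from_start <- e$to[e$from == "Start"]
  npaths[seg0] <- as.numeric(seg0 %in% from_start)
  for (s in sort(unique(fr$segment))[-1]) {
    for (id in fr$id[fr$segment == s]) {
      pred <- e$from[e$to == id & e$from != "Start"]
      npaths[id] <- sum(npaths[pred])
    }
  }
  term <- e$from[e$to == "Stop"]
  npaths[!(names(npaths) %in% term)] <- 0
  npaths
}

#' Enumerate every design in a combinatorial sequence space
#'
#' Walks all Start-to-Stop paths of the assembly graph and emits one design
#' per path: the ordered fragment ids, the assembled protein (concatenated
#' fragment translations), the assembled coding DNA, and a short code made of
#' each fragment's within-segment index. Duplicate protein sequences arising
#' from distinct paths are retained as distinct designs (they are different
#' genotypes) but flagged, with a warning, since a well-designed library
#' should make every path a unique protein.
#'
#' @param graph An [assembly_graph()].
#' @param max_designs Refuse enumeration above this many paths (guards
#'   against combinatorial blow-ups; default 1e6).
#' @return A \code{sequence_space}: list with \code{designs} (data frame
#'   \code{design}, \code{short_code}, \code{protein}, \code{dna},
#'   \code{duplicated_protein}), \code{fragment_ids} (design x segment
#'   character matrix), \code{fragments}, and lazily-cached encodings.
#' @examples
#' sp <- enumerate_designs(assembly_graph(synthetic_fragment_library()))
#' nrow(sp$designs)
#' @export
enumerate_designs <- function(graph, max_designs = 1e6) {
  np <- count_paths(graph)
  if (np > max_designs)
    stop("space has ", np, " paths, above the enumeration cap of ",
         max_designs)
  fr <- graph$fragments
  e <- graph$edges
  segs <- sort(unique(fr$segment))
  # expand segment by segment, keeping only extendable partial paths
  paths <- lapply(e$to[e$from == "Start"], function(id) id)
  for (s in segs[-1]) {
    nxt <- list()
    for (p in paths) {
      tail_id <- p[length(p)]
      succ <- e$to[e$from == tail_id & e$to != "Stop"]
      for (id in succ) nxt[[length(nxt) + 1]] <- c(p, id)
    }
    paths <- nxt
  }
  term <- e$from[e$to == "Stop"]
  paths <- Filter(function(p) p[length(p)] %in% term, paths)
  stopifnot(length(paths) == np)
  if (np == 0)
    return(structure(list(designs = data.frame(), fragment_ids = NULL,
                          fragments = fr), class = "sequence_space"))
  ids <- do.call(rbind, paths)
  colnames(ids) <- paste0("segment", segs)
  aa_of <- stats::setNames(fr$aa, fr$id)
  dna_of <- stats::setNames(fr$dna, fr$id)
  protein <- apply(ids, 1, function(r) paste0(aa_of[r], collapse = ""))
  dna <- apply(ids, 1, function(r) paste0(dna_of[r], collapse = ""))
  # short code: within-segment 1-based index of each chosen fragment
  code_mat <- vapply(seq_along(segs), function(j) {
    seg_ids <- fr$id[fr$segment == segs[j]]
    match(ids[, j], seg_ids)
  }, integer(np))
  if (np == 1L) code_mat <- matrix(code_mat, nrow = 1)
  short_code <- apply(code_mat, 1, paste0, collapse = "")
  dup <- duplicated(protein) | duplicated(protein, fromLast = TRUE)
  if (any(dup))
    warning(sum(dup), " designs share a protein sequence with another path")
  designs <- data.frame(design = seq_len(np), short_code = short_code,
                        protein = protein, dna = dna,
                        duplicated_protein = dup, stringsAsFactors = FALSE)
  structure(list(designs = designs, fragment_ids = ids, fragments = fr),
            class = "sequence_space")
}

#' @export
print.sequence_space <- function(x, ...) {
  n <- nrow(x$designs)
  cat("Combinatorial sequence space: ", n, " designs, ",
      if (n) nchar(x$designs$protein[1]) else 0, " aa each\n", sep = "")
  if (n) {
    st <- pairwise_distance_stats(x)
    cat(sprintf("pairwise substitutions: mean %.1f, min %d, max %d\n",
                st$mean, st$min, st$max))
  }
  invisible(x)
}
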