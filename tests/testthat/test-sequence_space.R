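test_that("fragment loading validates overhangs, translation and segments", {
  path <- write_toy_fragment_csv()
  fr <- read_fragments(path)
  expect_s3_class(fr, "fragment_set")
  expect_equal(nrow(fr), 3)
  expect_equal(fr$aa[fr$id == "A0"], "MA")
  expect_setequal(fr$left_overhang[fr$segment == 0], "AATG")

  bad <- data.frame(id = "x", segment = 0, left_overhang = "AAT",
                    right_overhang = "GCAA", dna = "ATGGCT")
  expect_error(read_fragments(write_toy_fragment_csv(bad)), "4 bases")

  stopc <- data.frame(id = "x", segment = 0, left_overhang = "AATG",
                      right_overhang = "GCAA", dna = "ATGTAAGCT")
  expect_error(read_fragments(write_toy_fragment_csv(stopc)), "stop codon")

  dup <- data.frame(id = c("x", "x"), segment = c(0, 0),
                    left_overhang = "AATG", right_overhang = "GCAA",
                    dna = "ATGGCT")
  expect_error(fragment_set(dup), "duplicated")

  uneq <- data.frame(id = c("x", "y"), segment = 0,
                     left_overhang = "AATG", right_overhang = "GCAA",
                     dna = c("ATGGCT", "ATG"))
  expect_error(fragment_set(uneq), "unequal amino-acid lengths")
})

test_that("fragment FASTA round-trips through structured headers", {
  fr <- toy_fragments(c(2, 2))
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_len(nrow(fr)), function(i)
    c(sprintf(">%s|%d|%s|%s", fr$id[i], fr$segment[i],
              fr$left_overhang[i], fr$right_overhang[i]), fr$dna[i]))),
    path)
  fr2 <- read_fragments(path)
  expect_equal(fr2$aa, fr$aa)
  expect_equal(fr2$right_overhang, fr$right_overhang)
})

test_that("assembly graph edges equal brute-force overhang comparison", {
  for (seed in 1:12) {
    fr <- random_library(seed)
    g <- assembly_graph(fr, start_overhang = "AATG",
                        stop_overhang = "TAAT")
    internal <- g$edges[g$edges$from != "Start" & g$edges$to != "Stop", ]
    # O(n^2) oracle: compare every ordered fragment pair directly
    expected <- list()
    for (i in seq_len(nrow(fr))) for (j in seq_len(nrow(fr))) {
      if (fr$segment[j] == fr$segment[i] + 1 &&
          fr$right_overhang[i] == fr$left_overhang[j])
        expected[[length(expected) + 1]] <- paste(fr$id[i], fr$id[j])
    }
    exp_edges <- unlist(expected)
    if (is.null(exp_edges)) exp_edges <- character(0)
    expect_setequal(paste(internal$from, internal$to), exp_edges)
  }
})

test_that("fully compatible segments give complete bipartite edges and
           product path counts", {
  sp <- tiny_space()
  expect_equal(nrow(sp$designs), 2 * 3 * 2)
  g <- assembly_graph(toy_fragments(c(2, 3, 2)))
  inner <- g$edges[g$edges$from != "Start" & g$edges$to != "Stop", ]
  expect_equal(nrow(inner), 2 * 3 + 3 * 2)
})

test_that("path-count DP agrees with recursive DFS enumeration on random
           graphs", {
  for (seed in 1:50) {
    fr <- random_library(seed + 100)
    g <- assembly_graph(fr, start_overhang = "AATG",
                        stop_overhang = "TAAT")
    expect_equal(count_paths(g), length(dfs_paths(g)),
                 info = paste("seed", seed))
  }
})

test_that("enumeration matches the DP count and respects the cap", {
  for (seed in c(3, 17, 44)) {
    fr <- random_library(seed + 300)
    g <- assembly_graph(fr, start_overhang = "AATG",
                        stop_overhang = "TAAT")
    np <- count_paths(g)
    sp <- enumerate_designs(g)
    expect_equal(nrow(sp$designs), np)
    if (np > 0) {
      # consecutive fragments in each design are graph-adjacent
      e <- paste(g$edges$from, g$edges$to)
      ids <- sp$fragment_ids
      for (r in seq_len(min(5, nrow(ids))))
        for (j in seq_len(ncol(ids) - 1))
          expect_true(paste(ids[r, j], ids[r, j + 1]) %in% e)
      # protein equals concatenated fragment translations
      aa_of <- setNames(fr$aa, fr$id)
      expect_equal(sp$designs$protein[1],
                   paste0(aa_of[ids[1, ]], collapse = ""))
    }
  }
  g <- assembly_graph(toy_fragments(c(3, 3)))
  expect_error(enumerate_designs(g, max_designs = 5), "cap")
})

test_that("a dead-end fragment yields zero paths through it", {
  df <- data.frame(
    id = c("a", "b", "c"), segment = c(0, 0, 1),
    left_overhang = c("AATG", "AATG", "GCAA"),
    right_overhang = c("GCAA", "CCCC", "TAAT"),  # b matches nothing
    dna = c("ATGGCT", "ATGTCT", "GGTGCT"))
  g <- assembly_graph(fragment_set(df), "AATG", "TAAT")
  expect_equal(count_paths(g), 1)
  expect_false("b" %in% g$edges$from[g$edges$to == "c"])
})

test_that("pairwise distance stats match hand-counted Hamming distances", {
  sp <- tiny_space()
  # overwrite proteins with hand-written 5-mers at distances {1,2,3}
  sp$designs <- sp$designs[1:3, ]
  sp$designs$protein <- c("AAAAA", "AAAAB", "AABBB")
  sp$fragment_ids <- sp$fragment_ids[1:3, ]
  st <- pairwise_distance_stats(sp)
  expect_equal(st$mean, 2)
  expect_equal(st$min, 1)
  expect_equal(st$max, 3)
  expect_equal(st$n_pairs, 3)

  one <- sp; one$designs <- one$designs[1, , drop = FALSE]
  expect_warning(st1 <- pairwise_distance_stats(one), "undefined")
  expect_true(is.na(st1$mean))
})

test_that("Hamming distances are symmetric, non-negative and satisfy the
           triangle inequality", {
  sp <- toy_space(c(3, 3), aa_len = 12, seed = 9)
  D <- hamming_matrix(sp)
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  with_seed_local(1, for (k in 1:50) {
    ijk <- sample(nrow(D), 3)
    expect_lte(D[ijk[1], ijk[3]], D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]])
  })
  # matrix route equals direct character comparison
  p <- sp$designs$protein
  for (k in 1:10) {
    ij <- with_seed_local(k, sample(length(p), 2))
    expect_equal(D[ij[1], ij[2]], hamming_chr(p[ij[1]], p[ij[2]]))
  }
})

test_that("one-hot encoding realizes Hamming similarity as a dot product", {
  sp <- toy_space(c(3, 2, 3), aa_len = 10, seed = 5)
  X <- encode_space(sp)
  V <- length(attr(X, "variable_columns"))
  expect_true(all(rowSums(X) == V))
  D <- hamming_matrix(sp)
  G <- tcrossprod(X)
  expect_equal(V - G, D, ignore_attr = TRUE)
  # identical rows dot to V; maximally different rows dot to 0
  expect_equal(unname(diag(G)), rep(V, nrow(X)))
})

test_that("argmax decoding of one-hot rows recovers the variable-column
           residues", {
  sp <- toy_space(c(2, 3), aa_len = 8, seed = 11)
  X <- encode_space(sp)
  dec <- decode_rows(X)
  M <- matrix(unlist(strsplit(sp$designs$protein, "")),
              nrow = nrow(X), byrow = TRUE)
  vc <- attr(X, "variable_columns") + 1L
  expect_equal(unname(dec), unname(M[, vc, drop = FALSE]))
})

test_that("protein FASTA export writes one record per design", {
  sp <- tiny_space()
  path <- tempfile(fileext = ".fa")
  write_space_fasta(sp, path)
  seqs <- Biostrings::readAAStringSet(path)
  expect_length(seqs, nrow(sp$designs))
  expect_equal(unname(as.character(seqs[1])), sp$designs$protein[1])
})
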