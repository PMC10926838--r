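# Shared fixtures and independent oracles used across the test files.
# Everything is built in code at test time; nothing is read from disk.

# -- tiny fragment CSV on disk (exercises the loader path)
write_toy_fragment_csv <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(
      id = c("A0", "B0", "A1"), segment = c(0, 0, 1),
      left_overhang = c("AATG", "AATG", "GCAA"),
      right_overhang = c("GCAA", "GCAA", "TAAT"),
      dna = c("ATGGCT", "ATGTCT", "GGTGCT"))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# -- random layered fragment libraries with partial overhang compatibility,
#    for property tests of the assembly graph
random_library <- function(seed) {
  with_seed_local(seed, {
    n_seg <- sample(2:4, 1)
    sizes <- sample(2:4, n_seg, replace = TRUE)
    ov_pool <- c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT", "TGCA")
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
    rows <- list()
    for (s in seq_len(n_seg)) {
      for (i in seq_len(sizes[s])) {
        aa <- sample(aas, 4, replace = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("S%dF%d", s - 1, i), segment = s - 1,
          left_overhang = if (s == 1) "AATG" else sample(ov_pool, 1),
          right_overhang = if (s == n_seg) "TAAT" else sample(ov_pool, 1),
          dna = paste0(codon[aa], collapse = ""))
      }
    }
    seqbo::fragment_set(do.call(rbind, rows))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# -- independent DFS path enumerator over an assembly graph (the oracle the
#    dynamic-programming count is checked against; recursive, no DP)
dfs_paths <- function(graph) {
  e <- graph$edges
  walk <- function(node) {
    succ <- e$to[e$from == node]
    if (length(succ) == 0) return(list())
    out <- list()
    for (v in succ) {
      if (v == "Stop") out[[length(out) + 1]] <- character(0)
      else for (p in walk(v)) out[[length(out) + 1]] <- c(v, p)
    }
    out
  }
  walk("Start")
}

# -- direct character-level Hamming distance
hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# -- closed-form GP regression posterior for small cases (direct solve,
#    no Cholesky), the oracle for the package's implementation
gp_posterior_direct <- function(X, y, Xs, sigma0, noise) {
  K <- sigma0^2 + X %*% t(X) + diag(noise, nrow(X))
  Ks <- sigma0^2 + Xs %*% t(X)
  kss <- sigma0^2 + rowSums(Xs^2)
  mu <- Ks %*% solve(K, y)
  v <- kss - diag(Ks %*% solve(K, t(Ks)))
  list(mu = drop(mu), var_latent = drop(v))
}

# -- small shared spaces
tiny_space <- function() toy_space(c(2, 3, 2), aa_len = 6, seed = 7)

# cached large synthetic arena (built once per test run)
arena <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- synthetic_space()
      X <- encode_space(sp)
      cache <<- list(space = sp, X = X, gram = tcrossprod(X),
                     oracle = generate_landscape(sp, oracle_params()))
    }
    cache
  }
})
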