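# shared builders and independent oracles for the test suite

# write a small data frame as a temporary TSV, returning its path
tmp_tsv <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  con <- file(path, open = "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# a minimal, well-formed ingredient table
make_catalogue <- function(n = 4) {
  m <- max(n, 1)
  df <- data.frame(
    ingredient_id = sprintf("m%02d", seq_len(m)),
    name = paste("cmpd", seq_len(m)),
    ob = seq(25, by = 10, length.out = m),
    dl = seq(0.1, by = 0.2, length.out = m),
    hl = seq(3, by = 1.5, length.out = m),
    stringsAsFactors = FALSE
  )
  df[seq_len(n), , drop = FALSE]
}

make_pairs <- function(compound, target, score) {
  data.frame(compound_id = compound, target_uniprot = target,
             likelihood = score, stringsAsFactors = FALSE)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw n of N subjects without replacement, term has K members (subjects
# 1..K); returns P[overlap >= k] by enumerating every C(N, n) draw
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# brute-force affine predictor used as the oracle for predict_hl
hl_oracle <- function(d, model) {
  total <- model$intercept
  for (nm in names(model$coef)) total <- total + model$coef[[nm]] * d[[nm]]
  total
}
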